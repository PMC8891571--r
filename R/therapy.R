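# Therapy: chemotherapy protocols and dosing, targeted receptor blockade,
# drug-induced kill rules and treatment metrics (fraction of killed cells).

#' Define a therapy protocol
#'
#' @param kind `"none"`, `"chemo"`, `"targeted"` or `"combination"`.
#' @param dose Dose per cycle in µg/m² (paper scenarios use 5, 7.5, 10).
#' @param cycle_days Cycle length in days (about 7 for the weekly schedule,
#'   10 for the MTD regimen, 6 for the metronomic one).
#' @param n_cycles Number of cycles.
#' @param start_day First treatment day.
#' @param infusion_days Days of continuous drug release at the start of each
#'   cycle.
#' @param blocked_receptors For targeted/combination therapy: receptors
#'   forced off, subset of `c("Integrin", "RTK", "Cadherin", "Wnt")`.
#' @param block_start,block_end Day window of the receptor blockade.
#' @return List of class `therapy_protocol`.
#' @export
therapy_protocol <- function(kind = c("none", "chemo", "targeted",
                                      "combination"),
                             dose = 0, cycle_days = 7, n_cycles = 5,
                             start_day = 0, infusion_days = 1,
                             blocked_receptors = character(),
                             block_start = start_day, block_end = Inf) {
  kind <- match.arg(kind)
  stopifnot(dose >= 0, start_day >= 0, cycle_days > 0, n_cycles >= 0)
  if (length(blocked_receptors) && !kind %in% c("targeted", "combination")) {
    stop("blocked receptors require kind 'targeted' or 'combination'",
         call. = FALSE)
  }
  bad <- setdiff(blocked_receptors, c("Integrin", "RTK", "Cadherin", "Wnt"))
  if (length(bad)) stop("unknown receptors: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(kind = kind, dose = dose, cycle_days = cycle_days,
                 n_cycles = n_cycles, start_day = start_day,
                 infusion_days = infusion_days,
                 blocked_receptors = blocked_receptors,
                 block_start = block_start, block_end = block_end),
            class = "therapy_protocol")
}

#' Per-MCS drug source activity of a protocol
#'
#' Maps the body-surface-area dose linearly onto the drug release interval
#' (5 µg/m² corresponds to 2.55e-16 and 10 µg/m² to 5.1e-16 mol/cell/s, so
#' the activity is `dose` in µg/m² during infusion windows and 0 outside).
#' Release is continuous for the first `infusion_days` of every cycle.
#' Doses above 10 µg/m² extrapolate linearly with a warning.
#'
#' @param protocol A `therapy_protocol`.
#' @param days Number of simulated days to expand.
#' @param mcs_per_day Monte Carlo steps (minutes) per day.
#' @return Numeric vector of length `days * mcs_per_day`: dose activity
#'   (µg/m²) per MCS; multiply by the configured per-dose release rate for
#'   pg/voxel/s.
#' @export
dose_timeseries <- function(protocol, days, mcs_per_day = 1440L) {
  n <- as.integer(round(days * mcs_per_day))
  act <- numeric(n)
  if (protocol$kind %in% c("chemo", "combination") && protocol$dose > 0) {
    if (protocol$dose > 10) {
      warning("dose above the 10 µg/m² calibration range; ",
              "extrapolating linearly")
    }
    for (cyc in seq_len(protocol$n_cycles)) {
      m0 <- round((protocol$start_day + (cyc - 1) * protocol$cycle_days) *
                    mcs_per_day)
      m1 <- min(m0 + round(protocol$infusion_days * mcs_per_day), n)
      if (m0 < n && m1 > m0) act[(m0 + 1):m1] <- protocol$dose
    }
  }
  act
}

#' Drug-damage transition rule
#'
#' Only proliferating/migrating (and already drug-arrested) cells take up
#' drug; reaching the first cumulative-uptake threshold forces the cell into
#' quiescence (mitotic arrest), reaching the second kills it by necrosis.
#'
#' @param type Current cell type code.
#' @param cum_uptake Cumulative drug uptake of the cell (pg).
#' @param cfg A `tumor_config` (thresholds `theta1`, `theta2`).
#' @return List: new `type` and logical `drug_arrested`, `killed`.
#' @export
drug_kill_update <- function(type, cum_uptake, cfg = default_config()) {
  if (!type %in% c(TYPE_M, TYPE_P, TYPE_Q)) {
    return(list(type = type, drug_arrested = FALSE, killed = FALSE))
  }
  if (cum_uptake >= cfg$theta2) {
    list(type = TYPE_N, drug_arrested = TRUE, killed = TRUE)
  } else if (cum_uptake >= cfg$theta1) {
    list(type = TYPE_Q, drug_arrested = TRUE, killed = FALSE)
  } else {
    list(type = type, drug_arrested = FALSE, killed = FALSE)
  }
}

#' Force blocked receptors off in a set of receptor inputs
#'
#' Targeted therapy is modelled as receptor-level signalling blockade: the
#' listed receptors are forced off in every tumour cell's 6-bit input before
#' the network is evaluated. Blocking RTK or integrin drives the network
#' into the apoptosis attractor.
#'
#' @param inputs Data frame from [receptor_inputs()].
#' @param blocked Character vector of receptors to force off.
#' @return The inputs with blocked columns set to `FALSE`.
#' @export
targeted_block <- function(inputs, blocked = character()) {
  map <- c(Integrin = "Integrin", RTK = "RTK", Cadherin = "Cadherin",
           Wnt = "Wnt")
  bad <- setdiff(blocked, names(map))
  if (length(bad)) stop("unknown receptors: ", paste(bad, collapse = ", "))
  for (b in blocked) inputs[[map[[b]]]] <- FALSE
  inputs
}

#' Fraction of killed cells
#'
#' FKC(t) = cells killed by therapy up to t divided by the population at
#' risk (viable tumour cells when therapy started plus cells born since),
#' clamped to [0, 1].
#'
#' @param trace A simulation trace data frame (see [run_simulation()]) with
#'   columns `day`, `n_P`, `n_Q`, `n_M`, `births`, `killed_therapy`.
#' @param start_day Day therapy started.
#' @return The trace with an `fkc` column.
#' @export
fkc <- function(trace, start_day) {
  i0 <- which(trace$day >= start_day)[1]
  if (is.na(i0)) stop("therapy never started within the trace", call. = FALSE)
  baseline <- trace$n_P[i0] + trace$n_Q[i0] + trace$n_M[i0]
  births0 <- trace$births[i0]
  killed0 <- trace$killed_therapy[i0]
  at_risk <- baseline + pmax(trace$births - births0, 0)
  val <- (trace$killed_therapy - killed0) / pmax(at_risk, 1)
  val[trace$day < start_day] <- 0
  trace$fkc <- pmin(pmax(val, 0), 1)
  trace
}

#' Classify the treatment outcome of a run
#'
#' `eradicated`: no viable tumour cells remain; `dormant`: the volume stays
#' within ±20% of the post-therapy nadir for at least 30 days; `relapse`:
#' regrowth above the pre-therapy volume after a nadir; `failure`: monotone
#' growth through therapy.
#'
#' @param trace Trace data frame with columns `day`, `tumor_vox`, `n_P`,
#'   `n_Q`, `n_M`.
#' @param protocol The `therapy_protocol` applied.
#' @return One of `"eradicated"`, `"dormant"`, `"relapse"`, `"failure"`.
#' @export
classify_outcome <- function(trace, protocol) {
  last_cycle_end <- protocol$start_day +
    protocol$n_cycles * protocol$cycle_days
  if (max(trace$day) < last_cycle_end + 30) {
    stop("trace must span at least 30 days beyond the last cycle",
         call. = FALSE)
  }
  viable <- trace$n_P + trace$n_Q + trace$n_M
  if (utils::tail(viable, 1) == 0) return("eradicated")
  v <- trace$tumor_vox
  pre <- v[which.min(abs(trace$day - protocol$start_day))]
  post <- trace$day >= protocol$start_day
  nadir_i <- which(post)[which.min(v[post])]
  nadir <- v[nadir_i]
  after <- v[trace$day >= trace$day[nadir_i]]
  if (any(after > pre) && nadir < pre) return("relapse")
  span <- trace$day >= trace$day[nadir_i] &
    trace$day <= trace$day[nadir_i] + 30
  if (sum(span) >= 2 && all(abs(v[span] - nadir) <= 0.2 * pmax(nadir, 1))) {
    return("dormant")
  }
  if (all(diff(v[post]) >= 0)) return("failure")
  "failure"
}
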