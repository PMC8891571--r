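# Coupling the microenvironment to the signalling network: receptor inputs
# from cell geometry and fields, phenotype application, the viability state
# machine and endothelial activation.

#' Receptor inputs of every live cell
#'
#' Derives the six Boolean receptor inputs from cell geometry and fields:
#' E-cadherin is on when the fraction of the cell boundary contacting other
#' viable tumour cells reaches `T_cad`; integrin is on when the fraction
#' contacting ECM reaches `T_ITG`; Wnt is on when the cadherin contact
#' fraction falls below `T_wnt` (cadherin loss de-represses Wnt); RTK is on
#' when the mean nutrient per voxel reaches `T_RTK` (`T_RTK_Q` for currently
#' quiescent cells — hysteresis); APC and NF1 are scenario flags. The inputs
#' are a pure function of (geometry, fields, thresholds).
#'
#' @param st A `sim_state`.
#' @param block Character vector of receptors forced off (targeted therapy):
#'   subset of `c("Integrin", "RTK", "Cadherin", "Wnt")`.
#' @return Data frame, one row per live cell: id, type, contact fractions,
#'   mean nutrient and the six input bits.
#' @export
receptor_inputs <- function(st, block = character()) {
  cfg <- st$config
  cs <- cpp_cell_stats(engine_state(st))
  ids <- seq_len(st$ncell)
  live <- st$cell_type[ids] != 0L
  bf <- pmax(cs$boundary_faces, 1L)
  frac_viable <- cs$faces_viable_tumor / bf
  frac_ecm <- cs$faces_ecm / bf
  mean_n <- cs$sum_nutrient / pmax(cs$volume, 1L)
  quiescent <- st$cell_type[ids] == TYPE_Q
  rtk_thr <- ifelse(quiescent & st$drug_q[ids] == 0L, cfg$T_RTK_Q, cfg$T_RTK)
  out <- data.frame(
    id = ids,
    type = st$cell_type[ids],
    contact_viable = frac_viable,
    contact_ecm = frac_ecm,
    mean_nutrient = mean_n,
    Integrin = frac_ecm >= cfg$T_ITG & !("Integrin" %in% block),
    RTK = mean_n >= rtk_thr & !("RTK" %in% block),
    Cadherin = frac_viable >= cfg$T_cad & !("Cadherin" %in% block),
    Wnt = frac_viable < cfg$T_wnt & !("Wnt" %in% block),
    APC = cfg$apc_on == 1L,
    NF1 = cfg$nf1_on == 1L
  )
  out[live, , drop = FALSE]
}

#' Behaviour flags implied by a phenotype code
#'
#' Maps a 4-bit phenotype code from the signalling network onto cellular
#' Potts behaviour: `1100` enables growth and division with chemotaxis off;
#' `1101` additionally makes the cell migratory (type M with the migrating
#' chemotactic potential); `0010`/`0011` mark apoptosis (target volume is
#' driven to zero and the cell is removed once it shrinks out). Codes never
#' reached by the network are rejected.
#'
#' @param code Phenotype code string (`"1100"`, `"1101"`, `"0010"`, `"0011"`).
#' @param cfg A `tumor_config` (for the chemotactic potential).
#' @return List: `grow`, `proliferate`, `apoptosis`, `migrate`, `cell_type`,
#'   `chi`.
#' @export
apply_phenotype <- function(code, cfg = default_config()) {
  reachable <- c("1100", "1101", "0010", "0011")
  if (!code %in% reachable) {
    stop("phenotype code '", code, "' is not reachable by the signalling ",
         "network (expected one of ", paste(reachable, collapse = ", "), ")",
         call. = FALSE)
  }
  bits <- as.integer(strsplit(code, "")[[1]]) == 1L
  if (bits[3]) {
    list(grow = FALSE, proliferate = FALSE, apoptosis = TRUE,
         migrate = bits[4], cell_type = NA_integer_, chi = 0)
  } else {
    list(grow = bits[1], proliferate = bits[2], apoptosis = FALSE,
         migrate = bits[4],
         cell_type = if (bits[4]) TYPE_M else TYPE_P,
         chi = if (bits[4]) unname(cfg$chi["M"]) else 0)
  }
}

#' Viability state transition of a tumour cell
#'
#' Pure transition rule of the P/M/Q/N machine: proliferating or migrating
#' cells fall quiescent when the mean nutrient drops below `T_RTK`;
#' quiescent cells recover to proliferating only above the higher `T_RTK_Q`
#' (hysteresis); quiescence longer than `tau_N` becomes necrosis; necrosis
#' is absorbing until cleared after `tau_clear`.
#'
#' @param type Current type code (2 = M, 3 = P, 4 = Q, 5 = N).
#' @param mean_nutrient Mean nutrient per voxel of the cell (pg/voxel).
#' @param hypoxia_min Minutes spent continuously nutrient-starved.
#' @param necro_min Minutes since necrosis.
#' @param cfg A `tumor_config`.
#' @return List: new `type` (`0` once a necrotic cell is cleared) and the
#'   updated clocks.
#' @export
update_viability_state <- function(type, mean_nutrient, hypoxia_min = 0L,
                                   necro_min = 0L, cfg = default_config()) {
  if (type == TYPE_N) {
    necro_min <- necro_min + 1L
    if (necro_min >= cfg$tau_clear) type <- 0L
    return(list(type = type, hypoxia_min = hypoxia_min,
                necro_min = necro_min))
  }
  thr <- if (type == TYPE_Q) cfg$T_RTK_Q else cfg$T_RTK
  if (mean_nutrient >= thr) {
    if (type == TYPE_Q) type <- TYPE_P
    hypoxia_min <- 0L
  } else {
    type <- TYPE_Q
    hypoxia_min <- hypoxia_min + 1L
    if (hypoxia_min >= cfg$tau_N) {
      type <- TYPE_N
      necro_min <- 0L
    }
  }
  list(type = type, hypoxia_min = hypoxia_min, necro_min = necro_min)
}

#' Endothelial activation by local VEGF
#'
#' Quiescent vessel endothelial cells whose mean VEGF per voxel reaches the
#' activation threshold `T_v` become activated: they respond chemotactically
#' to the VEGF gradient and may proliferate subject to VE-cadherin contact
#' inhibition.
#'
#' @param st A `sim_state`.
#' @return Integer ids of the endothelial cells activated by this call (the
#'   state with activation flags set is attached as attribute `state`).
#' @export
ec_activation <- function(st) {
  cs <- cpp_cell_stats(engine_state(st))
  ids <- seq_len(st$ncell)
  ec <- ids[st$cell_type[ids] == TYPE_EC & st$ec_active[ids] == 0L]
  mean_V <- cs$sum_vegf / pmax(cs$volume, 1L)
  newly <- ec[mean_V[ec] >= st$config$T_v]
  st$ec_active[newly] <- 1L
  structure(newly, state = st)
}

#' VE-cadherin contact inhibition of endothelial proliferation
#'
#' An activated endothelial cell may proliferate only while the fraction of
#' its boundary in contact with other endothelial cells stays below the
#' junction threshold `theta_VE`; above it, growth and the VEGF response
#' are suppressed (contact-inhibited stalk behaviour).
#'
#' @param st A `sim_state`.
#' @param id Endothelial cell id.
#' @param theta_VE Junction threshold (default from config; `1.0` disables
#'   inhibition).
#' @return `TRUE` if proliferation is permitted.
#' @export
ve_cadherin_inhibition <- function(st, id, theta_VE = NULL) {
  if (is.null(theta_VE)) theta_VE <- st$config$theta_VE
  if (theta_VE >= 1) return(TRUE)  # degenerate config: never inhibited
  cs <- cpp_cell_stats(engine_state(st))
  frac_ec <- cs$faces_ec[id] / max(cs$boundary_faces[id], 1L)
  frac_ec < theta_VE
}
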