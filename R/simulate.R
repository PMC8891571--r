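# Orchestration: the coupled per-minute simulation loop, daily traces,
# growth-phase segmentation and output writers.

#' Run the coupled multiscale simulation
#'
#' Per Monte Carlo step (one simulated minute) the engine (1) derives each
#' cell's receptor inputs from its contacts and the fields, (2) looks up the
#' phenotype decided by the signalling network, (3) performs one cellular
#' Potts sweep, (4) applies growth, division and the viability state
#' machine, (5) updates the nutrient/VEGF/drug fields, and (6) applies the
#' active therapy schedule. A trace record is appended once per simulated
#' day. The run is reproducible for a fixed seed and stops cleanly (flagged)
#' if the tumour reaches the domain boundary.
#'
#' @param st A `sim_state` (see [make_fixture()], [build_initial_tumor()]).
#' @param days Simulated days.
#' @param protocol Optional [therapy_protocol()].
#' @param seed RNG seed.
#' @return List of class `sim_result`: final `state` and the daily `trace`
#'   data frame (day, cell-state counts, EC counts, tumour volume in voxels
#'   and µm³, equivalent spherical diameter, field totals, cumulative birth
#'   and death counters, and FKC when a therapy was active).
#' @export
run_simulation <- function(st, days, protocol = NULL, seed = 1L) {
  stopifnot(inherits(st, "sim_state"), days >= 0)
  cfg <- st$config
  old <- bn_set_seed(seed)
  on.exit(bn_restore_seed(old), add = TRUE)
  # schedules are indexed by the absolute clock, so continuation runs need
  # the elapsed time included
  params <- build_engine_params(cfg, protocol = protocol,
                                days = days + st$clock_mcs / cfg$mcs_per_day)
  rows <- list(trace_record(st))
  if (days > 0) {
    res <- cpp_run(engine_state(st), params,
                   as.integer(days * cfg$mcs_per_day),
                   as.integer(cfg$mcs_per_day))
    st <- r_state(res$state, st)
    tr <- res$trace
    for (i in seq_len(nrow(tr))) rows[[length(rows) + 1L]] <- tr[i, ]
  }
  trace <- as.data.frame(do.call(rbind, rows))
  names(trace) <- c("mcs", "n_P", "n_Q", "n_M", "n_N", "n_EC", "n_EC_active",
                    "tumor_vox", "births", "deaths_apop", "drug_necro",
                    "killed_therapy", "total_n", "total_V", "total_c")
  trace$day <- trace$mcs / cfg$mcs_per_day
  vox_um3 <- cfg$voxel_um^3
  trace$volume_um3 <- trace$tumor_vox * vox_um3
  trace$diameter_um <- (6 * trace$volume_um3 / pi)^(1 / 3)
  if (!is.null(protocol) && protocol$kind != "none") {
    trace <- fkc(trace, protocol$start_day)
  }
  structure(list(state = st, trace = trace, seed = seed,
                 protocol = protocol),
            class = "sim_result")
}

trace_record <- function(st) {
  ids <- seq_len(st$ncell)
  ty <- st$cell_type[ids]
  tum <- ty %in% c(TYPE_M, TYPE_P, TYPE_Q, TYPE_N)
  c(mcs = st$clock_mcs,
    n_P = sum(ty == TYPE_P), n_Q = sum(ty == TYPE_Q),
    n_M = sum(ty == TYPE_M), n_N = sum(ty == TYPE_N),
    n_EC = sum(ty == TYPE_EC),
    n_EC_active = sum(ty == TYPE_EC & st$ec_active[ids] == 1L),
    tumor_vox = sum(st$volume[ids][tum]),
    births = st$births, deaths_apop = st$deaths_apop,
    drug_necro = st$drug_necro, killed_therapy = st$killed_therapy,
    total_n = sum(st$n_field), total_V = sum(st$V_field),
    total_c = sum(st$c_field))
}

#' @export
print.sim_result <- function(x, ...) {
  tr <- x$trace
  cat("sim_result:", max(tr$day), "days;",
      "final tumour", utils::tail(tr$tumor_vox, 1), "voxels (",
      round(utils::tail(tr$diameter_um, 1), 1), "µm );",
      utils::tail(tr$n_P + tr$n_Q + tr$n_M, 1), "viable cells\n")
  invisible(x)
}

#' Segment a growth curve into three linear phases
#'
#' Fits a continuous three-segment piecewise-linear model to log-volume
#' versus time by least squares over a grid of breakpoint pairs, and returns
#' the two breakpoints and the three slopes. Used to identify the
#' slow-aggregation, rapid-proliferation and plateau phases of spheroid
#' growth.
#'
#' @param trace Trace data frame with `day` and `tumor_vox` (or a `volume`
#'   column named by `value`).
#' @param value Column to segment (log-transformed internally).
#' @param min_pts Minimum points per segment.
#' @return List: `breaks` (two days), `slopes` (three log-volume slopes per
#'   day), `sse`.
#' @export
growth_phase_segmentation <- function(trace, value = "tumor_vox",
                                      min_pts = 4L) {
  t <- trace$day
  y <- log(pmax(trace[[value]], 1))
  n <- length(t)
  if (n < 3 * min_pts) {
    stop("need at least ", 3 * min_pts, " trace points (", n, " given)",
         call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    b <- stats::quantile(t, c(1 / 3, 2 / 3), names = FALSE)
    return(list(breaks = b, slopes = c(0, 0, 0), sse = 0))
  }
  best <- NULL
  idx <- seq_len(n)
  for (i in idx[min_pts:(n - 2 * min_pts + 1)]) {
    for (j in idx[(i + min_pts - 1):(n - min_pts + 1)]) {
      b1 <- t[i]; b2 <- t[j]
      X <- cbind(1, t, pmax(t - b1, 0), pmax(t - b2, 0))
      fit <- stats::lm.fit(X, y)
      sse <- sum(fit$residuals^2)
      if (is.null(best) || sse < best$sse - 1e-12) {
        cf <- fit$coefficients
        best <- list(breaks = c(b1, b2),
                     slopes = c(cf[2], cf[2] + cf[3], cf[2] + cf[3] + cf[4]),
                     sse = sse)
      }
    }
  }
  best$slopes <- unname(best$slopes)
  best
}

#' Write run outputs
#'
#' Writes the daily trace as CSV, a run summary as JSON (seed, outcome
#' counters, config hash) and optionally a VTK structured-points snapshot of
#' the cell lattice plus a CSV cell table.
#'
#' @param result A `sim_result`.
#' @param outdir Output directory (created if missing).
#' @param snapshot Write `lattice.vtk` and `cells.csv` for the final state.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, outdir, snapshot = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trace = file.path(outdir, "trace.csv"),
             summary = file.path(outdir, "summary.json"))
  utils::write.csv(result$trace, paths["trace"], row.names = FALSE)
  st <- result$state
  summary <- list(
    seed = result$seed,
    days = max(result$trace$day),
    stopped_at_boundary = isTRUE(st$stopped),
    final_tumor_vox = utils::tail(result$trace$tumor_vox, 1),
    births = st$births, deaths_apop = st$deaths_apop,
    drug_necro = st$drug_necro, killed_therapy = st$killed_therapy,
    config_hash = config_hash(st$config),
    protocol = if (is.null(result$protocol)) "none" else
      unclass(result$protocol)
  )
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (snapshot) {
    paths <- c(paths, vtk = file.path(outdir, "lattice.vtk"),
               cells = file.path(outdir, "cells.csv"))
    write_vtk(st, paths["vtk"])
    utils::write.csv(cell_table(st), paths["cells"], row.names = FALSE)
  }
  invisible(paths)
}

#' Per-cell summary table
#'
#' @param st A `sim_state`.
#' @return Data frame: id, type label, state flags, volume, centroid.
#' @export
cell_table <- function(st) {
  ids <- which(st$cell_type[seq_len(st$ncell)] != 0L)
  labels <- c("EC", "M", "P", "Q", "N")
  cent <- t(vapply(ids, function(id) {
    colMeans(voxel_coords(st$dims, which(st$owner == id)))
  }, numeric(3)))
  data.frame(id = ids, type = labels[st$cell_type[ids]],
             volume = st$volume[ids], target_volume = st$tvol[ids],
             ec_active = st$ec_active[ids] == 1L,
             drug_arrested = st$drug_q[ids] == 1L,
             cum_drug = st$cum_drug[ids],
             x = cent[, 1], y = cent[, 2], z = cent[, 3])
}

# legacy ASCII VTK structured-points export of owner + field arrays
write_vtk <- function(st, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- st$dims
  writeLines(c("# vtk DataFile Version 3.0",
               "tumorcpm lattice snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               paste("SPACING", st$voxel_um, st$voxel_um, st$voxel_um),
               paste("POINT_DATA", prod(d))), con)
  writeLines(c("SCALARS cell_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(st$owner, collapse = " "), con)
  writeLines(c("SCALARS nutrient float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(signif(st$n_field, 6), collapse = " "), con)
  writeLines(c("SCALARS vegf float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(signif(st$V_field, 6), collapse = " "), con)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' @param cfg A `tumor_config`.
#' @return MD5 string of the canonical serialized configuration.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  dput(cfg[order(names(cfg))], file = tmp, control = "all")
  unname(tools::md5sum(tmp))
}

#' Reload a snapshot written by [save_snapshot()]
#' @param path RDS path.
#' @return The `sim_state`.
#' @export
load_snapshot <- function(path) readRDS(path)

#' Save a state snapshot (RDS archive)
#' @param st A `sim_state`.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
save_snapshot <- function(st, path) {
  saveRDS(st, path, compress = "gzip")
  invisible(path)
}
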