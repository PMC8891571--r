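# Reaction-diffusion fields: nutrient, VEGF and drug on the cell lattice.
# Explicit FTCS diffusion with no-flux domain boundaries, exact exponential
# decay, voxel-local capped uptake and cell-type-dependent sources.

# per-voxel rate vectors (pg/voxel/s) for one field, derived from the state
field_site_rates <- function(st, kind, infusing = FALSE, dose_src = 0) {
  cfg <- st$config
  vr <- config_voxel_rates(cfg)
  n <- prod(st$dims)
  cap <- numeric(n); src <- numeric(n); clamp <- rep(-1, n)
  live <- st$owner > 0L
  ty <- integer(n)
  ty[live] <- st$cell_type[st$owner[live]]
  if (kind == "nutrient") {
    cap[ty == TYPE_P | ty == TYPE_M] <- vr$beta_P_vox
    cap[ty == TYPE_Q] <- vr$beta_Q_vox
    src[ty == TYPE_EC] <- vr$s_n_vox
    clamp[ty == TYPE_EC] <- cfg$n0
  } else if (kind == "vegf") {
    cap[ty == TYPE_EC] <- vr$e_vox
    hyp <- ty == TYPE_N |
      (ty == TYPE_Q & st$hypoxia_min[pmax(st$owner, 1L)] > 0L & live)
    src[hyp] <- cfg$s_V_mcs / cfg$mcs_seconds  # per-MCS secretion as a rate
  } else if (kind == "drug") {
    damaged <- ty == TYPE_Q & st$drug_q[pmax(st$owner, 1L)] == 1L & live
    cap[ty == TYPE_P | ty == TYPE_M | damaged] <- vr$kappa_P_vox
    if (infusing) src[ty == TYPE_EC] <- dose_src
  } else stop("unknown field kind: ", kind)
  list(cap = cap, src = src, clamp = clamp)
}

field_constants <- function(cfg, kind) {
  switch(kind,
    nutrient = list(D = cfg$D_n, k = 0),
    vegf = list(D = cfg$D_V, k = cfg$k_V),
    drug = list(D = cfg$D_c, k = cfg$k_c),
    stop("unknown field kind: ", kind))
}

#' One explicit time step of the nutrient field
#'
#' Diffusion, capped uptake by tumour-cell voxels (per-voxel cap = per-cell
#' cap divided by the nominal cell volume; quiescent cells consume at the
#' lower quiescent rate, necrotic cells consume nothing) and release at
#' endothelial voxels, where the concentration is additionally capped at the
#' vessel value so vessels behave as saturating sources. Refuses time steps
#' violating the diffusion stability bound D dt/dx^2 <= 1/6.
#'
#' @param st A `sim_state`.
#' @param dt Time step in seconds.
#' @return The state with an updated nutrient field.
#' @export
step_nutrient <- function(st, dt) {
  r <- field_site_rates(st, "nutrient")
  st$n_field <- cpp_rd_step(st$n_field, st$dims, st$config$D_n, dt,
                            st$config$voxel_um, r$cap, r$src, 0, r$clamp)
  st
}

#' One explicit time step of the VEGF field
#'
#' Diffusion, first-order decay (applied as an exact exponential factor),
#' capped uptake at endothelial voxels and secretion at hypoxic tumour
#' voxels (nutrient-starved quiescent cells and necrotic cells).
#'
#' @inheritParams step_nutrient
#' @return The state with an updated VEGF field.
#' @export
step_vegf <- function(st, dt) {
  r <- field_site_rates(st, "vegf")
  st$V_field <- cpp_rd_step(st$V_field, st$dims, st$config$D_V, dt,
                            st$config$voxel_um, r$cap, r$src, st$config$k_V,
                            r$clamp)
  st
}

#' One explicit time step of the drug field
#'
#' Diffusion, decay, uptake by proliferative (and drug-arrested) tumour
#' voxels and, while an infusion is active, release at endothelial voxels.
#'
#' @inheritParams step_nutrient
#' @param infusing Whether a therapy cycle is currently releasing drug.
#' @param dose Dose in µg/m² used to scale the release rate.
#' @return The state with an updated drug field.
#' @export
step_drug <- function(st, dt, infusing = FALSE, dose = 0) {
  vr <- config_voxel_rates(st$config)
  r <- field_site_rates(st, "drug", infusing = infusing,
                        dose_src = vr$drug_src_vox_per_dose * dose)
  st$c_field <- cpp_rd_step(st$c_field, st$dims, st$config$D_c, dt,
                            st$config$voxel_um, r$cap, r$src, st$config$k_c,
                            r$clamp)
  st
}

#' Relax a field toward its quasi-steady profile
#'
#' Sub-cycles the explicit solver at the stable step size until the maximum
#' change per sub-step falls below `tol` (relative to the field maximum) or
#' one MCS worth of physical time (60 s) has been integrated.
#'
#' @param st A `sim_state`.
#' @param kind `"nutrient"`, `"vegf"` or `"drug"`.
#' @param tol Relative convergence tolerance.
#' @param max_time Physical time budget in seconds.
#' @return List: updated `state`, integrated `time`, `steps`, `converged`.
#' @export
relax_to_quasi_steady <- function(st, kind, tol = 1e-6, max_time = 60) {
  stopifnot(tol > 0)
  fc <- field_constants(st$config, kind)
  r <- field_site_rates(st, kind)
  fld <- switch(kind, nutrient = st$n_field, vegf = st$V_field,
                drug = st$c_field)
  res <- cpp_rd_relax(fld, st$dims, fc$D, st$config$voxel_um, r$cap, r$src,
                      fc$k, r$clamp, tol, max_time)
  if (kind == "nutrient") st$n_field <- res$field
  if (kind == "vegf") st$V_field <- res$field
  if (kind == "drug") st$c_field <- res$field
  list(state = st, time = res$time, steps = res$steps,
       converged = res$converged)
}
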