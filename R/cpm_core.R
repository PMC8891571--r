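# Cellular Potts energies and dynamics: R-facing surface over the lattice
# engine. The Hamiltonian is the sum of adhesion, volume (growth),
# continuity and chemotaxis terms; dynamics are voxel copy attempts accepted
# by the Metropolis rule at motility temperature Tm.

#' Total adhesion energy of a lattice
#'
#' Sums the type-dependent contact energy `J` over all neighbouring voxel
#' pairs belonging to different cells (each unordered pair counted once);
#' pairs inside one cell contribute nothing.
#'
#' @param st A `sim_state`.
#' @param J Optional 6x6 adhesion matrix (defaults to the state's config).
#' @param order Neighbourhood order for the sum: 1 (6 faces) or 2 (18).
#' @return Energy (numeric scalar).
#' @export
adhesion_energy <- function(st, J = NULL, order = NULL) {
  cfg <- st$config
  if (is.null(J)) J <- cfg$J
  if (is.null(order)) order <- cfg$adh_order
  cpp_total_adhesion(st$owner, st$dims, st$cell_type[seq_len(max(st$ncell, 1L))],
                     unname(J), as.integer(order))
}

#' Total volume (growth) energy
#'
#' \eqn{\sum_\sigma \gamma_e (v_\sigma - V^T_\sigma)^2} over live cells, with
#' the elasticity taken per cell type.
#'
#' @param st A `sim_state`.
#' @return Energy (numeric scalar).
#' @export
growth_energy <- function(st) {
  live <- which(st$cell_type[seq_len(st$ncell)] != 0L)
  if (!length(live)) return(0)
  ga <- unname(st$config$gamma)[st$cell_type[live] + 1L]
  sum(ga * (st$volume[live] - st$tvol[live])^2)
}

#' Total continuity energy
#'
#' Adds the penalty `alpha` once for every live cell whose voxel set is not
#' a single face-connected component (a cell about to rupture).
#'
#' @param st A `sim_state`.
#' @param alpha Penalty per fragmented cell (default from config).
#' @return Energy (numeric scalar).
#' @export
continuity_energy <- function(st, alpha = NULL) {
  if (is.null(alpha)) alpha <- st$config$alpha
  if (st$ncell == 0L) return(0)
  comp <- cpp_cell_components(st$owner, st$dims, st$ncell)
  live <- st$cell_type[seq_len(st$ncell)] != 0L
  alpha * sum(comp[live] > 1L)
}

#' Chemotaxis contribution of a copy attempt
#'
#' Returns \eqn{\chi_\sigma (C(\mathrm{target}) - C(\mathrm{source}))}, the
#' energy change contributed by the moving cell extending from the source
#' voxel into the target voxel up (or down) the chemoattractant field.
#' Tumour cells with the migratory phenotype read the nutrient field;
#' activated endothelial cells read the VEGF field.
#'
#' @param source_value,target_value Field values at the source and target
#'   voxels.
#' @param chi Chemotactic potential (must be negative or zero).
#' @return Energy change.
#' @export
chemotaxis_delta <- function(source_value, target_value, chi) {
  if (any(chi > 0)) stop("chemotactic potential must be negative (chi <= 0)")
  chi * (target_value - source_value)
}

#' Energy change of a voxel copy attempt
#'
#' Computes the local change of the full Hamiltonian if the cell owning
#' `source` copied itself into `site`. The adhesion, growth and continuity
#' parts are exact local evaluations of the corresponding global energies
#' (the continuity part re-counts the affected cells' components); the
#' chemotaxis part follows the source-target convention of
#' [chemotaxis_delta()] scaled by the configured concentration unit.
#'
#' @param st A `sim_state`.
#' @param site Lattice index of the voxel to overwrite.
#' @param source Lattice index of the neighbouring voxel whose owner copies
#'   itself into `site`.
#' @param params Optional engine parameter list (defaults from the config).
#' @return Named numeric vector: `total`, `adhesion`, `growth`,
#'   `continuity`, `chemotaxis`.
#' @export
delta_hamiltonian <- function(st, site, source, params = NULL) {
  if (is.null(params)) params <- build_engine_params(st$config)
  cand <- st$owner[source]
  cpp_delta_h(engine_state(st), params, as.integer(site), as.integer(source),
              as.integer(cand))
}

#' Metropolis acceptance rule
#'
#' Accepts every energy-lowering change; an energy-raising change is
#' accepted with the Boltzmann probability \eqn{e^{-\Delta H / T_m}}.
#'
#' @param dh Energy change(s).
#' @param Tm Motility temperature (> 0).
#' @return Logical vector of acceptances (consumes one uniform draw per
#'   positive `dh`).
#' @export
metropolis_accept <- function(dh, Tm = 10) {
  stopifnot(Tm > 0)
  cpp_metropolis(as.numeric(dh), Tm)
}

#' Run Monte Carlo steps of the cellular Potts dynamics
#'
#' One MCS performs as many random voxel copy attempts as there are lattice
#' sites and advances the simulation clock by one minute. This entry point
#' runs the lattice dynamics alone (no phenotype updates, divisions or field
#' transport); see [run_simulation()] for the coupled loop.
#'
#' @param st A `sim_state`.
#' @param n_mcs Number of Monte Carlo steps.
#' @param params Optional engine parameter list.
#' @return The updated `sim_state`.
#' @export
monte_carlo_step <- function(st, n_mcs = 1L, params = NULL) {
  if (is.null(params)) params <- build_engine_params(st$config)
  res <- cpp_run(engine_state(st), params, as.integer(n_mcs), 0L,
                 do_cpm = TRUE, do_biology = FALSE, do_fields = FALSE)
  r_state(res$state, st)
}

#' Divide every cell that has doubled its initial volume
#'
#' Cells whose volume has reached twice their initial volume split along a
#' random plane: voxels are projected on a random normal and the daughter
#' takes the half above the median projection (ties stay with the parent),
#' giving a balanced split. The parent's target volume is reset to its
#' initial volume and the daughter inherits type and target volume under a
#' fresh unique id. One-voxel cells and degenerate splits are deferred.
#'
#' @param st A `sim_state`.
#' @return The updated `sim_state`.
#' @export
grow_and_divide <- function(st) {
  r_state(cpp_divide(engine_state(st)), st)
}

# conversions between the R-facing sim_state and the flat engine list
engine_state <- function(st) {
  st[c("dims", "owner", "cell_type", "volume", "init_vol", "competent",
       "settle_min", "hypoxia_min", "necro_min", "apop_min", "ec_active",
       "drug_q", "grow_acc", "apop_by_block", "tvol", "cum_drug", "n_field",
       "V_field", "c_field", "ncell", "clock_mcs", "births", "deaths_apop",
       "drug_necro", "killed_therapy")]
}

r_state <- function(eng, template) {
  out <- template
  for (nm in names(eng)) out[[nm]] <- eng[[nm]]
  class(out) <- "sim_state"
  out
}
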