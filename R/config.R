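# Model configuration: physical parameters, unit conversions and the flat
# parameter list handed to the lattice engine.

# cell type codes shared with the engine
TYPE_MEDIUM <- 0L; TYPE_EC <- 1L; TYPE_M <- 2L; TYPE_P <- 3L
TYPE_Q <- 4L; TYPE_N <- 5L

#' Default model configuration
#'
#' Returns the full set of physical and numerical parameters with their
#' default values. Mol-based rates are converted once into the internal
#' concentration unit (pg per 4-µm voxel) using declared molar-mass-scale
#' conversion constants and the nominal 64-voxel cell volume; the conversion
#' constants are explicit, logged entries of the configuration.
#'
#' Key parameters (units): diffusivities `D_n`, `D_V`, `D_c` (µm²/s); VEGF
#' decay `k_V` and drug decay `k_c` (1/s); uptake caps and sources in
#' pg/voxel/s; receptor thresholds `T_RTK`, `T_RTK_Q`, `T_v` (pg/voxel) and
#' `T_ITG`, `T_cad`, `T_wnt` (contact fractions); cellular Potts parameters
#' `J` (type-by-type adhesion energies), `gamma` (volume elasticity), `alpha`
#' (continuity penalty), `Tm` (motility temperature), `chi` (chemotactic
#' potentials, negative).
#'
#' @param ... Named overrides of any default entry.
#' @return Named list of class `tumor_config`.
#' @export
default_config <- function(...) {
  cell_vox <- 64                 # nominal cell volume in voxels
  conv_n <- 1.8e14               # pg per mol, glucose-scale nutrient
  conv_drug <- 8.54e14           # pg per mol, taxane-scale drug
  types <- c("medium", "EC", "M", "P", "Q", "N")
  J <- matrix(0, 6, 6, dimnames = list(types, types))
  J["medium", "medium"] <- 6
  J["medium", "EC"] <- 12
  J["medium", c("M", "P", "Q")] <- 12
  J["medium", "N"] <- 10
  J["EC", "EC"] <- 5
  J["EC", c("M", "P", "Q", "N")] <- 30
  J[c("M", "P", "Q"), c("M", "P", "Q")] <- 8
  J[c("M", "P", "Q"), "N"] <- 10
  J["N", "N"] <- 8
  J[lower.tri(J)] <- t(J)[lower.tri(J)]  # symmetrize from upper triangle
  cfg <- list(
    # --- geometry ---
    dims = c(150L, 150L, 200L),
    voxel_um = 4,
    # --- cellular Potts ---
    J = J,
    gamma = c(medium = 0, EC = 0.8, M = 8, P = 8, Q = 2, N = 2),
    chi = c(medium = 0, EC = -1.61e6, M = -1.50e6, P = -1.45e6, Q = 0, N = 0),
    alpha = 300,
    Tm = 10,
    adh_order = 1L,
    kappa_conc = 1e-6,           # pg/voxel -> chemotaxis concentration unit
    freeze_necrotic = TRUE,
    freeze_inactive_ec = TRUE,
    freeze_quiescent = TRUE,
    # --- transport (Table-scale physical values) ---
    D_n = 1e3, D_V = 10, D_c = 1.5e3,        # µm^2/s
    k_V = 0.9375 / 3600,                     # 1/s
    k_c = log(2) / (6 * 3600),               # 1/s (6-h half-life)
    conv_n = conv_n, conv_drug = conv_drug, cell_vox = cell_vox,
    beta_P = 5.17e-17, beta_Q = 2.41e-17, beta_N = 0,   # mol/cell/s
    s_n = 8.83e-16, kappa_P = 9.2e-18,                  # mol/cell/s
    s_d_per_dose = 5.1e-17,       # mol/cell/s per µg/m^2 (5 -> 2.55e-16)
    rho_mult = 1e4,               # drug uptake cap multiplier: under the
                                  # protocol concentrations the uptake then
                                  # operates in the linear branch, making
                                  # cumulative uptake dose-proportional
    e_uptake = 0.001,             # pg/cell/s VEGF uptake cap
    s_V_mcs = 0.035,              # pg/voxel per MCS hypoxic secretion
    n0 = 4.6,                     # initial + vessel nutrient, pg/voxel
    nsub_n = 2L, nsub_V = 2L, nsub_c = 2L,   # diffusion sub-steps per MCS
    mcs_seconds = 60, mcs_per_day = 1440L,
    # --- receptor thresholds ---
    T_RTK = 4.48e-3, T_RTK_Q = 8.96e-3,
    T_ITG = 0.3, T_cad = 0.3, T_wnt = 0.15,
    T_v = 0.00095, theta_VE = 0.65,
    # --- state-machine clocks (minutes = MCS) ---
    tau_N = 2880L, tau_clear = 7200L, tau_adh = 2880L, tau_apop = 720L,
    # --- growth schedule ---
    G_grow = 22L,                 # MCS per +1 voxel of target volume
    lag_max = 8L,                 # stop raising target this far above volume
    init_cell_vol = 64L,
    # --- chemotherapy damage thresholds (pg cumulative per cell) ---
    theta1 = 1600, theta2 = 4000,
    k_repair = log(2) / (24 * 3600),  # 1/s; damage repair half-life 1 day
    # --- scenario flags ---
    apc_on = 0L, nf1_on = 0L,
    max_cells = 8192L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration entries: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "tumor_config"
  cfg
}

#' Load a configuration from a YAML file
#'
#' Entries in the file override the defaults of [default_config()]; the `J`
#' matrix may be given as a nested list of rows.
#'
#' @param path YAML file.
#' @return A `tumor_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$J)) y$J <- matrix(unlist(y$J), 6, 6, byrow = TRUE)
  if (!is.null(y$dims)) y$dims <- as.integer(y$dims)
  do.call(default_config, y)
}

#' @export
print.tumor_config <- function(x, ...) {
  cat("tumorcpm configuration:", paste(x$dims, collapse = "x"),
      "lattice at", x$voxel_um, "µm/voxel\n")
  invisible(x)
}

# derived per-voxel rates (pg/voxel/s) from the mol-based table values
config_voxel_rates <- function(cfg) {
  list(
    beta_P_vox = cfg$beta_P * cfg$conv_n / cfg$cell_vox,
    beta_Q_vox = cfg$beta_Q * cfg$conv_n / cfg$cell_vox,
    s_n_vox = cfg$s_n * cfg$conv_n / cfg$cell_vox,
    kappa_P_vox = cfg$kappa_P * cfg$conv_drug * cfg$rho_mult / cfg$cell_vox,
    e_vox = cfg$e_uptake / cfg$cell_vox,
    drug_src_vox_per_dose = cfg$s_d_per_dose * cfg$conv_drug / cfg$cell_vox
  )
}

# flat parameter list consumed by the C++ engine
build_engine_params <- function(cfg, pheno_table = NULL, protocol = NULL,
                                days = 0) {
  vr <- config_voxel_rates(cfg)
  if (is.null(pheno_table)) pheno_table <- phenotype_table()
  sched <- protocol_schedule(protocol, days, vr$drug_src_vox_per_dose,
                             cfg$mcs_per_day)
  list(
    J = unname(cfg$J), gamma = unname(cfg$gamma), chi = unname(cfg$chi),
    alpha = cfg$alpha, Tm = cfg$Tm, kappa_conc = cfg$kappa_conc,
    adh_order = as.integer(cfg$adh_order),
    freeze_necrotic = cfg$freeze_necrotic,
    freeze_inactive_ec = cfg$freeze_inactive_ec,
    freeze_quiescent = cfg$freeze_quiescent,
    D_n = cfg$D_n, D_V = cfg$D_V, D_c = cfg$D_c, dx = cfg$voxel_um,
    k_V = cfg$k_V, k_c = cfg$k_c,
    beta_P_vox = vr$beta_P_vox, beta_Q_vox = vr$beta_Q_vox,
    s_n_vox = vr$s_n_vox, n_vessel = cfg$n0, e_vox = vr$e_vox,
    s_V_mcs = cfg$s_V_mcs, kappa_P_vox = vr$kappa_P_vox,
    nsub_n = as.integer(cfg$nsub_n), nsub_V = as.integer(cfg$nsub_V),
    nsub_c = as.integer(cfg$nsub_c),
    mcs_seconds = cfg$mcs_seconds, mcs_per_day = as.integer(cfg$mcs_per_day),
    T_RTK = cfg$T_RTK, T_RTK_Q = cfg$T_RTK_Q, T_ITG = cfg$T_ITG,
    T_cad = cfg$T_cad, T_wnt = cfg$T_wnt, T_v = cfg$T_v,
    theta_VE = cfg$theta_VE,
    tau_N = as.integer(cfg$tau_N), tau_clear = as.integer(cfg$tau_clear),
    tau_adh = as.integer(cfg$tau_adh), tau_apop = as.integer(cfg$tau_apop),
    G_grow = as.integer(cfg$G_grow), lag_max = as.integer(cfg$lag_max),
    theta1 = cfg$theta1, theta2 = cfg$theta2,
    repair_factor = exp(-cfg$k_repair * cfg$mcs_seconds),
    apc_on = as.integer(cfg$apc_on), nf1_on = as.integer(cfg$nf1_on),
    pheno_table = pheno_table,
    drug_src_mcs = sched$drug_src_mcs,
    block_mask_mcs = sched$block_mask_mcs
  )
}

# package-level cache for the phenotype lookup table
.tumorcpm_env <- new.env(parent = emptyenv())

#' Phenotype lookup table of the signalling network
#'
#' The 64-entry map from the six receptor bits to the 4-bit phenotype code,
#' computed from the shipped Boolean network (and cached). Index bit order:
#' integrin (bit 0), RTK, E-cadherin, Wnt, APC, NF1; value bit order: growth
#' (bit 3), proliferation, apoptosis, migration (bit 0).
#'
#' @param net Optionally, a `bn_network` to compute the table from.
#' @return Integer vector of length 64.
#' @export
phenotype_table <- function(net = NULL) {
  if (is.null(net) && !is.null(.tumorcpm_env$pheno_table)) {
    return(.tumorcpm_env$pheno_table)
  }
  cache <- is.null(net)
  if (is.null(net)) net <- bn_load_rules()
  m <- bn_input_output_map(net, n_seeds = 62L, seed = 1L)
  idx <- as.integer(m$Integrin) + 2L * as.integer(m$RTK) +
    4L * as.integer(m[["E-cadherin"]]) + 8L * as.integer(m$Wnt) +
    16L * as.integer(m$APC) + 32L * as.integer(m$NF1)
  bits <- do.call(rbind, lapply(strsplit(m$code, ""), as.integer))
  val <- bits[, 1] * 8L + bits[, 2] * 4L + bits[, 3] * 2L + bits[, 4]
  tab <- integer(64)
  tab[idx + 1L] <- val
  if (cache) .tumorcpm_env$pheno_table <- tab
  tab
}

# therapy schedule expanded to per-MCS engine vectors
protocol_schedule <- function(protocol, days, drug_src_per_dose,
                              mcs_per_day = 1440L) {
  n <- max(as.integer(round(days * mcs_per_day)) + 2L, 2L)
  drug_src_mcs <- numeric(n)
  block_mask_mcs <- integer(n)
  if (!is.null(protocol) && protocol$kind != "none") {
    if (protocol$kind %in% c("chemo", "combination") && protocol$dose > 0) {
      act <- dose_timeseries(protocol, n / mcs_per_day, mcs_per_day)
      drug_src_mcs[seq_along(act)] <- act * drug_src_per_dose
    }
    if (protocol$kind %in% c("targeted", "combination") &&
        length(protocol$blocked_receptors)) {
      bits <- c(Integrin = 1L, RTK = 2L, Cadherin = 4L, Wnt = 8L)
      mask <- sum(bits[protocol$blocked_receptors])
      m <- seq_len(n) - 1L
      sel <- m >= protocol$block_start * mcs_per_day &
        m < protocol$block_end * mcs_per_day
      block_mask_mcs[sel] <- mask
    }
  }
  list(drug_src_mcs = drug_src_mcs, block_mask_mcs = block_mask_mcs)
}
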