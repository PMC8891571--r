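# Reaction-diffusion fields: analytic limits, conservation, caps and the
# quasi-steady relaxation.

test_that("decay-only VEGF follows the exponential closed form", {
  cfg <- default_config(dims = c(8L, 8L, 8L), max_cells = 8L, D_V = 0)
  st <- sim_state(cfg)
  st$V_field[] <- 2.5
  st <- step_vegf(st, dt = 3600)
  expect_equal(st$V_field[1], 2.5 * exp(-0.9375), tolerance = 1e-9)
  expect_lt(max(abs(st$V_field / (2.5 * exp(-0.9375)) - 1)), 1e-6)
})

test_that("closed-domain diffusion conserves mass to machine accuracy", {
  cfg <- default_config(dims = c(10L, 10L, 10L), max_cells = 8L)
  st <- sim_state(cfg)
  set.seed(2)
  st$n_field <- runif(1000, 0, 10)
  m0 <- sum(st$n_field)
  dt <- 0.9 * cfg$voxel_um^2 / (6 * cfg$D_n)
  for (i in 1:200) st <- step_nutrient(st, dt)
  expect_lt(abs(sum(st$n_field) / m0 - 1), 1e-12)
  expect_true(all(st$n_field >= 0))
})

test_that("a uniform field with no cells is a steady state", {
  cfg <- default_config(dims = c(6L, 6L, 6L), max_cells = 8L)
  st <- sim_state(cfg)
  st$n_field[] <- 4.6
  out <- step_nutrient(st, dt = 0.001)
  expect_equal(out$n_field, st$n_field)
})

test_that("a step above the stability bound is refused with guidance", {
  cfg <- default_config(dims = c(6L, 6L, 6L), max_cells = 8L)
  st <- sim_state(cfg)
  expect_error(step_nutrient(st, dt = 1), "sub-steps")
})

test_that("tumour uptake is capped at the consumption ceiling", {
  vr <- tumorcpm:::config_voxel_rates(default_config())
  st <- box_state(c(6L, 6L, 6L), list(list(3, 3, 3)), tumorcpm:::TYPE_P,
                  cfg = default_config(dims = c(6L, 6L, 6L), max_cells = 8L,
                                       D_n = 0, n0 = 1))
  i <- tumorcpm:::voxel_index(st$dims, 3L, 3L, 3L)
  out <- step_nutrient(st, dt = 1)
  # plentiful nutrient: exactly the capped rate is consumed
  expect_equal(out$n_field[i], 1 - vr$beta_P_vox)
  # scarce nutrient: the whole voxel content is consumed, never negative
  st$n_field[i] <- vr$beta_P_vox / 4
  out2 <- step_nutrient(st, dt = 1)
  expect_equal(out2$n_field[i], 0)
})

test_that("an endothelial source voxel releases s_n per unit time", {
  cfg <- default_config(dims = c(8L, 8L, 8L), max_cells = 8L)
  st <- box_state(c(8L, 8L, 8L), list(list(4, 4, 4)), tumorcpm:::TYPE_EC,
                  cfg = cfg)
  st$n_field[] <- 0  # empty domain; the vessel cap (n0) stays above
  vr <- tumorcpm:::config_voxel_rates(cfg)
  dt <- 0.9 * cfg$voxel_um^2 / (6 * cfg$D_n)
  out <- step_nutrient(st, dt)
  expect_equal(sum(out$n_field), vr$s_n_vox * dt, tolerance = 1e-12)
  # the vessel concentration saturates at the vessel value
  res <- relax_to_quasi_steady(st, "nutrient", tol = 1e-10, max_time = 4000)
  i <- tumorcpm:::voxel_index(st$dims, 4L, 4L, 4L)
  expect_lte(res$state$n_field[i], cfg$n0 + 1e-12)
  expect_gt(res$state$n_field[i], 0)
})

test_that("VEGF stays zero without hypoxic cells and is capped at ECs", {
  cfg <- default_config(dims = c(8L, 8L, 8L), max_cells = 8L)
  st <- box_state(c(8L, 8L, 8L), list(list(2, 2, 2), list(6, 6, 6)),
                  c(tumorcpm:::TYPE_P, tumorcpm:::TYPE_EC), cfg = cfg)
  out <- step_vegf(st, dt = 0.1)
  expect_true(all(out$V_field == 0))
  # a hypoxic quiescent cell secretes; the EC voxel takes up at most e
  st$cell_type[1] <- tumorcpm:::TYPE_Q
  st$hypoxia_min[1] <- 10L
  st$V_field[] <- 1
  vr <- tumorcpm:::config_voxel_rates(cfg)
  out2 <- step_vegf(st, dt = 0.1)
  iec <- tumorcpm:::voxel_index(st$dims, 6L, 6L, 6L)
  expect_equal(out2$V_field[iec],
               1 * exp(-cfg$k_V * 0.1) - vr$e_vox * 0.1, tolerance = 1e-12)
})

test_that("drug uptake is restricted to proliferative voxels", {
  cfg <- default_config(dims = c(8L, 8L, 8L), max_cells = 8L, D_c = 0,
                        k_c = 0)
  st <- box_state(c(8L, 8L, 8L), list(list(2, 2, 2), list(4, 4, 4),
                                      list(6, 6, 6)),
                  c(tumorcpm:::TYPE_P, tumorcpm:::TYPE_Q, tumorcpm:::TYPE_N),
                  cfg = cfg)
  st$c_field[] <- 5
  out <- step_drug(st, dt = 1)
  ip <- tumorcpm:::voxel_index(st$dims, 2L, 2L, 2L)
  iq <- tumorcpm:::voxel_index(st$dims, 4L, 4L, 4L)
  inec <- tumorcpm:::voxel_index(st$dims, 6L, 6L, 6L)
  expect_lt(out$c_field[ip], 5)       # proliferating voxel consumes
  expect_equal(out$c_field[iq], 5)    # quiescent does not
  expect_equal(out$c_field[inec], 5)  # necrotic does not
  # without infusion and with no drug present the field stays zero
  st$c_field[] <- 0
  expect_true(all(step_drug(st, dt = 1)$c_field == 0))
})

test_that("point release relaxes to the 3D Gaussian kernel", {
  nvox <- 64L
  cfg <- default_config(dims = c(nvox, nvox, nvox), max_cells = 8L, n0 = 0)
  st <- sim_state(cfg)
  ctr <- c(32L, 32L, 32L)
  i0 <- tumorcpm:::voxel_index(st$dims, ctr[1], ctr[2], ctr[3])
  f <- numeric(prod(st$dims)); f[i0] <- 1
  D <- cfg$D_V  # slow field keeps the step count modest
  dt <- 0.9 * cfg$voxel_um^2 / (6 * D)
  sigma_vox <- 8
  t_end <- (sigma_vox * cfg$voxel_um)^2 / (2 * D)
  nstep <- ceiling(t_end / dt)
  zero <- numeric(0)
  for (i in seq_len(nstep)) {
    f <- tumorcpm:::cpp_rd_step(f, st$dims, D, t_end / nstep, cfg$voxel_um,
                                zero, zero, 0, zero)
  }
  xyz <- tumorcpm:::voxel_coords(st$dims, seq_len(prod(st$dims)))
  r2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
  s2 <- sigma_vox^2
  kern <- exp(-r2 / (2 * s2)) / (2 * pi * s2)^(3 / 2)
  kern <- kern / sum(kern)
  expect_lt(sum(abs(f - kern)), 0.02)  # L1 error within 2%
})

test_that("quasi-steady relaxation converges and is idempotent", {
  cfg <- default_config(dims = c(12L, 4L, 4L), max_cells = 8L)
  st <- sim_state(cfg)
  r1 <- relax_to_quasi_steady(st, "nutrient", tol = 1e-6)
  expect_true(r1$converged)
  expect_lte(r1$steps, 2)  # uniform no-cell field is already steady
})

test_that("the rod fixture reaches the linear two-plate steady profile", {
  st <- make_fixture("rod100")
  cfg <- st$config
  # vessel plate: EC cell at the left end; absorbing tumour slab at the
  # right end with a deliberately large uptake ceiling
  st <- tumorcpm:::add_cell(st, tumorcpm:::voxel_index(st$dims, 1:3, 1L, 1L),
                            tumorcpm:::TYPE_EC, init_vol = 3L)
  st <- tumorcpm:::add_cell(st, tumorcpm:::voxel_index(st$dims, 85:100, 1L, 1L),
                            tumorcpm:::TYPE_P, init_vol = 16L)
  st$config$beta_P <- 1e-12  # strong absorber
  st$config$s_n <- 1e-12     # vessel release strong enough to hold n0
  st$n_field[] <- 0
  res <- relax_to_quasi_steady(st, "nutrient", tol = 1e-9, max_time = 3000)
  prof <- res$state$n_field
  gap <- 4:84
  line <- prof[4] + (prof[84] - prof[4]) * (gap - 4) / 80
  expect_lt(max(abs(prof[gap] - line)), 0.01 * cfg$n0)
  expect_lt(prof[95], 0.05 * cfg$n0)   # absorbed inside the slab
  expect_gt(prof[2], 0.9 * cfg$n0)     # held near the vessel value
})

test_that("fields remain non-negative under random dynamics", {
  set.seed(14)
  for (rep in 1:10) {
    st <- random_state(dims = c(6L, 6L, 6L), k = 3L)
    st$n_field <- runif(216, 0, 5)
    st$V_field <- runif(216, 0, 0.01)
    st$c_field <- runif(216, 0, 2)
    st$hypoxia_min[1:3] <- sample(0:10, 3)
    for (i in 1:5) {
      st <- step_nutrient(st, dt = 0.002)
      st <- step_vegf(st, dt = 0.2)
      st <- step_drug(st, dt = 0.001)
    }
    expect_true(all(st$n_field >= 0) && all(st$V_field >= 0) &&
                  all(st$c_field >= 0))
  }
})

test_that("halving the relaxation tolerance leaves receptor states alone", {
  st <- make_fixture("spheroid50", seed = 4)
  a <- relax_to_quasi_steady(st, "nutrient", tol = 1e-6)$state
  b <- relax_to_quasi_steady(st, "nutrient", tol = 5e-7)$state
  ra <- receptor_inputs(a)
  rb <- receptor_inputs(b)
  expect_identical(ra[c("Integrin", "RTK", "Cadherin", "Wnt")],
                   rb[c("Integrin", "RTK", "Cadherin", "Wnt")])
})
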