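# Coupling layer: receptor inputs from geometry and fields, phenotype
# application, the viability state machine, endothelial activation and
# VE-cadherin contact inhibition.

test_that("receptor inputs follow the contact-fraction thresholds", {
  # an isolated cell fully embedded in ECM
  st <- box_state(c(8L, 8L, 8L), list(list(3:4, 3:4, 3:4)),
                  tumorcpm:::TYPE_P, n0 = 4.6)
  ri <- receptor_inputs(st)
  expect_true(ri$Integrin[1])        # full ECM contact
  expect_false(ri$Cadherin[1])       # no cell-cell junctions
  expect_true(ri$Wnt[1])             # cadherin loss de-represses Wnt
  expect_true(ri$RTK[1])             # nutrient-rich
  # the interior cell of a compact block contacts only other viable cells
  boxes <- list()
  types <- integer(0)
  for (x in 0:2) for (y in 0:2) for (z in 0:2) {
    boxes[[length(boxes) + 1]] <- list(2:3 + 2 * x, 2:3 + 2 * y, 2:3 + 2 * z)
    types <- c(types, tumorcpm:::TYPE_P)
  }
  st2 <- box_state(c(10L, 10L, 10L), boxes, types, n0 = 4.6)
  ri2 <- receptor_inputs(st2)
  centre <- which(ri2$contact_viable == 1)
  expect_true(length(centre) >= 1)
  expect_true(all(ri2$Cadherin[centre]))
  expect_false(any(ri2$Integrin[centre]))
  # starving the lattice silences RTK
  st$n_field[] <- 0
  expect_false(receptor_inputs(st)$RTK[1])
})

test_that("receptor inputs are a pure, idempotent function of the state", {
  st <- make_fixture("spheroid50", seed = 9)
  a <- receptor_inputs(st)
  b <- receptor_inputs(st)
  expect_identical(a, b)
})

test_that("raising T_RTK can only decrease the RTK-on census", {
  st <- make_fixture("spheroid50", seed = 10)
  set.seed(1)
  st$n_field <- st$n_field * runif(length(st$n_field), 0, 2e-3)
  counts <- vapply(c(1e-4, 1e-3, 4.48e-3, 1e-2), function(thr) {
    st$config$T_RTK <- thr
    sum(receptor_inputs(st)$RTK)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("phenotype codes map onto the documented cell behaviours", {
  cfg <- default_config()
  p1100 <- apply_phenotype("1100", cfg)
  expect_true(p1100$grow && p1100$proliferate)
  expect_equal(p1100$cell_type, tumorcpm:::TYPE_P)
  expect_equal(p1100$chi, 0)
  p1101 <- apply_phenotype("1101", cfg)
  expect_equal(p1101$cell_type, tumorcpm:::TYPE_M)
  expect_equal(p1101$chi, -1.5e6)
  for (code in c("0010", "0011")) {
    p <- apply_phenotype(code, cfg)
    expect_true(p$apoptosis)
    expect_false(p$grow)
  }
  expect_error(apply_phenotype("1111", cfg), "not reachable")
})

test_that("the viability machine implements hysteresis and necrosis", {
  cfg <- default_config()
  # nutrient just above the baseline threshold is not enough to wake a
  # quiescent cell (hysteresis)
  r <- update_viability_state(tumorcpm:::TYPE_Q, 5e-3, cfg = cfg)
  expect_equal(r$type, tumorcpm:::TYPE_Q)
  # above the quiescent threshold the cell resumes proliferation
  r2 <- update_viability_state(tumorcpm:::TYPE_Q, 1e-2, cfg = cfg)
  expect_equal(r2$type, tumorcpm:::TYPE_P)
  expect_equal(r2$hypoxia_min, 0L)
  # a proliferating cell starves into quiescence below T_RTK
  r3 <- update_viability_state(tumorcpm:::TYPE_P, 1e-3, cfg = cfg)
  expect_equal(r3$type, tumorcpm:::TYPE_Q)
  # prolonged hypoxia becomes necrosis
  r4 <- update_viability_state(tumorcpm:::TYPE_Q, 0,
                               hypoxia_min = cfg$tau_N - 1L, cfg = cfg)
  expect_equal(r4$type, tumorcpm:::TYPE_N)
  # necrosis is absorbing until clearance
  r5 <- update_viability_state(tumorcpm:::TYPE_N, 10, necro_min = 5L,
                               cfg = cfg)
  expect_equal(r5$type, tumorcpm:::TYPE_N)
  r6 <- update_viability_state(tumorcpm:::TYPE_N, 10,
                               necro_min = cfg$tau_clear - 1L, cfg = cfg)
  expect_equal(r6$type, 0L)
})

test_that("endothelial cells activate on the VEGF threshold", {
  cfg <- default_config(dims = c(8L, 8L, 8L), max_cells = 8L)
  st <- box_state(c(8L, 8L, 8L), list(list(2:3, 2:3, 2:3)),
                  tumorcpm:::TYPE_EC, cfg = cfg)
  expect_length(ec_activation(st), 0)      # V = 0 everywhere
  st$V_field[] <- cfg$T_v * 1.5
  newly <- ec_activation(st)
  expect_equal(as.integer(newly), 1L)
  st2 <- attr(newly, "state")
  expect_equal(st2$ec_active[1], 1L)
})

test_that("an activated EC shows no net drift in a uniform VEGF field", {
  set.seed(77)
  drift <- replicate(3, {
    cfg <- default_config(dims = c(20L, 8L, 8L), max_cells = 8L, n0 = 0)
    cfg$gamma["EC"] <- 8  # stiffen the isolated cell; the test probes drift
    st <- sim_state(cfg)
    st <- tumorcpm:::add_cell(st, as.vector(outer(
      outer(9:11, (3:5 - 1) * 20, "+"), (3:5 - 1) * 160, "+")),
      tumorcpm:::TYPE_EC, tvol = 27, init_vol = 27L, ec_active = TRUE)
    st$V_field[] <- 0.01  # uniform: zero gradient
    out <- monte_carlo_step(st, n_mcs = 500)
    mean(tumorcpm:::voxel_coords(st$dims, which(out$owner == 1L))[, 1]) - 10
  })
  expect_lt(max(abs(drift)), 4)
})

test_that("VE-cadherin junction coverage gates endothelial proliferation", {
  # an EC completely walled in by other ECs is contact-inhibited
  boxes <- list(list(3:4, 3:4, 3:4))
  types <- tumorcpm:::TYPE_EC
  for (d in list(c(-2, 0, 0), c(2, 0, 0), c(0, -2, 0), c(0, 2, 0),
                 c(0, 0, -2), c(0, 0, 2))) {
    boxes[[length(boxes) + 1]] <- list(3:4 + d[1], 3:4 + d[2], 3:4 + d[3])
    types <- c(types, tumorcpm:::TYPE_EC)
  }
  st <- box_state(c(8L, 8L, 8L), boxes, types)
  st$ec_active[1:7] <- 1L
  expect_false(ve_cadherin_inhibition(st, 1))
  # a tip cell with a single EC neighbour keeps proliferating
  st2 <- box_state(c(10L, 6L, 6L), list(list(2:3, 2:3, 2:3),
                                        list(4:5, 2:3, 2:3)),
                   c(tumorcpm:::TYPE_EC, tumorcpm:::TYPE_EC))
  st2$ec_active[1:2] <- 1L
  expect_true(ve_cadherin_inhibition(st2, 2))
  # theta_VE = 1 disables contact inhibition entirely
  expect_true(ve_cadherin_inhibition(st, 1, theta_VE = 1.0))
})

test_that("rim cells stay proliferative while the core falls quiescent", {
  # small closed avascular spheroid: the interior depletes first
  cfg <- default_config(dims = c(26L, 26L, 26L), max_cells = 1024L,
                        tau_adh = 0L)
  set.seed(33)
  st <- build_initial_tumor(cfg, diameter_um = 40)
  st$competent[seq_len(st$ncell)] <- 1L
  r <- run_simulation(st, days = 5, seed = 21)
  tr <- r$trace
  # pick the most balanced mixed day, when the depletion gradient has
  # actually developed (the very first quiescent flips are threshold noise)
  mixed <- pmin(tr$n_Q, tr$n_P)
  expect_gt(max(mixed), 0)  # a mixed rim/core day must occur before arrest
  i <- which.max(mixed)
  # re-run to that day and compare radii of P vs Q cells
  r2 <- run_simulation(st, days = tr$day[i], seed = 21)
  s <- r2$state
  ctr <- (s$dims + 1) / 2
  rad <- function(ids) {
    vapply(ids, function(id) {
      co <- tumorcpm:::voxel_coords(s$dims, which(s$owner == id))
      sqrt(sum((colMeans(co) - ctr)^2))
    }, numeric(1))
  }
  ids <- seq_len(s$ncell)
  pr <- rad(ids[s$cell_type[ids] == tumorcpm:::TYPE_P])
  qr <- rad(ids[s$cell_type[ids] == tumorcpm:::TYPE_Q])
  expect_gt(mean(pr), mean(qr))
})
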