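# Cellular Potts core: energy terms against hand counts, incremental delta-H
# against the brute-force Hamiltonian, Metropolis statistics, sweeps and
# division bookkeeping.

test_that("adhesion energy matches hand-counted contact sums", {
  # a single 1-voxel proliferating cell exposes 6 faces to ECM
  st <- box_state(c(4L, 4L, 4L), list(list(2, 2, 2)), tumorcpm:::TYPE_P)
  expect_equal(adhesion_energy(st), 6 * 12)
  # two adjacent 1-voxel P cells: one P-P bond plus 10 P-ECM faces
  st2 <- box_state(c(4L, 4L, 4L), list(list(2, 2, 2), list(3, 2, 2)),
                   c(tumorcpm:::TYPE_P, tumorcpm:::TYPE_P))
  expect_equal(adhesion_energy(st2), 8 + 10 * 12)
  # one cell filling the whole lattice: no boundary pairs at all
  st3 <- box_state(c(3L, 3L, 3L), list(list(1:3, 1:3, 1:3)),
                   tumorcpm:::TYPE_P)
  expect_equal(adhesion_energy(st3), 0)
  # second-order neighbourhood adds the 12 edge-diagonal contacts
  expect_equal(adhesion_energy(st, order = 2), 6 * 12 + 12 * 12)
})

test_that("growth energy is the elastic volume deviation", {
  st <- box_state(c(6L, 6L, 6L), list(list(1:5, 1:4, 1:3)),
                  tumorcpm:::TYPE_P)  # 60 voxels
  st$tvol[1] <- 64
  expect_equal(growth_energy(st), 8 * 16)   # proliferating elasticity 8
  st$cell_type[1] <- tumorcpm:::TYPE_Q
  expect_equal(growth_energy(st), 2 * 16)   # quiescent elasticity 2
  st$tvol[1] <- 60
  expect_equal(growth_energy(st), 0)
})

test_that("continuity energy charges alpha per fragmented cell", {
  st <- box_state(c(8L, 4L, 4L), list(list(1:2, 1:2, 1:2)),
                  tumorcpm:::TYPE_P)
  expect_equal(continuity_energy(st), 0)
  # teleport one voxel away from the cell: one fragmented cell
  st$owner[tumorcpm:::voxel_index(st$dims, 7L, 3L, 3L)] <- 1L
  st$volume[1] <- st$volume[1] + 1L
  expect_equal(continuity_energy(st), 300)
  # a second split cell doubles the penalty
  st <- tumorcpm:::add_cell(st, tumorcpm:::voxel_index(st$dims, 5L, 1L, 1L),
                            tumorcpm:::TYPE_P)
  st$owner[tumorcpm:::voxel_index(st$dims, 5L, 4L, 4L)] <- 2L
  st$volume[2] <- 2L
  expect_equal(continuity_energy(st), 600)
})

test_that("chemotaxis contribution is chi times the concentration step", {
  expect_equal(chemotaxis_delta(0.5, 0.5, -1e6), 0)
  # the endothelial sensitivity drives a -1.61 gain for a 1e-6 uphill step
  expect_equal(chemotaxis_delta(0, 1e-6, -1.61e6), -1.61)
  expect_error(chemotaxis_delta(0, 1, 5), "negative")
})

test_that("incremental delta-H equals the brute-force Hamiltonian change", {
  set.seed(202)
  checked <- 0
  for (rep in 1:12) {
    st <- random_state(dims = c(6L, 6L, 6L), k = 4L)
    params <- tumorcpm:::build_engine_params(st$config)
    H1 <- oracle_hamiltonian(st)
    for (tr in 1:60) {
      site <- sample.int(prod(st$dims), 1)
      nbs <- tumorcpm:::face_neighbors(st$dims, site)
      src <- nbs[sample.int(length(nbs), 1)]
      if (st$owner[site] == st$owner[src]) next
      dh <- delta_hamiltonian(st, site, src, params)
      H2 <- oracle_hamiltonian(apply_copy_r(st, site, src))
      expect_lt(abs(dh[["total"]] - (H2 - H1)), 1e-9)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 200)
  # a null copy (same owner) has exactly zero energy change
  st <- box_state(c(4L, 4L, 4L), list(list(2:3, 2:3, 2:3)),
                  tumorcpm:::TYPE_P)
  i1 <- tumorcpm:::voxel_index(st$dims, 2L, 2L, 2L)
  i2 <- tumorcpm:::voxel_index(st$dims, 3L, 2L, 2L)
  expect_equal(delta_hamiltonian(st, i1, i2)[["total"]], 0)
})

test_that("delta-H reduces to the volume term when adhesion is silenced", {
  st <- box_state(c(4L, 2L, 2L), list(list(1:2, 1:2, 1:2),
                                      list(3:4, 1:2, 1:2)),
                  c(tumorcpm:::TYPE_P, tumorcpm:::TYPE_P))
  st$config$J[, ] <- 0  # isolate the elastic volume term
  site <- tumorcpm:::voxel_index(st$dims, 2L, 1L, 1L)
  src <- tumorcpm:::voxel_index(st$dims, 3L, 1L, 1L)
  dh <- delta_hamiltonian(st, site, src)
  ga <- 8
  expected <- ga * ((7 - 8)^2 - 0) + ga * ((9 - 8)^2 - 0)
  expect_equal(dh[["growth"]], expected)
  expect_equal(dh[["chemotaxis"]], 0)
})

test_that("Metropolis acceptance follows the Boltzmann probability", {
  set.seed(7)
  # energy-lowering changes always pass
  expect_true(all(metropolis_accept(rep(-5, 100), Tm = 10)))
  # at dH = Tm the acceptance frequency is e^-1 within +-0.01
  acc <- metropolis_accept(rep(10, 1e5), Tm = 10)
  expect_lt(abs(mean(acc) - exp(-1)), 0.01)
  # immense barriers are never crossed
  expect_false(any(metropolis_accept(rep(1e4, 1e4), Tm = 10)))
})

test_that("a lattice with only uphill moves freezes at low temperature", {
  st <- box_state(c(8L, 8L, 8L), list(list(3:6, 3:6, 3:6)),
                  tumorcpm:::TYPE_P)   # cubic cell at its target volume
  st$config$Tm <- 1e-9
  set.seed(12)
  out <- monte_carlo_step(st, n_mcs = 3)
  expect_identical(out$owner, st$owner)
  expect_equal(out$clock_mcs, 3L)
})

test_that("sweeps conserve the registry/lattice volume audit", {
  set.seed(31)
  for (rep in 1:5) {
    st <- random_state(dims = c(6L, 6L, 6L), k = 3L, scatter = 0)
    out <- monte_carlo_step(st, n_mcs = 5)
    expect_true(tumorcpm:::audit_volumes(out))
    expect_equal(sum(out$volume[seq_len(out$ncell)]), sum(out$owner != 0L))
  }
})

test_that("a motile cell drifts up a chemoattractant gradient", {
  set.seed(91)
  disp <- replicate(8, {
    cfg <- default_config(dims = c(24L, 8L, 8L), max_cells = 8L, n0 = 0)
    st <- sim_state(cfg)
    st <- tumorcpm:::add_cell(st, as.vector(outer(
      outer(4:5, (3:4 - 1) * 24, "+"), (3:4 - 1) * 24 * 8, "+")),
      tumorcpm:::TYPE_M, tvol = 8, init_vol = 8L)
    xs <- tumorcpm:::voxel_coords(st$dims, seq_len(prod(st$dims)))[, 1]
    st$n_field <- xs * 10  # strong linear gradient along x
    out <- monte_carlo_step(st, n_mcs = 400)
    mean(tumorcpm:::voxel_coords(st$dims, which(out$owner == 1L))[, 1]) -
      mean(tumorcpm:::voxel_coords(st$dims, which(st$owner == 1L))[, 1])
  })
  expect_true(all(disp > 0))
})

test_that("division splits doubled cells into balanced daughters", {
  st <- box_state(c(12L, 6L, 6L), list(list(2:9, 2:5, 2:5)),
                  tumorcpm:::TYPE_P)  # 128 voxels
  st$init_vol[1] <- 64L
  set.seed(5)
  out <- grow_and_divide(st)
  expect_equal(out$ncell, 2L)
  v <- out$volume[1:2]
  expect_equal(sum(v), 128L)
  expect_lte(abs(v[1] - v[2]), 2L)
  expect_equal(out$cell_type[2], tumorcpm:::TYPE_P)
  expect_equal(out$tvol[1:2], c(64, 64))
  expect_equal(out$births, 1)
  expect_true(tumorcpm:::audit_volumes(out))
  # a cell below the doubling volume is left alone
  st2 <- box_state(c(8L, 6L, 6L), list(list(2:5, 2:5, 2:3)),
                   tumorcpm:::TYPE_P)
  st2$init_vol[1] <- 64L
  expect_equal(grow_and_divide(st2)$ncell, 1L)
  # a 1-voxel cell defers division
  st3 <- box_state(c(4L, 4L, 4L), list(list(2, 2, 2)), tumorcpm:::TYPE_P)
  st3$init_vol[1] <- 0L
  expect_equal(grow_and_divide(st3)$ncell, 1L)
})
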