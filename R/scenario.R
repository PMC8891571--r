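# Synthetic scenario generation: empty lattices, the initial tumour sphere,
# the pre-existing vessel plexus, and the registered test fixtures.

#' Create an empty simulation state
#'
#' The state is a plain list: the voxel lattice (`owner`, 0 = ECM), parallel
#' per-cell registries (type, volume, target volume, clocks, drug uptake),
#' the three concentration fields, and run counters.
#'
#' @param cfg A `tumor_config`.
#' @return List of class `sim_state`.
#' @export
sim_state <- function(cfg = default_config()) {
  n <- prod(cfg$dims)
  mc <- cfg$max_cells
  st <- list(
    dims = as.integer(cfg$dims), voxel_um = cfg$voxel_um,
    owner = integer(n),
    cell_type = integer(mc), volume = integer(mc), init_vol = integer(mc),
    competent = integer(mc), settle_min = integer(mc),
    hypoxia_min = integer(mc), necro_min = integer(mc),
    apop_min = rep(-1L, mc), ec_active = integer(mc), drug_q = integer(mc),
    grow_acc = integer(mc), apop_by_block = integer(mc),
    tvol = numeric(mc), cum_drug = numeric(mc),
    n_field = rep(cfg$n0, n), V_field = numeric(n), c_field = numeric(n),
    ncell = 0L, clock_mcs = 0L,
    births = 0, deaths_apop = 0, drug_necro = 0, killed_therapy = 0,
    stopped = FALSE, config = cfg
  )
  class(st) <- "sim_state"
  st
}

#' @export
print.sim_state <- function(x, ...) {
  alive <- x$cell_type[seq_len(x$ncell)] != 0L
  cat("sim_state:", paste(x$dims, collapse = "x"), "lattice,",
      sum(alive), "cells,", sum(x$owner != 0L), "occupied voxels, t =",
      x$clock_mcs, "MCS\n")
  invisible(x)
}

voxel_index <- function(dims, x, y, z) {
  1L + (x - 1L) + dims[1] * ((y - 1L) + dims[2] * (z - 1L))
}

voxel_coords <- function(dims, i) {
  i0 <- i - 1L
  cbind(x = i0 %% dims[1] + 1L,
        y = (i0 %/% dims[1]) %% dims[2] + 1L,
        z = i0 %/% (dims[1] * dims[2]) + 1L)
}

# register one cell occupying `vox` (lattice indices); returns new id
add_cell <- function(st, vox, type, tvol = length(vox),
                     init_vol = st$config$init_cell_vol, competent = FALSE,
                     ec_active = FALSE) {
  id <- st$ncell + 1L
  if (id > length(st$cell_type)) stop("max_cells capacity exceeded")
  if (any(st$owner[vox] != 0L)) stop("voxels already occupied")
  st$owner[vox] <- id
  st$cell_type[id] <- as.integer(type)
  st$volume[id] <- length(vox)
  st$tvol[id] <- tvol
  st$init_vol[id] <- as.integer(init_vol)
  st$competent[id] <- as.integer(competent)
  st$apop_min[id] <- -1L
  st$ec_active[id] <- as.integer(ec_active)
  st$ncell <- id
  st
}

#' Build the initial tumour sphere
#'
#' Places a centred sphere of proliferating tumour cells, tiled by a seeded
#' Voronoi partition into cells of roughly the nominal 64-voxel volume.
#' Stray Voronoi fragments are re-attached to a face-adjacent neighbour so
#' every generated cell is face-connected.
#'
#' @param cfg A `tumor_config`.
#' @param diameter_um Tumour diameter (default 65 µm).
#' @param st Optional existing state to place the tumour into.
#' @return A `sim_state` with the tumour added.
#' @export
build_initial_tumor <- function(cfg = default_config(), diameter_um = 65,
                                st = NULL) {
  if (is.null(st)) st <- sim_state(cfg)
  r_vox <- diameter_um / 2 / cfg$voxel_um
  if (2 * r_vox < 1) stop("tumour diameter smaller than one voxel")
  ctr <- (st$dims + 1) / 2
  if (any(r_vox + 2 > st$dims / 2)) stop("tumour does not fit inside domain")
  n <- prod(st$dims)
  xyz <- voxel_coords(st$dims, seq_len(n))
  d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
  sphere <- which(d2 <= r_vox^2)
  if (length(sphere) < 1) stop("tumour diameter smaller than one voxel")
  k <- max(1L, as.integer(round(length(sphere) / cfg$init_cell_vol)))
  seeds <- sphere[sample.int(length(sphere), k)]
  sc <- voxel_coords(st$dims, seeds)
  pc <- xyz[sphere, , drop = FALSE]
  # nearest seed (squared Euclidean); ties resolved to the lowest seed index
  assign <- integer(length(sphere))
  best <- rep(Inf, length(sphere))
  for (j in seq_len(k)) {
    dj <- (pc[, 1] - sc[j, 1])^2 + (pc[, 2] - sc[j, 2])^2 +
      (pc[, 3] - sc[j, 3])^2
    better <- dj < best
    assign[better] <- j
    best[better] <- dj[better]
  }
  base_id <- st$ncell
  for (j in seq_len(k)) {
    vox <- sphere[assign == j]
    if (!length(vox)) next
    st <- add_cell(st, vox, TYPE_P, tvol = length(vox))
  }
  st <- repair_connectivity(st, (base_id + 1L):st$ncell)
  st
}

# reattach non-principal components of each listed cell to a face-adjacent
# neighbouring cell (or to its own principal component's owner)
repair_connectivity <- function(st, ids) {
  for (pass in 1:5) {
    comp <- cpp_cell_components(st$owner, st$dims, st$ncell)
    bad <- ids[comp[ids] > 1L]
    if (!length(bad)) break
    for (id in bad) {
      vox <- which(st$owner == id)
      lab <- label_components(st$dims, vox)
      main <- which.max(tabulate(lab))
      stray <- vox[lab != main]
      for (v in stray) {
        nb <- face_neighbors(st$dims, v)
        cand <- setdiff(unique(st$owner[nb]), c(0L, id))
        new_owner <- if (length(cand)) cand[1] else 0L
        st$owner[v] <- new_owner
        st$volume[id] <- st$volume[id] - 1L
        if (new_owner > 0L) st$volume[new_owner] <- st$volume[new_owner] + 1L
      }
      st$tvol[id] <- st$volume[id]
      if (length(cand <- which(st$owner == id)) == 0L) st$cell_type[id] <- 0L
    }
  }
  st
}

face_neighbors <- function(dims, i) {
  co <- voxel_coords(dims, i)
  out <- integer(0)
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    p <- co + d
    if (all(p >= 1) && all(p <= dims)) {
      out <- c(out, voxel_index(dims, p[1], p[2], p[3]))
    }
  }
  out
}

# face-connected component labels of a voxel set (R-side, used by the
# scenario repair; the test-suite oracle uses igraph independently)
label_components <- function(dims, vox) {
  lab <- integer(length(vox))
  key <- match(seq_len(prod(dims)), vox)
  cur <- 0L
  for (s in seq_along(vox)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (nb in face_neighbors(dims, vox[v])) {
        j <- key[nb]
        if (!is.na(j) && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  lab
}

#' Build the pre-existing vessel plexus
#'
#' Lays straight parallel vessels of quiescent endothelial cells on two
#' planes near opposite domain faces. Each vessel runs along the y axis with
#' a 2x2-voxel cross-section and is segmented into 16-voxel-long EC cells
#' (64 voxels each). Vessels must not intersect the initial tumour.
#'
#' @param st A `sim_state` (typically already holding the tumour).
#' @param spacing_um Spacing between vessels within a plane (default 200).
#' @param margin_vox Distance of the vessel planes from the domain faces.
#' @return The state with EC cells added.
#' @export
build_vessel_plexus <- function(st, spacing_um = 200, margin_vox = 2L) {
  cfg <- st$config
  spacing_vox <- max(1L, as.integer(round(spacing_um / cfg$voxel_um)))
  if (spacing_vox < 3L) stop("vessel spacing smaller than vessel diameter")
  dims <- st$dims
  xs <- c(margin_vox, dims[1] - margin_vox - 1L)
  if (spacing_vox > dims[3]) return(st)  # spacing beyond domain: no vessels
  zs <- seq(margin_vox + 1L, dims[3] - 2L, by = spacing_vox)
  if (!length(zs)) return(st)
  seg_len <- 16L
  for (x0 in xs) {
    for (z0 in zs) {
      y <- 1L
      while (y + seg_len - 1L <= dims[2]) {
        vox <- integer(0)
        for (dx in 0:1) for (dz in 0:1) {
          yy <- y:(y + seg_len - 1L)
          vox <- c(vox, voxel_index(dims, rep(x0 + dx, seg_len), yy,
                                    rep(z0 + dz, seg_len)))
        }
        if (any(st$owner[vox] != 0L)) {
          stop("vessel would intersect an existing cell; ",
               "enlarge the margin or the domain")
        }
        st <- add_cell(st, vox, TYPE_EC, tvol = length(vox),
                       init_vol = length(vox), competent = TRUE)
        y <- y + seg_len
      }
    }
  }
  st
}

#' Deterministic small scenarios for tests and oracles
#'
#' Registered fixtures:
#' \describe{
#'   \item{toy6}{6^3 lattice with two 8-voxel tumour cells, fields zero.}
#'   \item{rod100}{100x1x1 rod for one-dimensional transport checks.}
#'   \item{spheroid50}{50^3 lattice with a 65-µm avascular tumour.}
#'   \item{vascular80}{80^3 lattice, 65-µm tumour, two vessel planes.}
#'   \item{vascular32}{compact 32^3 therapy fixture: 32-µm tumour between
#'     two vessel planes, junction-maturation lag disabled.}
#' }
#'
#' @param name Fixture name.
#' @param seed RNG seed used for the scenario's random choices.
#' @return A `sim_state`.
#' @export
make_fixture <- function(name, seed = 1L) {
  old <- bn_set_seed(seed)
  on.exit(bn_restore_seed(old), add = TRUE)
  switch(name,
    toy6 = {
      cfg <- default_config(dims = c(6L, 6L, 6L), max_cells = 64L, n0 = 0)
      st <- sim_state(cfg)
      st$n_field[] <- 0
      b1 <- as.vector(outer(outer(2:3, (2:3 - 1) * 6, "+"), (2:3 - 1) * 36, "+"))
      b2 <- as.vector(outer(outer(4:5, (4:5 - 1) * 6, "+"), (4:5 - 1) * 36, "+"))
      st <- add_cell(st, b1, TYPE_P, tvol = 8, init_vol = 8L)
      st <- add_cell(st, b2, TYPE_P, tvol = 8, init_vol = 8L)
      st
    },
    rod100 = {
      cfg <- default_config(dims = c(100L, 1L, 1L), max_cells = 16L)
      sim_state(cfg)
    },
    spheroid50 = {
      cfg <- default_config(dims = c(50L, 50L, 50L), max_cells = 4096L)
      build_initial_tumor(cfg, diameter_um = 65)
    },
    vascular80 = {
      cfg <- default_config(dims = c(80L, 80L, 80L), max_cells = 8192L)
      st <- build_initial_tumor(cfg, diameter_um = 65)
      build_vessel_plexus(st, spacing_um = 120, margin_vox = 3L)
    },
    vascular32 = {
      cfg <- default_config(dims = c(32L, 32L, 32L), max_cells = 4096L,
                            tau_adh = 0L)
      st <- build_initial_tumor(cfg, diameter_um = 32)
      st$competent[seq_len(st$ncell)] <- 1L  # pre-aggregated tumour
      build_vessel_plexus(st, spacing_um = 48, margin_vox = 1L)
    },
    stop("unknown fixture '", name, "'; registered: toy6, rod100, ",
         "spheroid50, vascular80, vascular32", call. = FALSE)
  )
}

# registry/site audit: per-cell registered volumes against the lattice
audit_volumes <- function(st) {
  tab <- tabulate(st$owner, nbins = st$ncell)
  live <- seq_len(st$ncell)
  all(tab == st$volume[live])
}
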