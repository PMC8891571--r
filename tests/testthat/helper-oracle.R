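# Shared helpers: brute-force Hamiltonian oracle (independent of the
# engine's incremental path) and random small-lattice states.

# independent connected-component count per cell using igraph
oracle_components <- function(st) {
  vapply(seq_len(st$ncell), function(id) {
    vox <- which(st$owner == id)
    if (!length(vox)) return(0L)
    co <- tumorcpm:::voxel_coords(st$dims, vox)
    edges <- integer(0)
    for (a in seq_along(vox)) {
      d <- abs(co[, 1] - co[a, 1]) + abs(co[, 2] - co[a, 2]) +
        abs(co[, 3] - co[a, 3])
      nb <- which(d == 1L & seq_along(vox) > a)
      if (length(nb)) edges <- c(edges, rbind(a, nb))
    }
    g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    as.integer(igraph::components(g)$no)
  }, integer(1))
}

# brute-force total Hamiltonian (adhesion + growth + continuity; chemotaxis
# is exercised separately because the copy convention is path-dependent)
oracle_hamiltonian <- function(st) {
  cfg <- st$config
  # adhesion by explicit pair enumeration
  dims <- st$dims
  n <- prod(dims)
  e_adh <- 0
  offs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  if (cfg$adh_order == 2) {
    offs <- c(offs, list(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                         c(0, 1, 1), c(0, 1, -1)))
  }
  co <- tumorcpm:::voxel_coords(dims, seq_len(n))
  type_of <- function(o) ifelse(o > 0L, st$cell_type[pmax(o, 1L)], 0L)
  for (off in offs) {
    x2 <- co[, 1] + off[1]; y2 <- co[, 2] + off[2]; z2 <- co[, 3] + off[3]
    ok <- x2 >= 1 & x2 <= dims[1] & y2 >= 1 & y2 <= dims[2] &
      z2 >= 1 & z2 <= dims[3]
    j <- tumorcpm:::voxel_index(dims, x2[ok], y2[ok], z2[ok])
    i <- which(ok)
    diff <- st$owner[i] != st$owner[j]
    ti <- type_of(st$owner[i][diff]) + 1L
    tj <- type_of(st$owner[j][diff]) + 1L
    e_adh <- e_adh + sum(unname(cfg$J)[cbind(ti, tj)])
  }
  live <- which(st$cell_type[seq_len(st$ncell)] != 0L)
  ga <- unname(cfg$gamma)[st$cell_type[live] + 1L]
  e_vol <- sum(ga * (st$volume[live] - st$tvol[live])^2)
  comp <- oracle_components(st)
  e_cont <- cfg$alpha * sum(comp[live] > 1L & st$volume[live] > 0L)
  e_adh + e_vol + e_cont
}

# random occupancy on a small lattice: k blobby-ish cells grown from seeds,
# plus optional random scatter to create fragmented cells
random_state <- function(dims = c(6L, 6L, 6L), k = 4L, scatter = 0.05,
                         cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- default_config(dims = as.integer(dims), max_cells = 64L, n0 = 0)
  }
  st <- sim_state(cfg)
  st$n_field[] <- 0
  n <- prod(dims)
  owner <- integer(n)
  seeds <- sample.int(n, k)
  owner[seeds] <- seq_len(k)
  frontier <- as.list(seeds)
  for (step in seq_len(5L * n)) {
    grow <- sample.int(k, 1)
    vox <- which(owner == grow)
    nbs <- unlist(lapply(vox, function(v) tumorcpm:::face_neighbors(dims, v)))
    nbs <- nbs[owner[nbs] == 0L]
    if (length(nbs)) owner[nbs[sample.int(length(nbs), 1)]] <- grow
    if (mean(owner > 0) > 0.35) break
  }
  # random scatter makes some cells fragmented (stress for continuity)
  sc <- which(owner == 0L)
  sc <- sc[stats::runif(length(sc)) < scatter]
  if (length(sc)) owner[sc] <- sample.int(k, length(sc), replace = TRUE)
  st$owner <- owner
  st$ncell <- k
  st$cell_type[seq_len(k)] <- sample(c(tumorcpm:::TYPE_M, tumorcpm:::TYPE_P, tumorcpm:::TYPE_Q, tumorcpm:::TYPE_EC), k,
                                     replace = TRUE)
  st$volume[seq_len(k)] <- tabulate(owner, nbins = k)
  st$tvol[seq_len(k)] <- pmax(st$volume[seq_len(k)] +
                                sample(-3:3, k, replace = TRUE), 0)
  st$init_vol[seq_len(k)] <- pmax(st$volume[seq_len(k)], 1L)
  st$ec_active[seq_len(k)] <- 1L
  st
}

# apply one copy (site takes the owner of source) to a state, R-side
apply_copy_r <- function(st, site, source) {
  from <- st$owner[site]; to <- st$owner[source]
  if (from > 0) st$volume[from] <- st$volume[from] - 1L
  if (to > 0) st$volume[to] <- st$volume[to] + 1L
  st$owner[site] <- to
  st
}

# hand-built state: one box-shaped cell per entry of `boxes` (list of
# x/y/z ranges), types parallel vector
box_state <- function(dims, boxes, types, cfg = NULL, n0 = 0) {
  if (is.null(cfg)) {
    cfg <- default_config(dims = as.integer(dims), max_cells = 64L, n0 = n0)
  }
  st <- sim_state(cfg)
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    g <- expand.grid(x = b[[1]], y = b[[2]], z = b[[3]])
    vox <- tumorcpm:::voxel_index(st$dims, g$x, g$y, g$z)
    st <- tumorcpm:::add_cell(st, vox, types[i], tvol = length(vox),
                              init_vol = length(vox))
  }
  st
}
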