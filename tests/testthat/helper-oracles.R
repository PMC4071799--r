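# Independent brute-force oracles. These deliberately share no code with the
# package kernels: sphere marking is a vectorized distance matrix over
# (points x atoms), dilation is an offset-shift OR over the lattice ball,
# and connectivity is a queue-based BFS in R.

oracle_grid_coords <- function(grid) {
  idx <- as.matrix(expand.grid(i = seq_len(grid$dims[1]),
                               j = seq_len(grid$dims[2]),
                               k = seq_len(grid$dims[3])))
  cbind(grid$origin[1] + grid$spacing * (idx[, 1] - 1),
        grid$origin[2] + grid$spacing * (idx[, 2] - 1),
        grid$origin[3] + grid$spacing * (idx[, 3] - 1))
}

# point set iff ||p - atom|| <= radius for some atom (<= convention)
oracle_mark_spheres <- function(atoms, grid, radii) {
  pts <- oracle_grid_coords(grid)
  out <- rep(FALSE, nrow(pts))
  for (a in seq_len(nrow(atoms))) {
    d2 <- (pts[, 1] - atoms$x[a])^2 + (pts[, 2] - atoms$y[a])^2 +
      (pts[, 3] - atoms$z[a])^2
    out <- out | d2 <= radii[a]^2
  }
  array(out, dim = grid$dims)
}

oracle_center_field <- function(atoms, grid, probe) {
  !oracle_mark_spheres(atoms, grid, atoms$vdw_radius + probe)
}

# dilation by the discretized ball: OR of the center field shifted by every
# integer offset with ||offset*h|| <= probe
oracle_dilate <- function(centers, grid, probe) {
  h <- grid$spacing
  m <- ceiling(probe / h)
  out <- array(FALSE, dim = grid$dims)
  d <- grid$dims
  for (di in -m:m) for (dj in -m:m) for (dk in -m:m) {
    if ((di^2 + dj^2 + dk^2) * (h * h) > probe * probe) next
    src_i <- seq_len(d[1]) - di; src_j <- seq_len(d[2]) - dj
    src_k <- seq_len(d[3]) - dk
    ok_i <- src_i >= 1 & src_i <= d[1]
    ok_j <- src_j >= 1 & src_j <= d[2]
    ok_k <- src_k >= 1 & src_k <= d[3]
    out[ok_i, ok_j, ok_k] <- out[ok_i, ok_j, ok_k] |
      centers[src_i[ok_i], src_j[ok_j], src_k[ok_k], drop = FALSE]
  }
  out
}

# independent 26-connectivity labeling by iterated min-label propagation:
# every set point starts with a unique id and repeatedly takes the minimum
# over its 26 neighbors until a fixed point is reached
oracle_flood_fill <- function(field) {
  d <- dim(field)
  lab <- array(0L, dim = d)
  lab[field] <- seq_len(sum(field))
  pad <- array(0L, dim = d + 2L)
  ix <- seq(2L, d[1] + 1L); iy <- seq(2L, d[2] + 1L); iz <- seq(2L, d[3] + 1L)
  repeat {
    pad[] <- 0L
    pad[ix, iy, iz] <- lab
    best <- lab
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      nb <- pad[ix + di, iy + dj, iz + dk]
      upd <- field & nb > 0L & nb < best
      best[upd] <- nb[upd]
    }
    if (identical(best, lab)) break
    lab <- best
  }
  lab
}

# TRUE where any 26-neighbor of a set voxel is TRUE
shift26_or <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  ix <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); iz <- 2:(d[3] + 1)
  pad[ix, iy, iz] <- m
  out <- array(FALSE, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    out <- out | pad[ix + di, iy + dj, iz + dk]
  }
  out
}

# labellings agree up to renaming of labels
expect_same_partition <- function(lab_a, lab_b) {
  expect_equal(lab_a > 0, lab_b > 0)
  set <- which(lab_a > 0)
  if (length(set)) {
    expect_equal(length(unique(lab_a[set])), length(unique(lab_b[set])))
    key <- paste(lab_a[set], lab_b[set])
    expect_equal(length(unique(key)), length(unique(lab_a[set])))
  }
}

# small random atom cloud with radii, as a receptor-like tibble
random_atoms <- function(n, extent = 6, rmin = 1.2, rmax = 2.0) {
  tibble::tibble(
    record = "ATOM", serial = seq_len(n), atom_name = "C", alt_loc = " ",
    residue_name = "UNK", chain_id = "A", residue_number = seq_len(n),
    insertion_code = " ",
    x = stats::runif(n, -extent, extent),
    y = stats::runif(n, -extent, extent),
    z = stats::runif(n, -extent, extent),
    occupancy_value = 1, element = "C",
    vdw_radius = stats::runif(n, rmin, rmax), radius_source = "fixture"
  )
}

toy_pdb_lines <- function() {
  c("HEADER    TOY STRUCTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "HETATM    4  O   HOH A 101       5.000   5.000   5.000  1.00 20.00           O",
    "HETATM    5  C1  LIG A 201       3.000   3.000   3.000  1.00 15.00           C",
    "HETATM    6  C2  LIG A 201       3.500   3.000   3.000  1.00 15.00           C",
    "END")
}
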