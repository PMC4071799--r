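test_that("grid construction covers the padded region minimally", {
  a <- random_atoms(1)
  a$x <- a$y <- a$z <- 0
  a$vdw_radius <- 1.7
  g <- build_grid(a, spacing = 0.5, probe_out = 4.0, probe_in = 1.4)
  lo <- g$origin
  hi <- g$origin + g$spacing * (g$dims - 1)
  need <- 1.7 + 4.0 + 1.4 + 0.5
  expect_true(all(lo <= -need) && all(hi >= need))
  expect_true(all(lo > -need - 2 * g$spacing))  # minimal up to one step

  two <- random_atoms(2)
  two$x <- c(0, 10); two$y <- two$z <- c(0, 0); two$vdw_radius <- 1.7
  g2 <- build_grid(two, spacing = 0.5)
  expect_gt(g2$dims[1], g2$dims[2])
  expect_equal(g2$dims[2], g2$dims[3])

  box <- box_space(c(0, 0, 0), c(8, 8, 8))
  g3 <- build_grid(two, box, spacing = 0.5, probe_out = 4, probe_in = 1.4)
  expect_true(all(g3$spacing * (g3$dims - 1) >= 8 + 2 * (4 + 1.4 + 0.5)))
})

test_that("occupancy and center fields match frozen lattice-ball counts", {
  a <- random_atoms(1)
  a$x <- a$y <- a$z <- 0
  a$vdw_radius <- 1.7
  g <- grid_spec(origin = c(-5, -5, -5), spacing = 0.5, dims = c(21, 21, 21))
  occ <- mark_occupancy(a, g)
  # independent enumeration: lattice points with i^2+j^2+k^2 <= (1.7/0.5)^2
  expect_equal(sum(occ), 171L)

  cen <- compute_center_field(a, g, probe_radius = 1.4)
  # blocked ball: distance <= 1.7 + 1.4 = 3.1, i.e. 6.2 steps
  expect_equal(sum(!cen), 1021L)

  # larger probe yields nested centers
  cen_big <- compute_center_field(a, g, probe_radius = 2.0)
  expect_true(all(cen | !cen_big))
})

test_that("dilation of a single center is the frozen lattice ball", {
  g <- grid_spec(origin = c(0, 0, 0), spacing = 0.5, dims = c(15, 15, 15))
  centers <- array(FALSE, dim = g$dims)
  centers[8, 8, 8] <- TRUE
  cov <- dilate_centers(centers, g, probe_radius = 1.4)
  expect_equal(sum(cov), 81L)
  # empty centers dilate to empty
  expect_equal(sum(dilate_centers(array(FALSE, g$dims), g, 1.4)), 0L)
  # dilation distributes over union
  c2 <- array(FALSE, dim = g$dims); c2[3, 3, 3] <- TRUE
  both <- dilate_centers(centers | c2, g, 1.4)
  expect_equal(both, dilate_centers(centers, g, 1.4) |
                 dilate_centers(c2, g, 1.4), ignore_attr = TRUE)
})

test_that("all fields match brute-force oracles on random instances", {
  withr::local_seed(41)
  for (rep in 1:6) {
    atoms <- random_atoms(sample(3:20, 1), extent = 4)
    probe_in <- stats::runif(1, 1.0, 1.8)
    probe_out <- stats::runif(1, 2.5, 5)
    g <- build_grid(atoms, spacing = stats::runif(1, 0.5, 0.9),
                    probe_out = probe_out, probe_in = probe_in)
    expect_lte(prod(g$dims), 42^3)

    occ <- mark_occupancy(atoms, g)
    expect_equal(occ, oracle_mark_spheres(atoms, g, atoms$vdw_radius),
                 ignore_attr = TRUE)

    cen_in <- compute_center_field(atoms, g, probe_in)
    expect_equal(cen_in, oracle_center_field(atoms, g, probe_in),
                 ignore_attr = TRUE)

    cov_in <- dilate_centers(cen_in, g, probe_in)
    expect_equal(cov_in, oracle_dilate(cen_in, g, probe_in),
                 ignore_attr = TRUE)

    cen_out <- compute_center_field(atoms, g, probe_out)
    cov_out <- dilate_centers(cen_out, g, probe_out)
    expect_equal(cov_out, oracle_dilate(cen_out, g, probe_out),
                 ignore_attr = TRUE)

    cavity <- extract_cavity_field(cov_in, cen_in, cov_out, occ, g)
    expect_equal(cavity, cov_in & !cov_out & !occ, ignore_attr = TRUE)
    # cavity never intersects occupancy; sas mode nests in vdw mode
    expect_false(any(cavity & occ))
    sas <- extract_cavity_field(cov_in, cen_in, cov_out, occ, g, "sas")
    expect_true(all(cov_in | !sas))
  }
})

test_that("EDT-based dilation equals a literal double loop on a tiny grid", {
  withr::local_seed(7)
  g <- grid_spec(origin = c(0, 0, 0), spacing = 0.6, dims = c(10, 10, 10))
  centers <- array(stats::runif(1000) < 0.05, dim = g$dims)
  probe <- 1.3
  pts <- oracle_grid_coords(g)
  cts <- pts[as.vector(centers), , drop = FALSE]
  lit <- vapply(seq_len(nrow(pts)), function(p) {
    any((cts[, 1] - pts[p, 1])^2 + (cts[, 2] - pts[p, 2])^2 +
          (cts[, 3] - pts[p, 3])^2 <= probe^2)
  }, logical(1))
  expect_equal(as.vector(dilate_centers(centers, g, probe)), lit)
})

test_that("bulk restriction drops sealed-void probe placements only", {
  atoms <- make_hollow_sphere(void_radius = 5)
  g <- detect_cavities(atoms, spacing = 0.6, keep_fields = TRUE)
  cen_out_all <- compute_center_field(atoms, g$grid, 4.0)
  cen_out_bulk <- bulk_centers(cen_out_all, g$grid)
  expect_true(sum(cen_out_bulk) < sum(cen_out_all))  # void placements dropped
  # dropped centers all lie inside the void
  dropped <- which(cen_out_all & !cen_out_bulk)
  xyz <- grid_coords(arrayInd(dropped, g$grid$dims), g$grid)
  expect_true(all(sqrt(rowSums(xyz^2)) < 5))
  # on an open structure nothing is dropped
  slab <- make_slab_pocket(slab_dims = c(8, 8, 4), pocket_radius = 2)
  gs <- detect_cavities(slab, spacing = 0.6, keep_fields = TRUE)
  co <- compute_center_field(slab, gs$grid, 4.0)
  expect_equal(sum(bulk_centers(co, gs$grid)), sum(co))
})

test_that("step re-dimension rescales spacing to the point budget", {
  g <- grid_spec(c(0, 0, 0), 0.25, c(200, 200, 200))  # 8e6 points
  expect_identical(apply_step_redimension(g, 1e7), g)
  g2 <- suppressMessages(apply_step_redimension(g, 1e6))
  expect_lte(prod(as.numeric(g2$dims)), 1e6)
  expect_equal(g2$spacing %% 0.05, 0, tolerance = 1e-9)
  expect_equal(g2$spacing, 0.25 * 2, tolerance = 0.2)  # ~cube-root scaling
  # quantized minimality: one 0.05 step finer would blow the budget
  finer <- g2$spacing - 0.05
  expect_gt((ceiling(0.25 * 199 / finer) + 1)^3, 1e6)
  expect_message(apply_step_redimension(g, 1e6), "coarsened")
  expect_identical(apply_step_redimension(g, Inf), g)
})
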