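test_that("component labeling implements 26-connectivity", {
  g <- grid_spec(c(0, 0, 0), 0.5, c(6, 6, 6))
  f <- array(FALSE, g$dims)
  f[2, 2, 2] <- TRUE; f[4, 2, 2] <- TRUE        # index difference (2,0,0)
  expect_length(label_components(f, g), 2L)
  f <- array(FALSE, g$dims)
  f[2, 2, 2] <- TRUE; f[3, 3, 3] <- TRUE        # full diagonal neighbor
  expect_length(label_components(f, g), 1L)
})

test_that("labeling matches the flood-fill oracle on random fields", {
  withr::local_seed(99)
  g <- grid_spec(c(0, 0, 0), 0.5, c(12, 12, 12))
  for (dens in c(0.03, 0.15, 0.4)) {
    f <- array(stats::runif(prod(g$dims)) < dens, g$dims)
    comps <- label_components(f, g)
    lab <- array(0L, g$dims)
    for (ci in seq_along(comps)) lab[comps[[ci]]] <- ci
    expect_same_partition(lab, oracle_flood_fill(f))
    # partition property: sizes sum to the set count, no duplicates
    expect_equal(sum(vapply(comps, nrow, integer(1))), sum(f))
  }
})

test_that("volume and area follow the voxel rules", {
  block <- as.matrix(expand.grid(i = 1:3, j = 1:3, k = 1:3))
  expect_equal(cavity_volume(block, 0.5), 3.375)
  expect_equal(cavity_volume(block[0, , drop = FALSE], 0.5), 0)
  expect_equal(cavity_area(block, 0.5), 13.5)          # 54 faces
  single <- matrix(c(5L, 5L, 5L), ncol = 3)
  expect_equal(cavity_area(single, 0.5), 1.5)          # 6 faces

  # area equals a brute-force 6-neighbor face count on a random component
  withr::local_seed(3)
  g <- grid_spec(c(0, 0, 0), 0.7, c(10, 10, 10))
  f <- array(stats::runif(1000) < 0.3, g$dims)
  comps <- label_components(f, g)
  for (pts in comps[seq_len(min(4, length(comps)))]) {
    keys <- paste(pts[, 1], pts[, 2], pts[, 3])
    faces <- 0L
    for (r in seq_len(nrow(pts))) {
      for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        if (!paste(pts[r, 1] + d[1], pts[r, 2] + d[2],
                   pts[r, 3] + d[3]) %in% keys) {
          faces <- faces + 1L
        }
      }
    }
    expect_equal(cavity_area(pts, 0.7), faces * 0.49)
    expect_gte(cavity_area(pts, 0.7), 6 * 0.49)
  }
})

test_that("center of mass is the plain mean of point coordinates", {
  g <- grid_spec(c(0, 0, 0), 1, c(5, 5, 5))
  pts <- rbind(c(1L, 1L, 1L), c(2L, 1L, 1L))  # coords (0,0,0), (1,0,0)
  expect_equal(cavity_center_of_mass(pts, g), c(0.5, 0, 0))
  expect_error(cavity_center_of_mass(pts[0, , drop = FALSE], g), "empty")
  withr::local_seed(11)
  idx <- cbind(sample(1:5, 20, TRUE), sample(1:5, 20, TRUE),
               sample(1:5, 20, TRUE))
  expect_equal(cavity_center_of_mass(idx, g), colMeans(idx - 1))
})

test_that("residue contacts use the inclusive vdw + probe + margin rule", {
  g <- grid_spec(c(0, 0, 0), 0.5, c(5, 5, 5))
  pts <- matrix(c(1L, 1L, 1L), ncol = 3)  # cavity point at the origin
  mk <- function(x, rnum) tibble::tibble(
    residue_name = "ALA", atom_name = "CA", chain_id = "A",
    residue_number = rnum, x = x, y = 0, z = 0, element = "C",
    vdw_radius = 1.7
  )
  thr <- 1.7 + 1.4 + 0.5
  atoms <- dplyr::bind_rows(mk(thr, 1), mk(thr + 0.01, 2))
  out <- contributing_residues(pts, g, atoms, probe_in = 1.4,
                               contact_margin = 0.5)
  expect_equal(out$residue_number, 1)  # at threshold in, just beyond out
  expect_equal(nrow(contributing_residues(pts[0, , drop = FALSE], g, atoms)),
               0L)
  # ordering by chain then residue number
  atoms2 <- dplyr::bind_rows(mk(1, 7), mk(1.2, 2))
  atoms2$chain_id <- c("B", "A")
  out2 <- contributing_residues(pts, g, atoms2)
  expect_equal(out2$chain_id, c("A", "B"))
})

test_that("volume filter and ranking are deterministic", {
  mkcav <- function(vol, imin) tibble::tibble(
    points = list(matrix(c(imin, 1L, 1L), ncol = 3)),
    n_points = 1L, volume = vol, area = 1,
    com_x = 0, com_y = 0, com_z = 0, residues = list(tibble::tibble())
  )
  cavs <- dplyr::bind_rows(mkcav(10, 5L), mkcav(4, 1L), mkcav(2, 2L))
  out <- filter_and_rank(cavs, 5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$volume, 10)
  expect_equal(out$tag, "KAA")

  out_all <- filter_and_rank(cavs, 0)
  expect_equal(out_all$volume, c(10, 4, 2))

  ties <- dplyr::bind_rows(mkcav(3, 9L), mkcav(3, 2L))
  out_tie <- filter_and_rank(ties, 0)
  expect_equal(out_tie$points[[1]][1, 1], 2L)  # min index wins the tie

  # idempotent
  expect_equal(filter_and_rank(out_all, 0)$volume, out_all$volume)
})
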