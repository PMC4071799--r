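mk_ranked <- function(coms, volumes = rev(seq_along(coms))) {
  tibble::tibble(
    tag = cavity_tags(length(coms)),
    com_x = vapply(coms, `[`, numeric(1), 1),
    com_y = vapply(coms, `[`, numeric(1), 2),
    com_z = vapply(coms, `[`, numeric(1), 3),
    volume = as.numeric(volumes)
  )
}

mk_ligand <- function(xyz = c(0, 0, 0)) {
  lig <- random_atoms(1)
  lig$x <- xyz[1]; lig$y <- xyz[2]; lig$z <- xyz[3]
  lig
}

test_that("top-k evaluation applies the inclusive 4 A rule at the rank cutoff", {
  lig <- mk_ligand()
  expect_true(evaluate_prediction(mk_ranked(list(c(3.9, 0, 0))), lig, k = 1))
  expect_false(evaluate_prediction(mk_ranked(list(c(4.1, 0, 0),
                                                  c(0, 4.1, 0),
                                                  c(0, 0, 4.1))), lig, k = 3))
  expect_true(evaluate_prediction(mk_ranked(list(c(4.0, 0, 0))), lig, k = 1))
  ranked <- mk_ranked(list(c(10, 0, 0), c(0, 10, 0), c(1, 0, 0)))
  expect_false(evaluate_prediction(ranked, lig, k = 2))
  expect_true(evaluate_prediction(ranked, lig, k = 3))
  expect_error(evaluate_prediction(ranked, lig[0, ], k = 1), "empty ligand")
  expect_false(evaluate_prediction(ranked[0, ], lig, k = 1))
})

test_that("probe scan runs 13 whole-protein detections on one lattice", {
  atoms <- make_slab_pocket(slab_dims = c(8, 8, 4), pocket_radius = 2.5)
  scan <- probe_out_scan(atoms, spacing = 0.6)
  expect_length(scan, 13L)
  expect_equal(names(scan)[c(1, 13)], c("2.0", "8.0"))
  dims <- vapply(scan, function(r) r$grid$dims, integer(3))
  expect_true(all(dims == dims[, 1]))  # shared lattice
  expect_error(probe_out_scan(atoms, radii = c(1.0, 4)), "exceed probe_in")

  one <- probe_out_scan(atoms, radii = 4.0, spacing = 0.6)
  plain <- detect_cavities(atoms, probe_out = 4.0, spacing = 0.6,
                           grid = one[["4.0"]]$grid)
  expect_equal(one[["4.0"]]$cavities$volume, plain$cavities$volume)
})

test_that("combined prediction is the union of per-radius successes", {
  lig <- mk_ligand()
  hit <- list(cavities = mk_ranked(list(c(1, 0, 0))))
  miss <- list(cavities = mk_ranked(list(c(9, 9, 9))))
  class(hit) <- class(miss) <- "cavity_result"
  expect_false(combine_predictions(list(`2.0` = miss, `2.5` = miss), lig,
                                   k = 3))
  expect_true(combine_predictions(list(`2.0` = miss, `2.5` = hit), lig,
                                  k = 3))
  # union success rate dominates every single radius on any case set
  scans <- list(list(`2.0` = miss, `4.0` = hit),
                list(`2.0` = hit, `4.0` = miss))
  combined <- vapply(scans, combine_predictions, logical(1), ligand = lig,
                     k = 1)
  for (rn in c("2.0", "4.0")) {
    single <- vapply(scans, function(s) {
      evaluate_prediction(s[[rn]], lig, k = 1)
    }, logical(1))
    expect_gte(mean(combined), mean(single))
  }
  # pooled rule re-ranks across radii by volume
  big_far <- list(cavities = mk_ranked(list(c(9, 9, 9)), volumes = 100))
  class(big_far) <- "cavity_result"
  expect_false(combine_predictions(list(a = big_far, b = hit), lig, k = 1,
                                   rule = "pooled"))
  expect_true(combine_predictions(list(a = big_far, b = hit), lig, k = 2,
                                  rule = "pooled"))
})

test_that("success summaries are fractions, monotone in k", {
  per_case <- tibble::tibble(
    case_id = rep(c("a", "b", "c", "d"), 2),
    condition = rep(c("default", "combined"), each = 4),
    top1 = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    top2 = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    top3 = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  s <- success_rate_summary(per_case)
  expect_equal(s$top1[s$condition == "default"], 0.25)
  expect_equal(s$top2[s$condition == "default"], 0.5)
  expect_true(all(s$top1 <= s$top2 & s$top2 <= s$top3))
  expect_true(all(s$top1 >= 0 & s$top3 <= 1))
  expect_error(success_rate_summary(per_case[0, ]), "no benchmark cases")
})

test_that("the manifest workflow scores constructed cases end to end", {
  dir <- withr::local_tempdir()
  manifest <- write_benchmark_fixtures(dir, n_cases = 2, seed = 11)
  bench <- run_benchmark(manifest, spacing = 0.6)
  expect_s3_class(bench, "benchmark_summary")
  expect_equal(nrow(bench$per_case), 2L)
  expect_true(all(bench$per_case$top1))

  # a missing case file is reported and skipped, the rest still scored
  tab <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$pdb_path[2] <- file.path(dir, "gone.pdb")
  expect_warning(b2 <- run_benchmark(tab, spacing = 0.6), "skipped 1")
  expect_equal(nrow(b2$per_case), 1L)
  expect_error(run_benchmark(tab[0, ]), "empty benchmark manifest")
})
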