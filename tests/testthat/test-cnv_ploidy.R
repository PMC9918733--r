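test_that("good-cell rule anchors on the 10th-ranked cell's reads", {
  # 12 cells: ranks 1..10 have 1000+ reads, so the 10th-ranked has 1000;
  # threshold = 100
  totals <- c(seq(2000, 1000, length.out = 10), 100, 99)
  counts <- matrix(0L, 12, 4)
  counts[, 1] <- as.integer(totals)
  m <- make_amp_matrix(counts)
  good <- good_quality_cells(m)
  expect_true("bc11" %in% good)    # exactly at threshold: "at least" keeps it
  expect_false("bc12" %in% good)   # 99 < 100
})

test_that("equal-read cells are all good; small sets degrade to all cells", {
  m <- make_amp_matrix(matrix(10L, 15, 3))
  expect_equal(good_quality_cells(m), rownames(m))
  small <- make_amp_matrix(matrix(c(1000L, 1L), 2, 3))
  expect_message(good_small <- good_quality_cells(small), "keeping all")
  expect_equal(good_small, rownames(small))
})

test_that("good-cell selection equals a brute-force sort-and-threshold oracle", {
  set.seed(91)
  counts <- matrix(rnbinom(50 * 8, size = 2, mu = 40), 50, 8)
  m <- make_amp_matrix(counts)
  totals <- rowSums(counts)
  anchor <- sort(totals, decreasing = TRUE)[10]
  oracle <- rownames(m)[totals >= anchor / 10]
  expect_setequal(good_quality_cells(m), oracle)
})

test_that("two-step normalization has the stated symmetry properties", {
  # constant matrix -> all ones
  m <- make_amp_matrix(matrix(7L, 12, 4))
  expect_equal(unname(normalize_counts(m)), matrix(1, 12, 4), ignore_attr = TRUE)
  # doubling a cell's counts changes nothing after within-cell normalization
  counts <- matrix(rep(c(10L, 20L, 30L, 40L), each = 12), 12, 4)
  counts[1, ] <- counts[1, ] * 2L
  norm <- normalize_counts(make_amp_matrix(counts))
  expect_equal(norm[1, ], norm[2, ])
})

test_that("normalization matches a hand-computed 4x3 example", {
  counts <- matrix(c(10L, 20L, 30L,
                     20L, 40L, 60L,
                     10L, 10L, 10L,
                     30L, 30L, 60L), 4, 3, byrow = TRUE)
  m <- make_amp_matrix(counts)
  # step 1: rows / row means (20, 40, 10, 40)
  step1 <- counts / c(20, 40, 10, 40)
  # step 2: columns / per-column medians of step1 (all cells are good here)
  med <- apply(step1, 2, median)
  expected <- sweep(step1, 2, med, "/")
  expect_equal(unname(normalize_counts(m)), unname(expected),
               ignore_attr = TRUE)
})

test_that("ploidy is 2 at the baseline median and scales as a ratio", {
  counts <- matrix(rep(c(50L, 100L, 150L), each = 20), 20, 3)
  counts[20, ] <- counts[20, ] %/% 2L   # one cell at half the counts everywhere
  m <- make_amp_matrix(counts)
  norm <- normalize_counts(m)
  pm <- compute_ploidy(norm, baseline = rownames(m)[1:19])
  expect_equal(unname(pm$ploidy[1, ]), rep(2, 3))
  # relative ploidy of the half-count cell is still 2: within-cell
  # normalization removes pure scale differences
  expect_equal(unname(pm$ploidy[20, ]), rep(2, 3))
})

test_that("scaling a cell's raw counts leaves its ploidy row unchanged", {
  set.seed(5)
  counts <- matrix(rnbinom(30 * 6, size = 8, mu = 100), 30, 6) + 1L
  m1 <- make_amp_matrix(counts)
  counts2 <- counts; counts2[3, ] <- counts2[3, ] * 7L
  m2 <- make_amp_matrix(counts2)
  base <- rownames(m1)[10:30]
  p1 <- ploidy_pipeline(m1, base)
  p2 <- ploidy_pipeline(m2, base)
  expect_equal(p2$ploidy[3, ], p1$ploidy[3, ], tolerance = 1e-12)
})

test_that("baseline cells have median ploidy exactly 2 on every amplicon", {
  set.seed(23)
  counts <- matrix(rnbinom(60 * 10, size = 8, mu = 80), 60, 10) + 1L
  m <- make_amp_matrix(counts)
  base <- rownames(m)[1:30]
  pm <- ploidy_pipeline(m, base)
  base_used <- pm$baseline_cells
  med <- apply(pm$ploidy[base_used, ], 2, median)
  expect_equal(unname(med), rep(2, 10), tolerance = 1e-9)
})

test_that("norm_a/b/c split of simulated normals yields medians near 2", {
  vs <- panel_variants(1)
  cfg <- sim_config(list(clone_spec("normal", 1)), make_panel(15), vs,
                    n_cells = 6000L, doublet_rate = 0, ado_prob = 0,
                    n_background = 0L, seed = 101L)
  sim <- simulate_dataset(cfg)
  cells <- sim$cells$barcodes
  groups <- split(cells, rep_len(c("norm_a", "norm_b", "norm_c"), length(cells)))
  pm <- ploidy_pipeline(sim$amplicons, groups$norm_a)
  assignment <- setNames(rep(names(groups), lengths(groups)), unlist(groups))
  med <- clone_median_ploidy(pm, assignment)
  expect_true(all(med["norm_b", ] >= 1.9 & med["norm_b", ] <= 2.1))
  expect_true(all(med["norm_c", ] >= 1.9 & med["norm_c", ] <= 2.1))
})

test_that("low-noise ploidy recovers true copy number on a realistic panel", {
  # within-cell mean normalization makes ploidy relative to the cell's
  # average copy number, so recovery is near-exact only when the aberrant
  # amplicons are a small fraction of the panel (as in a real targeted panel)
  vs <- panel_variants(1)
  clones <- list(
    clone_spec("normal", 0.5),
    clone_spec("aneuploid", 0.5, copy_number = c(AMP02 = 1, AMP03 = 0, AMP04 = 3))
  )
  cfg <- sim_config(clones, make_panel(60), vs, n_cells = 400L,
                    doublet_rate = 0, ado_prob = 0, mean_depth = 2000,
                    depth_dispersion = 1e6, n_background = 0L, seed = 17L)
  sim <- simulate_dataset(cfg)
  lab <- setNames(sim$truth$barcodes$clone, sim$truth$barcodes$barcode)
  pm <- ploidy_pipeline(sim$amplicons, names(lab)[lab == "normal"])
  med <- clone_median_ploidy(pm, lab)
  expect_equal(unname(med["aneuploid", c("AMP02", "AMP03", "AMP04")]),
               c(1, 0, 3), tolerance = 0.03)
  expect_equal(unname(med["normal", ]), rep(2, 60), tolerance = 0.03)
})

test_that("clone medians flag homozygous deletions on deleted amplicons only", {
  vs <- panel_variants(1)
  smad4_amps <- sprintf("AMP%02d", 5:12)   # 8 amplicons; delete 7 of them
  deleted <- smad4_amps[1:7]
  clones <- list(
    clone_spec("normal", 0.6),
    clone_spec("homdel", 0.4,
               copy_number = setNames(rep(0, 7), deleted))
  )
  cfg <- sim_config(clones, make_panel(12), vs, n_cells = 500L,
                    doublet_rate = 0, ado_prob = 0, n_background = 0L,
                    seed = 29L)
  sim <- simulate_dataset(cfg)
  lab <- setNames(sim$truth$barcodes$clone, sim$truth$barcodes$barcode)
  pm <- ploidy_pipeline(sim$amplicons, names(lab)[lab == "normal"])
  med <- clone_median_ploidy(pm, lab)
  flags <- detect_homdel(med)
  expect_true(all(flags["homdel", deleted]))
  expect_false(any(flags["homdel", setdiff(colnames(med), deleted)]))
  expect_false(any(flags["normal", ]))
})

test_that("single-cell clones return that cell's ploidy as the median", {
  set.seed(3)
  counts <- matrix(rnbinom(20 * 4, size = 8, mu = 60), 20, 4) + 1L
  m <- make_amp_matrix(counts)
  pm <- ploidy_pipeline(m, rownames(m)[1:10])
  lab <- setNames(c("solo", rep("rest", 19)), rownames(m))
  med <- clone_median_ploidy(pm, lab)
  expect_equal(unname(med["solo", ]), unname(pm$ploidy["bc01", ]))
})
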