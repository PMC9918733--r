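make_geno <- function(mat, variants) {
  structure(mat, dimnames = list(sprintf("c%03d", seq_len(nrow(mat))), variants))
}

test_that("ordered rules assign hierarchically and MISSING blocks both ways", {
  vs <- variant_id("12", c(100L, 200L), "C", "A")
  g <- make_geno(rbind(
    c("HET", "WT"),       # tumor by rule 1
    c("WT", "WT"),        # putative normal by rule 2
    c("MISSING", "WT"),   # missing KRAS: neither carrier nor WT -> unassigned
    c("HOM", "HET")       # still tumor (first rule wins)
  ), vs)
  rules <- list(
    clone_rule("tumor", required_carriers = vs[1]),
    clone_rule("putative_normal", required_wt = vs)
  )
  ca <- assign_clones(g, rules)
  expect_equal(unname(ca$assignment),
               c("tumor", "putative_normal", "unassigned", "tumor"))
  expect_equal(sum(ca$summary$n_cells), nrow(g))
  expect_equal(sum(ca$summary$fraction), 1)
})

test_that("any-of carrier rules accept cells with at least one driver", {
  vs <- variant_id("12", c(100L, 200L, 300L), "C", "A")
  g <- make_geno(rbind(
    c("HET", "WT", "WT"),
    c("WT", "WT", "HOM"),
    c("WT", "WT", "WT")
  ), vs)
  ca <- assign_clones(g, list(clone_rule("tumor", vs, any_of = TRUE)))
  expect_equal(unname(ca$assignment), c("tumor", "tumor", "unassigned"))
  # the same rule read as ALL-of matches nobody
  ca_all <- assign_clones(g, list(clone_rule("tumor", vs)))
  expect_equal(unname(table(ca_all$assignment)[["unassigned"]]), 3L)
})

test_that("clone percent formatting uses one decimal, integers below 2%", {
  expect_equal(format_clone_percent(113 / 479), "23.6%")
  expect_equal(format_clone_percent(40 / 3866), "1%")
  expect_equal(format_clone_percent(0.5), "50.0%")
})

test_that("rules referencing absent variants fail fast", {
  vs <- variant_id("12", 100L, "C", "A")
  g <- make_geno(matrix("WT", 2, 1), vs)
  expect_error(assign_clones(g, list()), "no clone rules")
  expect_error(
    assign_clones(g, list(clone_rule("x", variant_id("1", 5L, "G", "T")))),
    "absent")
  expect_error(clone_rule("x", vs, vs), "disjoint")
})

test_that("two-variant Venn regions enumerate carrier combinations", {
  vs <- variant_id("3", c(10L, 20L), "G", "T")
  g <- make_geno(rbind(
    matrix(rep(c("HET", "WT"), 5), 5, 2, byrow = TRUE),
    matrix(rep(c("WT", "HOM"), 3), 3, 2, byrow = TRUE),
    matrix(rep(c("HET", "HET"), 2), 2, 2, byrow = TRUE),
    c("WT", "WT"),
    c("WT", "MISSING")
  ), vs)
  vc <- colocalization_counts(g, vs)
  expect_equal(unname(vc$regions[vs[1]]), 5L)
  expect_equal(unname(vc$regions[vs[2]]), 3L)
  expect_equal(unname(vc$regions[paste(vs, collapse = "&")]), 2L)
  expect_equal(vc$neither, 1L)
  expect_equal(vc$excluded_missing, 1L)
  expect_error(colocalization_counts(g, c(vs[1], vs[1])), "duplicate")
})

test_that("Venn conservation holds on random genotype fixtures", {
  set.seed(202)
  vs <- variant_id("7", c(1L, 2L, 3L), "A", "C")
  for (k in 2:3) {
    for (rep in 1:5) {
      g <- make_geno(matrix(sample(c("WT", "HET", "HOM", "MISSING"), 60 * k,
                                   replace = TRUE), 60, k), vs[seq_len(k)])
      vc <- colocalization_counts(g, vs[seq_len(k)])
      expect_equal(sum(vc$regions) + vc$neither + vc$excluded_missing,
                   vc$n_total)
    }
  }
})

test_that("mutually exclusive noise-free clones share no cells", {
  mix <- simulate_mixing_experiment(0.4, 0, 800, seed = 6L)
  g <- assign_genotypes(mix$cells)
  vc <- colocalization_counts(g, c(mix$driver_a, mix$driver_b))
  expect_equal(unname(vc$regions[paste(c(mix$driver_a, mix$driver_b),
                                       collapse = "&")]), 0L)
})

test_that("multilayer features concatenate genotype and homdel layers", {
  vs <- variant_id("18", seq_len(25), "A", "G")
  cells <- sprintf("c%03d", 1:30)
  g <- structure(matrix(sample(c("WT", "HET", "HOM", "MISSING"), 750,
                               replace = TRUE, prob = c(.6, .2, .1, .1)),
                        30, 25), dimnames = list(cells, vs))
  amps <- sprintf("SMAD4_AMP%d", 1:8)
  homdel <- matrix(FALSE, 30, 8, dimnames = list(cells, amps))
  homdel[1:10, 1:7] <- TRUE
  feat <- build_multilayer_features(g, vs, homdel, amps)
  expect_equal(ncol(feat), 33L)
  expect_s3_class(feat[[1]], "factor")
  expect_equal(levels(feat[[1]]), c("WT", "HET", "HOM", "MISSING"))
  expect_type(feat[["homdel_SMAD4_AMP1"]], "logical")
  expect_equal(attr(feat, "provenance"),
               c(rep("genotype", 25), rep("homdel", 8)))

  # genotype-only matrix when no amplicons are selected
  feat0 <- build_multilayer_features(g, vs, homdel, character(0))
  expect_equal(ncol(feat0), 25L)

  bad <- homdel[1:20, , drop = FALSE]
  expect_error(build_multilayer_features(g, vs, bad, amps), "different cell")
})

test_that("clone-structured features separate clones under k-modes-style clustering", {
  # 4 clones with distinct genotype + homdel signatures; hierarchical
  # clustering on simple matching distance should recover them
  vs <- panel_variants(6)
  smad4 <- sprintf("AMP%02d", 7:10)
  clones <- list(
    clone_spec("c1", 0.25, genotype = setNames(rep("HET", 2), vs[1:2])),
    clone_spec("c2", 0.25, genotype = setNames(rep("HET", 2), vs[3:4])),
    clone_spec("c3", 0.25, genotype = setNames(rep("HOM", 2), vs[5:6]),
               copy_number = setNames(rep(0, 4), smad4)),
    clone_spec("c4", 0.25)
  )
  cfg <- sim_config(clones, make_panel(10), vs, n_cells = 400L,
                    doublet_rate = 0, ado_prob = 0.05, n_background = 0L,
                    seed = 67L)
  sim <- simulate_dataset(cfg)
  g <- assign_genotypes(sim$cells)
  pm <- ploidy_pipeline(sim$amplicons,
                        rownames(g)[sim$truth$barcodes$clone == "c4"])
  homdel_cells <- pm$ploidy < 0.5
  feat <- build_multilayer_features(g, vs, homdel_cells, smad4)
  num <- vapply(feat, function(col) as.integer(as.factor(col)), integer(nrow(feat)))
  # simple matching distance: fraction of disagreeing features
  n <- nrow(num)
  dmat <- matrix(0, n, n)
  for (j in seq_len(ncol(num))) {
    dmat <- dmat + outer(num[, j], num[, j], "!=")
  }
  cl <- stats::cutree(stats::hclust(stats::as.dist(dmat / ncol(num)), "average"), k = 4)
  truth_lab <- sim$truth$barcodes$clone
  tab <- table(cl, truth_lab)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(purity, 0.9)
})
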