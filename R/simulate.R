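# Clone-structured synthetic data generator for droplet snDNA-seq.
#
# Each real barcode is a nucleus drawn from a declared clone; its per-amplicon
# reads follow a negative binomial whose mean scales with amplicon efficiency
# and the clone's copy number (2 = diploid). Variant DP equals the covering
# amplicon's reads; AD is binomial at the genotype's allele fraction, modified
# by symmetric per-allele dropout. Doublets are the elementwise sum of two
# independently drawn nuclei. Background barcodes emit shallow ambient reads.

#' Declare a clone for the simulator
#'
#' @param clone_id Clone label.
#' @param proportion Fraction of real nuclei belonging to this clone.
#' @param genotype Named character vector, variant id -> one of
#'   `"WT"`, `"HET"`, `"HOM"`. Unlisted variants are `WT`.
#' @param copy_number Named numeric vector, amplicon id -> copy number
#'   (2 = diploid, 0 = homozygous deletion). Unlisted amplicons are diploid.
#' @return A `clone_spec` list.
#' @export
clone_spec <- function(clone_id, proportion, genotype = character(),
                       copy_number = numeric()) {
  if (length(genotype) && !all(genotype %in% c("WT", "HET", "HOM"))) {
    stop("genotype values must be WT/HET/HOM", call. = FALSE)
  }
  if (length(copy_number) && any(copy_number < 0)) {
    stop("copy numbers must be >= 0", call. = FALSE)
  }
  structure(list(clone_id = as.character(clone_id),
                 proportion = proportion,
                 genotype = genotype, copy_number = copy_number),
            class = "clone_spec")
}

#' Map variants to their covering amplicons
#'
#' Each variant must fall inside exactly one panel interval on the same
#' chromosome; its DP is that amplicon's read count (amplicon reads are the
#' physical unit of the assay). When several amplicons overlap a position the
#' first in panel order wins.
#'
#' @param variants Character vector of canonical variant ids.
#' @param panel An [amplicon_panel()].
#' @return Named integer vector of panel row indices, one per variant.
#' @export
map_variants_to_amplicons <- function(variants, panel) {
  vp <- parse_variant_id(variants)
  idx <- vapply(seq_len(nrow(vp)), function(i) {
    hit <- which(panel$chrom == vp$chrom[i] &
                   panel$start <= vp$pos[i] & panel$end >= vp$pos[i])
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  if (anyNA(idx)) {
    stop("variant(s) not covered by any panel amplicon: ",
         paste(variants[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  names(idx) <- variants
  idx
}

#' Simulator configuration
#'
#' Bundles clones, panel, variants and the noise model. Defaults are the
#' assay's nominal operating point: 100 reads per cell per amplicon target
#' depth, moderate negative-binomial overdispersion, per-allele dropout
#' probability 0.1101 (so the expected exactly-one-allele dropout fraction at
#' a heterozygous site, 2q(1-q), is 19.6%), and a 4% doublet rate.
#'
#' @param clones List of [clone_spec()] objects; proportions must sum to 1.
#' @param panel An [amplicon_panel()].
#' @param variants Character vector of canonical variant ids; each must be
#'   covered by a panel amplicon.
#' @param n_cells Number of real nuclei barcodes.
#' @param doublet_rate Probability `d` in `[0, 1)` that a barcode holds two
#'   nuclei.
#' @param ado_prob Per-allele dropout probability `q` in `[0, 1)`.
#' @param mean_depth Mean reads per cell per amplicon at diploid copy number
#'   and unit efficiency.
#' @param depth_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param amplicon_efficiency Optional named numeric vector of per-amplicon
#'   relative amplification factors (default 1 for all).
#' @param n_background Number of low-read background (ambient) barcodes.
#' @param background_depth_scale Depth multiplier for background barcodes.
#' @param seed Integer seed; the simulation is deterministic given the config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(clones, panel, variants,
                       n_cells = 1000L,
                       doublet_rate = 0.04,
                       ado_prob = 0.1101,
                       mean_depth = 100,
                       depth_dispersion = 8,
                       amplicon_efficiency = NULL,
                       n_background = n_cells,
                       background_depth_scale = 0.05,
                       seed = 1L) {
  stopifnot(length(clones) >= 1L, inherits(panel, "amplicon_panel"))
  props <- vapply(clones, function(cl) cl$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-9) {
    stop("clone proportions must sum to 1", call. = FALSE)
  }
  if (doublet_rate < 0 || doublet_rate >= 1) stop("doublet_rate must be in [0,1)", call. = FALSE)
  if (ado_prob < 0 || ado_prob >= 1) stop("ado_prob must be in [0,1)", call. = FALSE)
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  if (mean_depth <= 0 || depth_dispersion <= 0) {
    stop("mean_depth and depth_dispersion must be positive", call. = FALSE)
  }
  eff <- stats::setNames(rep(1, nrow(panel)), panel$amplicon_id)
  if (!is.null(amplicon_efficiency)) {
    if (any(amplicon_efficiency <= 0)) stop("efficiencies must be positive", call. = FALSE)
    eff[names(amplicon_efficiency)] <- amplicon_efficiency
  }
  bad_amp <- unlist(lapply(clones, function(cl) {
    setdiff(names(cl$copy_number), panel$amplicon_id)
  }))
  if (length(bad_amp)) {
    stop("clone copy_number references unknown amplicon(s): ",
         paste(unique(bad_amp), collapse = ", "), call. = FALSE)
  }
  bad_var <- unlist(lapply(clones, function(cl) {
    setdiff(names(cl$genotype), variants)
  }))
  if (length(bad_var)) {
    stop("clone genotype references undeclared variant(s): ",
         paste(unique(bad_var), collapse = ", "), call. = FALSE)
  }
  va <- map_variants_to_amplicons(variants, panel)  # errors if uncovered
  structure(list(
    clones = clones, panel = panel, variants = variants,
    variant_amplicon = va,
    n_cells = as.integer(n_cells), doublet_rate = doublet_rate,
    ado_prob = ado_prob, mean_depth = mean_depth,
    depth_dispersion = depth_dispersion, amplicon_efficiency = eff,
    n_background = as.integer(n_background),
    background_depth_scale = background_depth_scale,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# clone-level genotype (K x V) and copy-number (K x A) matrices
clone_matrices <- function(config) {
  K <- length(config$clones)
  V <- length(config$variants)
  A <- nrow(config$panel)
  geno <- matrix("WT", K, V, dimnames = list(NULL, config$variants))
  cn <- matrix(2, K, A, dimnames = list(NULL, config$panel$amplicon_id))
  for (k in seq_len(K)) {
    cl <- config$clones[[k]]
    if (length(cl$genotype)) geno[k, names(cl$genotype)] <- cl$genotype
    if (length(cl$copy_number)) cn[k, names(cl$copy_number)] <- cl$copy_number
  }
  list(geno = geno, cn = cn,
       ids = vapply(config$clones, function(cl) cl$clone_id, character(1)),
       props = vapply(config$clones, function(cl) cl$proportion, numeric(1)))
}

# expected alt fraction per genotype label
alt_fraction <- function(g) c(WT = 0, HET = 0.5, HOM = 1)[g]

#' Simulate a clone-structured snDNA-seq dataset
#'
#' @param config A [sim_config()].
#' @return A list with `cells` ([cell_variant_data()]), `amplicons`
#'   ([amplicon_matrix()] spanning real and background barcodes), `panel`,
#'   and `truth` (a `sim_truth` list: per-barcode table with clone labels and
#'   doublet flags, true genotype / copy-number matrices for real barcodes,
#'   per cell-variant dropped-allele codes for singlets, and the constituent
#'   amplicon counts from which doublets were summed).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cm <- clone_matrices(config)
  A <- nrow(config$panel); V <- length(config$variants)
  n <- config$n_cells
  va <- config$variant_amplicon
  eff <- config$amplicon_efficiency
  q <- config$ado_prob

  is_dbl <- stats::runif(n) < config$doublet_rate
  owner <- rep(seq_len(n), times = 1L + is_dbl)
  k_tot <- length(owner)
  const_clone <- sample.int(length(cm$ids), k_tot, replace = TRUE, prob = cm$props)

  mu <- config$mean_depth * matrix(eff, k_tot, A, byrow = TRUE) *
    cm$cn[const_clone, , drop = FALSE] / 2
  counts_c <- matrix(stats::rnbinom(k_tot * A, size = config$depth_dispersion,
                                    mu = mu), k_tot, A)
  # Doublets share one droplet reaction: overdispersion acts at droplet
  # level, so the droplet's total per-amplicon reads are drawn at the
  # combined mean and allocated between the two nuclei binomially by their
  # template share. Constituent counts still sum exactly to the barcode's.
  first_const <- match(seq_len(n), owner)
  if (any(is_dbl)) {
    r1 <- first_const[is_dbl]; r2 <- r1 + 1L
    mu_pair <- mu[r1, , drop = FALSE] + mu[r2, , drop = FALSE]
    tot <- matrix(stats::rnbinom(length(mu_pair),
                                 size = config$depth_dispersion,
                                 mu = mu_pair), nrow(mu_pair), A)
    share <- ifelse(mu_pair > 0, mu[r1, , drop = FALSE] / mu_pair, 0)
    x1 <- matrix(stats::rbinom(length(tot), tot, share), nrow(tot), A)
    counts_c[r1, ] <- x1
    counts_c[r2, ] <- tot - x1
  }

  DP_c <- counts_c[, va, drop = FALSE]
  g_c <- cm$geno[const_clone, , drop = FALSE]
  d1 <- matrix(stats::runif(k_tot * V) < q, k_tot, V)  # ref-class failure
  d2 <- matrix(stats::runif(k_tot * V) < q, k_tot, V)  # alt-class failure
  frac <- matrix(alt_fraction(g_c), k_tot, V)
  het <- g_c == "HET"
  frac[het & d1 & !d2] <- 1   # ref allele dropped -> apparent HOM
  frac[het & !d1 & d2] <- 0   # alt allele dropped -> apparent WT
  zero <- d1 & d2             # both copies failed -> site unobservable
  DP_c[zero] <- 0L
  AD_c <- matrix(stats::rbinom(k_tot * V, DP_c, frac), k_tot, V)

  agg <- function(m) rowsum(m, group = owner, reorder = TRUE)
  counts_cell <- agg(counts_c)
  DP_cell <- agg(DP_c)
  AD_cell <- agg(AD_c)

  first <- first_const
  second <- ifelse(is_dbl, first + 1L, NA_integer_)
  c1 <- const_clone[first]
  c2 <- ifelse(is_dbl, const_clone[pmax(second, 1L)], NA_integer_)
  clone_lab <- ifelse(is_dbl, paste(cm$ids[c1], cm$ids[c2], sep = "+"),
                      cm$ids[c1])

  # merged truth genotype: alt allele copies out of 4 for doublets
  copies <- c(WT = 0L, HET = 1L, HOM = 2L)
  cp1 <- matrix(copies[cm$geno[c1, , drop = FALSE]], n, V)
  true_geno <- cm$geno[c1, , drop = FALSE]
  if (any(is_dbl)) {
    cp2 <- matrix(copies[cm$geno[ifelse(is.na(c2), c1, c2), , drop = FALSE]], n, V)
    tot <- cp1 + cp2
    merged <- matrix("HET", n, V)
    merged[tot == 0L] <- "WT"
    merged[tot == 4L] <- "HOM"
    true_geno[is_dbl, ] <- merged[is_dbl, ]
  }
  true_cn <- cm$cn[c1, , drop = FALSE]
  if (any(is_dbl)) {
    true_cn[is_dbl, ] <- (cm$cn[c1[is_dbl], , drop = FALSE] +
                            cm$cn[c2[is_dbl], , drop = FALSE]) / 2
  }

  drop_code <- matrix(NA_character_, n, V)
  sing <- which(!is_dbl)
  dd1 <- d1[first[sing], , drop = FALSE]
  dd2 <- d2[first[sing], , drop = FALSE]
  dc <- matrix("none", length(sing), V)
  dc[dd1 & !dd2] <- "ref"
  dc[!dd1 & dd2] <- "alt"
  dc[dd1 & dd2] <- "both"
  drop_code[sing, ] <- dc

  cell_bc <- sprintf("cell_%05d", seq_len(n))
  rownames(counts_cell) <- rownames(DP_cell) <- rownames(AD_cell) <- cell_bc
  rownames(true_geno) <- rownames(true_cn) <- rownames(drop_code) <- cell_bc
  colnames(counts_cell) <- config$panel$amplicon_id
  colnames(DP_cell) <- colnames(AD_cell) <- colnames(true_geno) <-
    colnames(drop_code) <- config$variants

  # background barcodes: shallow ambient reads; alt fraction per variant is
  # the clone-proportion-weighted expected VAF (ambient pool of lysed cells)
  nb <- config$n_background
  if (nb > 0L) {
    mu_bg <- config$mean_depth * config$background_depth_scale *
      matrix(eff, nb, A, byrow = TRUE)
    counts_bg <- matrix(stats::rnbinom(nb * A, size = config$depth_dispersion,
                                       mu = mu_bg), nb, A)
    DP_bg <- counts_bg[, va, drop = FALSE]
    ambient <- as.numeric(cm$props %*% matrix(alt_fraction(cm$geno),
                                              nrow(cm$geno), V))
    AD_bg <- matrix(stats::rbinom(nb * V, DP_bg,
                                  matrix(ambient, nb, V, byrow = TRUE)), nb, V)
    bg_bc <- sprintf("bg_%05d", seq_len(nb))
    rownames(counts_bg) <- rownames(DP_bg) <- rownames(AD_bg) <- bg_bc
    counts_all <- rbind(counts_cell, counts_bg)
    DP_all <- rbind(DP_cell, DP_bg)
    AD_all <- rbind(AD_cell, AD_bg)
  } else {
    bg_bc <- character(0)
    counts_all <- counts_cell; DP_all <- DP_cell; AD_all <- AD_cell
  }
  colnames(DP_all) <- colnames(AD_all) <- config$variants
  colnames(counts_all) <- config$panel$amplicon_id

  barcode_table <- data.frame(
    barcode = c(cell_bc, bg_bc),
    is_cell = c(rep(TRUE, n), rep(FALSE, length(bg_bc))),
    is_doublet = c(is_dbl, rep(FALSE, length(bg_bc))),
    clone = c(clone_lab, rep(NA_character_, length(bg_bc))),
    clone_1 = c(cm$ids[c1], rep(NA_character_, length(bg_bc))),
    clone_2 = c(ifelse(is.na(c2), NA_character_, cm$ids[c2]),
                rep(NA_character_, length(bg_bc))),
    stringsAsFactors = FALSE
  )
  truth <- structure(list(
    barcodes = barcode_table,
    genotype = true_geno,
    copy_number = true_cn,
    dropout = drop_code,
    constituents = list(owner = owner, clone = cm$ids[const_clone],
                        counts = counts_c),
    config = config
  ), class = "sim_truth")

  list(cells = cell_variant_data(DP_all, AD_all),
       amplicons = amplicon_matrix(counts_all),
       panel = config$panel,
       truth = truth)
}

#' Simulate a two-population nuclei mixing experiment
#'
#' Emulates the doublet-rate experiment in which nuclei from two different
#' tumors, each carrying a private clonal driver SNV, are mixed and run as one
#' library; barcodes genotyped as carrying both drivers reveal doublets.
#'
#' @param p Fraction of nuclei from population A.
#' @param d Doublet rate in `[0, 1)`.
#' @param n_droplets Number of droplet barcodes.
#' @param seed Integer seed.
#' @param mean_depth Mean reads per cell per amplicon (default 100, the assay
#'   target depth).
#' @param depth_dispersion Negative-binomial size.
#' @param ado_q Per-allele dropout probability (default 0: the experiment's
#'   drivers are deliberately deep, well-behaved sites).
#' @return A list with `cells`, `amplicons`, `truth` (with a per-barcode
#'   `category` column: `"A"`, `"B"` or `"AB"`), and the two driver ids
#'   `driver_a`, `driver_b`.
#' @export
simulate_mixing_experiment <- function(p, d, n_droplets, seed = 1L,
                                       mean_depth = 100, depth_dispersion = 8,
                                       ado_q = 0) {
  if (p <= 0 || p >= 1) stop("p must be in (0,1)", call. = FALSE)
  if (n_droplets <= 0) stop("n_droplets must be positive", call. = FALSE)
  panel <- amplicon_panel(
    amplicon_id = c("AMP_TP53_1", "AMP_ARID1A_1", "AMP_KRAS_1", "AMP_GATA6_1"),
    chrom = c("17", "1", "12", "18"),
    start = c(7578100, 27106300, 25398200, 19751000),
    end = c(7578300, 27106500, 25398400, 19751200),
    gene = c("TP53", "ARID1A", "KRAS", "GATA6")
  )
  driver_a <- variant_id("17", 7578190, "G", "A")   # TP53-like driver
  driver_b <- variant_id("1", 27106355, "C", "T")   # ARID1A-like driver
  clones <- list(
    clone_spec("popA", p, genotype = stats::setNames("HET", driver_a)),
    clone_spec("popB", 1 - p, genotype = stats::setNames("HET", driver_b))
  )
  cfg <- sim_config(clones, panel, variants = c(driver_a, driver_b),
                    n_cells = n_droplets, doublet_rate = d, ado_prob = ado_q,
                    mean_depth = mean_depth,
                    depth_dispersion = depth_dispersion,
                    n_background = 0L, seed = seed)
  sim <- simulate_dataset(cfg)
  bt <- sim$truth$barcodes
  cat1 <- ifelse(bt$clone_1 == "popA", "A", "B")
  cat2 <- ifelse(is.na(bt$clone_2), cat1,
                 ifelse(bt$clone_2 == "popA", "A", "B"))
  sim$truth$barcodes$category <- ifelse(cat1 == cat2, cat1, "AB")
  list(cells = sim$cells, amplicons = sim$amplicons, truth = sim$truth,
       driver_a = driver_a, driver_b = driver_b)
}

#' Simulate read counts at heterozygous germline SNPs
#'
#' Every nucleus is truly heterozygous at every SNP; each of the two allele
#' classes independently fails to amplify with probability `ado_q`. A single
#' failed allele yields an all-ref or all-alt observation; both failed yields
#' zero depth (the site is unobservable). This is the calibration substrate
#' for the allelic-dropout estimator: the expected exactly-one-allele dropout
#' fraction is `2q(1-q)`.
#'
#' @param n_cells Number of nuclei.
#' @param n_snps Number of heterozygous SNPs.
#' @param ado_q Per-allele dropout probability in `[0, 1)`.
#' @param mean_depth Mean site depth per nucleus (default 50).
#' @param depth_dispersion Negative-binomial size.
#' @param seed Integer seed.
#' @return A [cell_variant_data()] with an attached `"dropout"` attribute
#'   (character matrix of `"none"/"ref"/"alt"/"both"` truth codes).
#' @export
simulate_het_snp_reads <- function(n_cells, n_snps, ado_q,
                                   mean_depth = 50, depth_dispersion = 8,
                                   seed = 1L) {
  if (n_cells <= 0 || n_snps <= 0) stop("n_cells and n_snps must be positive", call. = FALSE)
  if (ado_q < 0 || ado_q >= 1) stop("ado_q must be in [0,1)", call. = FALSE)
  if (mean_depth <= 0) stop("mean_depth must be positive", call. = FALSE)
  set.seed(seed)
  n <- as.integer(n_cells); s <- as.integer(n_snps)
  DP <- matrix(stats::rnbinom(n * s, size = depth_dispersion, mu = mean_depth), n, s)
  d_ref <- matrix(stats::runif(n * s) < ado_q, n, s)
  d_alt <- matrix(stats::runif(n * s) < ado_q, n, s)
  frac <- matrix(0.5, n, s)
  frac[d_ref & !d_alt] <- 1
  frac[!d_ref & d_alt] <- 0
  DP[d_ref & d_alt] <- 0L
  AD <- matrix(stats::rbinom(n * s, DP, frac), n, s)
  rownames(DP) <- rownames(AD) <- sprintf("cell_%05d", seq_len(n))
  colnames(DP) <- colnames(AD) <- variant_id("1", 1000000L + 1000L * seq_len(s),
                                             "A", "G")
  code <- matrix("none", n, s)
  code[d_ref & !d_alt] <- "ref"
  code[!d_ref & d_alt] <- "alt"
  code[d_ref & d_alt] <- "both"
  out <- cell_variant_data(DP, AD)
  attr(out, "dropout") <- code
  out
}

#' Write simulation truth labels as TSV
#'
#' @param truth A `sim_truth` object.
#' @param path Output file for the per-barcode truth table.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  utils::write.table(truth$barcodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
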