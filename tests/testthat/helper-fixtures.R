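# Shared fixture builders. Everything is generated in code; matrices are tiny
# unless a statistical property needs n.

make_cvd <- function(DP, AD, barcodes = NULL, variants = NULL) {
  DP <- as.matrix(DP); AD <- as.matrix(AD)
  if (is.null(barcodes)) barcodes <- sprintf("bc%02d", seq_len(nrow(DP)))
  if (is.null(variants)) {
    variants <- variant_id("1", 1000L + seq_len(ncol(DP)), "A", "T")
  }
  dimnames(DP) <- dimnames(AD) <- list(barcodes, variants)
  cell_variant_data(DP, AD)
}

make_amp_matrix <- function(counts, barcodes = NULL, amplicons = NULL) {
  counts <- as.matrix(counts)
  if (is.null(barcodes)) barcodes <- sprintf("bc%02d", seq_len(nrow(counts)))
  if (is.null(amplicons)) amplicons <- sprintf("AMP%02d", seq_len(ncol(counts)))
  dimnames(counts) <- list(barcodes, amplicons)
  amplicon_matrix(counts)
}

# a small panel: n amplicons of 200 bp laid end to end on chr1, one gene each
make_panel <- function(n, genes = sprintf("GENE%02d", seq_len(n))) {
  start <- 10000L + (seq_len(n) - 1L) * 1000L
  amplicon_panel(sprintf("AMP%02d", seq_len(n)), "1", start, start + 199L, genes)
}

# one variant in the middle of each of the first k amplicons of make_panel(n)
panel_variants <- function(k) {
  variant_id("1", 10100L + (seq_len(k) - 1L) * 1000L, "A", "T")
}

# scalar re-implementation of the genotyping rule, used as brute-force oracle
oracle_genotype <- function(dp, ad, min_depth = 5, min_alt = 3,
                            wt_max = 20, het_max = 80) {
  if (dp < min_depth) return("MISSING")
  vaf <- 100 * ad / dp
  g <- if (vaf <= wt_max) "WT" else if (vaf <= het_max) "HET" else "HOM"
  if (g %in% c("HET", "HOM") && ad < min_alt) g <- "WT"
  g
}

# nested-loop re-implementation of cell calling, used as oracle
oracle_call_cells <- function(counts, mult = 8, comp = 0.8, factor = 0.2) {
  qualified <- character()
  for (b in rownames(counts)) {
    if (sum(counts[b, ]) > mult * ncol(counts)) qualified <- c(qualified, b)
  }
  stopifnot(length(qualified) > 0)
  working <- character()
  means <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) means[j] <- mean(counts[qualified, j])
  for (j in seq_len(ncol(counts))) {
    if (means[j] > factor * mean(means)) working <- c(working, colnames(counts)[j])
  }
  called <- character()
  for (b in qualified) {
    hit <- 0
    for (a in working) if (counts[b, a] >= 1) hit <- hit + 1
    if (hit / length(working) > comp) called <- c(called, b)
  }
  list(qualified = qualified, working = working, called = called)
}
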