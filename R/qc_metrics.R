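# Library-level QC: allelic-dropout (ADO) estimation from germline
# heterozygous SNPs, and sequencing depth planning.
#
# ADO rate per SNP = (nuclei with strictly 0 reads of exactly one allele) /
# (nuclei with adequate depth at that SNP). A truly heterozygous site should
# show both alleles in every nucleus; an all-ref or all-alt observation marks
# a dropout event. Nuclei with zero depth carry no allele information and are
# excluded from both numerator and denominator.

#' Germline SNP selection parameters
#'
#' @param min_bulk_normal_vaf Keep variants with bulk-normal VAF strictly
#'   above this (default 0.2), excluding technical artifacts.
#' @param sc_mean_vaf_low,sc_mean_vaf_high Keep variants whose mean
#'   single-nucleus VAF (over nuclei with VAF > 0) lies strictly between
#'   these bounds (defaults 0.2 and 0.8), excluding homozygous sites and
#'   somatic mosaicism.
#' @return An `snp_selection_params` list.
#' @export
snp_selection_params <- function(min_bulk_normal_vaf = 0.2,
                                 sc_mean_vaf_low = 0.2,
                                 sc_mean_vaf_high = 0.8) {
  stopifnot(sc_mean_vaf_low > 0, sc_mean_vaf_low < sc_mean_vaf_high,
            sc_mean_vaf_high < 1)
  structure(list(min_bulk_normal_vaf = min_bulk_normal_vaf,
                 sc_mean_vaf_low = sc_mean_vaf_low,
                 sc_mean_vaf_high = sc_mean_vaf_high),
            class = "snp_selection_params")
}

#' Select germline heterozygous SNPs for ADO estimation
#'
#' Keeps variants detected in the matched bulk normal with VAF above
#' `min_bulk_normal_vaf`, then requires the mean single-nucleus VAF —
#' computed over nuclei with nonzero VAF — to fall strictly between the two
#' single-cell bounds.
#'
#' @param d A [cell_variant_data()].
#' @param bulk A `bulk_annotations` table from [read_bulk_annotations()] (or
#'   an equivalent data.frame).
#' @param params An [snp_selection_params()].
#' @return Character vector of selected germline SNP ids.
#' @export
select_germline_snps <- function(d, bulk, params = snp_selection_params()) {
  stopifnot(inherits(d, "cell_variant_data"), is.data.frame(bulk))
  normal <- bulk[bulk$is_normal_sample, , drop = FALSE]
  if (nrow(normal) == 0L) {
    stop("no normal-sample bulk annotations provided", call. = FALSE)
  }
  candidate <- unique(normal$variant[normal$bulk_vaf > params$min_bulk_normal_vaf])
  candidate <- intersect(d$variants, candidate)
  keep <- vapply(candidate, function(v) {
    dp <- d$DP[, v]; ad <- d$AD[, v]
    vaf <- ad[dp > 0] / dp[dp > 0]
    vaf <- vaf[vaf > 0]
    if (length(vaf) == 0L) return(FALSE)
    m <- mean(vaf)
    m > params$sc_mean_vaf_low && m < params$sc_mean_vaf_high
  }, logical(1))
  candidate[keep]
}

#' Estimate the allelic dropout rate from germline SNPs
#'
#' Per SNP: the denominator is the number of nuclei with `DP >= min_depth`;
#' the numerator is those among them with strictly zero reads of exactly one
#' allele (`AD == 0` or `AD == DP`; ref reads are `DP - AD`). The summary
#' `mean_ado` is the unweighted mean of per-SNP rates. SNPs with an empty
#' denominator are dropped with a warning.
#'
#' @param d A [cell_variant_data()].
#' @param snps Character vector of SNP ids, a subset of `d$variants`.
#' @param min_depth Depth floor for a nucleus to enter the denominator
#'   (default 5); nuclei below it cannot distinguish one- from both-allele
#'   dropout.
#' @return An `ado_result` list: `per_snp` (data.frame with per-SNP rate,
#'   numerator, denominator), `mean_ado`, `n_snps`.
#' @export
compute_ado <- function(d, snps, min_depth = 5L) {
  stopifnot(inherits(d, "cell_variant_data"))
  if (!all(snps %in% d$variants)) {
    stop("unknown SNP id(s): ",
         paste(setdiff(snps, d$variants), collapse = ", "), call. = FALSE)
  }
  DP <- d$DP[, snps, drop = FALSE]
  AD <- d$AD[, snps, drop = FALSE]
  eligible <- DP >= min_depth
  one_allele <- eligible & (AD == 0L | AD == DP)
  denom <- colSums(eligible)
  numer <- colSums(one_allele)
  per_snp <- data.frame(
    snp = snps, n_dropout = numer, n_nuclei = denom,
    ado = ifelse(denom > 0, numer / denom, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(denom == 0)) {
    warning(sum(denom == 0), " SNP(s) had no nucleus at depth >= ",
            min_depth, " and were excluded from the mean", call. = FALSE)
  }
  rates <- per_snp$ado[denom > 0]
  structure(list(per_snp = per_snp,
                 mean_ado = if (length(rates)) mean(rates) else NA_real_,
                 n_snps = length(rates),
                 min_depth = as.integer(min_depth)),
            class = "ado_result")
}

#' @export
print.ado_result <- function(x, ...) {
  cat(sprintf("<ado_result> mean ADO %.1f%% over %d SNPs (depth >= %d)\n",
              100 * x$mean_ado, x$n_snps, x$min_depth))
  invisible(x)
}

#' Total read pairs required for a target per-cell per-amplicon depth
#'
#' `X = expected_nuclei * n_amplicons * target_depth / frac_reads_to_cells`,
#' rounded up. Defaults are the assay's planning values: 100 reads per cell
#' per amplicon and half of all reads expected to land in cell barcodes.
#'
#' @param expected_nuclei Expected number of nuclei called.
#' @param n_amplicons Number of panel amplicons.
#' @param target_depth Target reads per cell per amplicon (default 100).
#' @param frac_reads_to_cells Expected proportion of reads assigned to cells
#'   (default 0.5).
#' @return Required read pairs (numeric, integral value).
#' @export
required_read_pairs <- function(expected_nuclei, n_amplicons,
                                target_depth = 100,
                                frac_reads_to_cells = 0.5) {
  stopifnot(expected_nuclei > 0, n_amplicons > 0, target_depth > 0)
  if (frac_reads_to_cells <= 0 || frac_reads_to_cells > 1) {
    stop("frac_reads_to_cells must be in (0, 1]", call. = FALSE)
  }
  ceiling(expected_nuclei * n_amplicons * target_depth / frac_reads_to_cells)
}

#' Expected nuclei called from an input suspension
#'
#' The loading rule of thumb: a microfluidic run consumes ~1 microliter of
#' suspension, so the expected number of nuclei called equals the input
#' concentration times 1 microliter.
#'
#' @param concentration Input nuclei concentration (nuclei per microliter).
#' @return Expected number of nuclei called (integer).
#' @export
expected_nuclei_called <- function(concentration) {
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  as.integer(round(concentration * 1))
}
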