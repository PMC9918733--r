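# Per-cell genotype assignment from DP/AD counts, the stricter de-novo
# high-quality variant filter, and pseudobulk VAF aggregation.
#
# Genotype rule, per cell-variant pair: DP below the depth floor is MISSING;
# otherwise the percent VAF = 100*AD/DP falls into [0,20] -> WT,
# (20,80] -> HET, (80,100] -> HOM; finally any HET/HOM call supported by
# fewer than min_alt alternate reads is demoted to WT. The wide WT bin
# tolerates up to 20% of a barcode's reads being false positives from barcode
# contamination. This genotyper assigns states for known (bulk-validated)
# variants; it is not a de-novo somatic caller.

#' Genotyping thresholds
#'
#' @param min_depth Minimum DP for a call; below it the pair is `MISSING`
#'   (default 5).
#' @param min_alt Minimum alternate reads to retain a HET/HOM call; below it
#'   the call is demoted to WT (default 3).
#' @param vaf_wt_max Upper bound (percent, inclusive) of the WT bin
#'   (default 20).
#' @param vaf_het_max Upper bound (percent, inclusive) of the HET bin
#'   (default 80).
#' @return A `genotype_params` list.
#' @export
genotype_params <- function(min_depth = 5L, min_alt = 3L,
                            vaf_wt_max = 20, vaf_het_max = 80) {
  stopifnot(min_depth >= 1L, min_alt >= 0L,
            vaf_wt_max > 0, vaf_wt_max < vaf_het_max, vaf_het_max <= 100)
  structure(list(min_depth = as.integer(min_depth),
                 min_alt = as.integer(min_alt),
                 vaf_wt_max = vaf_wt_max, vaf_het_max = vaf_het_max),
            class = "genotype_params")
}

#' Assign per-cell genotypes
#'
#' @param d A [cell_variant_data()].
#' @param params A [genotype_params()].
#' @return A character matrix (class `genotype_matrix`) of
#'   `"WT"/"HET"/"HOM"/"MISSING"` with the same barcode/variant dimnames as
#'   the input.
#' @export
assign_genotypes <- function(d, params = genotype_params()) {
  stopifnot(inherits(d, "cell_variant_data"))
  DP <- d$DP; AD <- d$AD
  vaf <- 100 * AD / pmax(DP, 1L)   # DP=0 rows become MISSING below anyway
  g <- matrix("WT", nrow(DP), ncol(DP), dimnames = dimnames(DP))
  g[vaf > params$vaf_wt_max & vaf <= params$vaf_het_max] <- "HET"
  g[vaf > params$vaf_het_max] <- "HOM"
  g[(g == "HET" | g == "HOM") & AD < params$min_alt] <- "WT"
  g[DP < params$min_depth] <- "MISSING"
  structure(g, class = c("genotype_matrix", class(matrix())))
}

#' Strict variant-filter parameters for de-novo high-quality variant lists
#'
#' @param strict_min_depth Depth floor for the stricter regenotyping
#'   (default 10).
#' @param strict_min_alt Alternate-read floor for the stricter regenotyping
#'   (default 5).
#' @param max_missing_fraction Variants `MISSING` in strictly more than this
#'   fraction of cells are discarded unless whitelisted (default 0.75).
#' @param whitelist_genes Genes exempt from the missingness filter; defaults
#'   to genes prone to homozygous deletion in PDAC (`SMAD4`, `CDKN2A`), whose
#'   variants go missing for biological rather than technical reasons.
#' @param min_prevalence A variant is kept only if HET or HOM in at least
#'   this fraction of all cells (default 0.005).
#' @return A `variant_filter_params` list.
#' @export
variant_filter_params <- function(strict_min_depth = 10L, strict_min_alt = 5L,
                                  max_missing_fraction = 0.75,
                                  whitelist_genes = c("SMAD4", "CDKN2A"),
                                  min_prevalence = 0.005) {
  stopifnot(max_missing_fraction > 0, max_missing_fraction < 1,
            min_prevalence > 0, min_prevalence < 1)
  structure(list(strict_min_depth = as.integer(strict_min_depth),
                 strict_min_alt = as.integer(strict_min_alt),
                 max_missing_fraction = max_missing_fraction,
                 whitelist_genes = whitelist_genes,
                 min_prevalence = min_prevalence),
            class = "variant_filter_params")
}

#' Derive a de-novo high-quality variant list
#'
#' Regenotypes with the stricter depth/alt thresholds (same VAF bins), drops
#' variants missing in more than `max_missing_fraction` of cells unless their
#' gene is whitelisted, then keeps variants mutated (HET or HOM) in at least
#' `min_prevalence` of all cells.
#'
#' @param d A [cell_variant_data()].
#' @param params A [variant_filter_params()].
#' @param gene_map Named character vector, variant id -> gene symbol.
#'   Variants absent from the map get no whitelist protection.
#' @return Character vector of retained variant ids ordered by carrier
#'   prevalence (descending, ties broken by canonical id).
#' @export
filter_high_quality_variants <- function(d, params = variant_filter_params(),
                                         gene_map = character()) {
  stopifnot(inherits(d, "cell_variant_data"))
  if (length(d$barcodes) == 0L) stop("empty cell set", call. = FALSE)
  g <- assign_genotypes(d, genotype_params(
    min_depth = params$strict_min_depth, min_alt = params$strict_min_alt))
  miss_frac <- colMeans(g == "MISSING")
  genes <- gene_map[d$variants]
  whitelisted <- !is.na(genes) & genes %in% params$whitelist_genes
  keep_missing <- miss_frac <= params$max_missing_fraction | whitelisted
  prevalence <- colMeans(g == "HET" | g == "HOM")
  keep <- keep_missing & prevalence >= params$min_prevalence
  kept <- d$variants[keep]
  kept[order(-prevalence[keep], kept)]
}

#' Pseudobulk variant allele frequencies
#'
#' Aggregates single-cell counts into a bulk-like measurement: per variant,
#' the sum of AD over the selected cells divided by the sum of DP
#' (read-weighted, matching bulk semantics). Variants with zero total depth
#' are excluded and reported via the `"undefined"` attribute.
#'
#' @param d A [cell_variant_data()].
#' @param cells Barcodes to aggregate (default: all).
#' @return Named numeric vector of VAF fractions in `[0, 1]`.
#' @export
pseudobulk_vaf <- function(d, cells = d$barcodes) {
  stopifnot(inherits(d, "cell_variant_data"))
  if (length(cells) == 0L) stop("empty cell subset", call. = FALSE)
  if (!all(cells %in% d$barcodes)) {
    stop("unknown barcode(s) in cell subset", call. = FALSE)
  }
  dp <- colSums(d$DP[cells, , drop = FALSE])
  ad <- colSums(d$AD[cells, , drop = FALSE])
  defined <- dp > 0
  out <- ad[defined] / dp[defined]
  attr(out, "undefined") <- d$variants[!defined]
  out
}
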