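# Per-amplicon ploidy from read counts: two-step normalization (within-cell
# by mean, then within-amplicon by the median over good-quality cells),
# followed by the ratio against a diploid baseline population scaled so
# baseline cells read as ploidy 2. Homozygous deletions appear as ploidy ~ 0.

#' Ploidy-stage parameters
#'
#' @param good_cell_rank,good_cell_fraction Good-quality cells are those with
#'   at least `good_cell_fraction` times the total reads of the cell at rank
#'   `good_cell_rank` (descending by total reads); defaults 10 and 1/10.
#' @param homdel_ploidy_max Median ploidy strictly below this flags a
#'   homozygous deletion (default 0.5; true homdels sit near 0).
#' @return A `ploidy_params` list.
#' @export
ploidy_params <- function(good_cell_rank = 10L, good_cell_fraction = 0.1,
                          homdel_ploidy_max = 0.5) {
  stopifnot(good_cell_rank >= 1L,
            good_cell_fraction > 0, good_cell_fraction <= 1,
            homdel_ploidy_max >= 0, homdel_ploidy_max < 1)
  structure(list(good_cell_rank = as.integer(good_cell_rank),
                 good_cell_fraction = good_cell_fraction,
                 homdel_ploidy_max = homdel_ploidy_max),
            class = "ploidy_params")
}

#' Select good-quality cells by total read count
#'
#' Threshold = `good_cell_fraction` times the total reads of the
#' `good_cell_rank`-th cell (descending); cells at or above the threshold are
#' kept. With fewer cells than `good_cell_rank` the rule degrades to keeping
#' every cell (reported via message).
#'
#' @param m An [amplicon_matrix()].
#' @param params A [ploidy_params()].
#' @return Character vector of good-quality cell barcodes.
#' @export
good_quality_cells <- function(m, params = ploidy_params()) {
  stopifnot(inherits(m, "amplicon_matrix"))
  totals <- rowSums(unclass_matrix(m))
  if (length(totals) < params$good_cell_rank) {
    message("fewer cells than good_cell_rank; keeping all cells")
    return(rownames(m))
  }
  anchor <- sort(totals, decreasing = TRUE)[params$good_cell_rank]
  rownames(m)[totals >= params$good_cell_fraction * anchor]
}

#' Two-step normalization of amplicon counts
#'
#' Step 1 divides each cell's row by that cell's mean across amplicons
#' (removing per-cell library size); step 2 divides each amplicon's column by
#' the median of step-1 values over good-quality cells (removing per-amplicon
#' efficiency). Cells with zero total reads cannot be normalized: their rows
#' are `NA` and they are excluded from the medians.
#'
#' @param m An [amplicon_matrix()].
#' @param params A [ploidy_params()].
#' @return Numeric matrix of normalized counts with attributes
#'   `"good_cells"` (barcodes used for the medians) and `"zero_cells"`.
#' @export
normalize_counts <- function(m, params = ploidy_params()) {
  stopifnot(inherits(m, "amplicon_matrix"), nrow(m) > 0L)
  mm <- unclass_matrix(m)
  storage.mode(mm) <- "double"
  row_mean <- rowMeans(mm)
  zero_cells <- rownames(mm)[row_mean == 0]
  step1 <- mm / row_mean            # rows with mean 0 become NaN
  step1[row_mean == 0, ] <- NA_real_
  good <- setdiff(good_quality_cells(m, params), zero_cells)
  if (length(good) == 0L) stop("no usable good-quality cells", call. = FALSE)
  med <- apply(step1[good, , drop = FALSE], 2L, stats::median)
  if (any(med == 0)) {
    warning(sum(med == 0), " amplicon(s) with zero median over good cells; ",
            "normalized values undefined there", call. = FALSE)
    med[med == 0] <- NA_real_
  }
  out <- sweep(step1, 2L, med, "/")
  attr(out, "good_cells") <- good
  attr(out, "zero_cells") <- zero_cells
  out
}

#' Compute per-amplicon ploidy against a diploid baseline
#'
#' `ploidy(cell, amp) = 2 * norm(cell, amp) / median over baseline cells of
#' norm(., amp)`. The factor 2 scales the ratio so baseline cells read as
#' diploid. Amplicons whose baseline median is zero are undefined (`NA`,
#' flagged).
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param baseline Character vector of baseline (assumed-diploid) cells.
#' @return A `ploidy_matrix` list: `ploidy` (cell x amplicon), `baseline_cells`,
#'   `undefined_amplicons`.
#' @export
compute_ploidy <- function(norm, baseline) {
  if (length(baseline) == 0L) stop("empty baseline", call. = FALSE)
  if (!all(baseline %in% rownames(norm))) {
    stop("baseline cells absent from matrix", call. = FALSE)
  }
  med <- apply(norm[baseline, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  undefined <- colnames(norm)[!is.na(med) & med == 0]
  med[med == 0] <- NA_real_
  ploidy <- 2 * sweep(norm, 2L, med, "/")
  if (length(undefined)) {
    warning("baseline median is zero for amplicon(s): ",
            paste(undefined, collapse = ", "), call. = FALSE)
  }
  structure(list(ploidy = ploidy, baseline_cells = baseline,
                 undefined_amplicons = undefined),
            class = "ploidy_matrix")
}

#' Full ploidy pipeline
#'
#' Good-cell selection, two-step normalization, and baseline-ratio ploidy in
#' one call; the baseline is intersected with the good-quality cells before
#' taking medians.
#'
#' @param m An [amplicon_matrix()].
#' @param baseline Character vector of assumed-diploid cells.
#' @param params A [ploidy_params()].
#' @return A `ploidy_matrix` (see [compute_ploidy()]).
#' @export
ploidy_pipeline <- function(m, baseline, params = ploidy_params()) {
  norm <- normalize_counts(m, params)
  base <- intersect(baseline, attr(norm, "good_cells"))
  if (length(base) == 0L) {
    stop("no baseline cell passes the good-quality filter", call. = FALSE)
  }
  compute_ploidy(norm, base)
}

#' Median per-amplicon ploidy per clone
#'
#' @param pm A `ploidy_matrix` from [compute_ploidy()].
#' @param assignment Named character vector, cell barcode -> clone label.
#'   Cells not in the ploidy matrix are ignored; empty clones are omitted
#'   with a warning.
#' @return Numeric matrix, clone x amplicon, of median ploidies.
#' @export
clone_median_ploidy <- function(pm, assignment) {
  stopifnot(inherits(pm, "ploidy_matrix"))
  cells <- intersect(names(assignment), rownames(pm$ploidy))
  clones <- unique(assignment)
  dropped <- clones[!clones %in% assignment[cells]]
  if (length(dropped)) {
    warning("clone(s) with no cells in ploidy matrix omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  clones <- setdiff(clones, dropped)
  out <- t(vapply(clones, function(cl) {
    members <- cells[assignment[cells] == cl]
    apply(pm$ploidy[members, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  }, numeric(ncol(pm$ploidy))))
  rownames(out) <- clones
  colnames(out) <- colnames(pm$ploidy)
  out
}

#' Flag homozygous deletions from clone median ploidies
#'
#' @param medians Clone x amplicon median-ploidy matrix from
#'   [clone_median_ploidy()].
#' @param params A [ploidy_params()]; medians strictly below
#'   `homdel_ploidy_max` are flagged.
#' @return Logical clone x amplicon matrix (`NA` medians give `NA`).
#' @export
detect_homdel <- function(medians, params = ploidy_params()) {
  medians < params$homdel_ploidy_max
}
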