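# Barcode quality control: separate complete nuclei from ambient background
# barcodes using total-read and per-amplicon completeness rules. All three
# thresholds are strict inequalities.

#' Cell-calling parameters
#'
#' @param total_read_multiplier A barcode qualifies only if its total reads
#'   strictly exceed `total_read_multiplier * n_amplicons` (default 8).
#' @param completeness_fraction A qualified barcode is called a cell only if
#'   its fraction of working amplicons with at least one read strictly
#'   exceeds this (default 0.80).
#' @param working_amplicon_factor An amplicon is "working" if its mean reads
#'   over qualified barcodes strictly exceed this factor times the grand mean
#'   of all per-amplicon means (default 0.2).
#' @return A `cell_calling_params` list.
#' @export
cell_calling_params <- function(total_read_multiplier = 8,
                                completeness_fraction = 0.80,
                                working_amplicon_factor = 0.2) {
  stopifnot(total_read_multiplier > 0,
            completeness_fraction > 0, completeness_fraction <= 1,
            working_amplicon_factor > 0, working_amplicon_factor <= 1)
  structure(list(total_read_multiplier = total_read_multiplier,
                 completeness_fraction = completeness_fraction,
                 working_amplicon_factor = working_amplicon_factor),
            class = "cell_calling_params")
}

#' Qualify barcodes on total read count
#'
#' @param m An [amplicon_matrix()].
#' @param params A [cell_calling_params()].
#' @return Character vector of qualified barcodes (total reads strictly
#'   greater than `total_read_multiplier * n_amplicons`).
#' @export
qualify_barcodes <- function(m, params = cell_calling_params()) {
  stopifnot(inherits(m, "amplicon_matrix"), nrow(m) > 0L)
  totals <- rowSums(unclass_matrix(m))
  rownames(m)[totals > params$total_read_multiplier * ncol(m)]
}

#' Identify working amplicons among qualified barcodes
#'
#' @param m An [amplicon_matrix()].
#' @param qualified Character vector of qualified barcodes.
#' @param params A [cell_calling_params()].
#' @return Character vector of amplicons whose mean reads over qualified
#'   barcodes strictly exceed `working_amplicon_factor` times the grand mean
#'   of the per-amplicon means.
#' @export
find_working_amplicons <- function(m, qualified,
                                   params = cell_calling_params()) {
  stopifnot(inherits(m, "amplicon_matrix"))
  if (length(qualified) == 0L) {
    stop("no qualified barcodes; cannot define working amplicons", call. = FALSE)
  }
  sub <- unclass_matrix(m)[qualified, , drop = FALSE]
  amp_means <- colMeans(sub)
  colnames(m)[amp_means > params$working_amplicon_factor * mean(amp_means)]
}

#' Call complete cells from raw barcode counts
#'
#' Three-stage pipeline: (1) qualify barcodes on total reads; (2) define
#' working amplicons from the qualified barcodes; (3) keep qualified barcodes
#' whose completeness — the fraction of working amplicons with >= 1 read —
#' strictly exceeds `completeness_fraction`.
#'
#' @param m An [amplicon_matrix()].
#' @param params A [cell_calling_params()].
#' @return A `cell_calling_result` list: `called_cells`,
#'   `qualified_barcodes`, `working_amplicons`, and a per-barcode
#'   `diagnostics` data.frame (total reads, completeness, flags).
#' @export
call_cells <- function(m, params = cell_calling_params()) {
  qualified <- qualify_barcodes(m, params)
  working <- find_working_amplicons(m, qualified, params)
  if (length(working) == 0L) {
    stop("no working amplicons; library failed QC", call. = FALSE)
  }
  mm <- unclass_matrix(m)
  completeness <- rowMeans(mm[, working, drop = FALSE] >= 1L)
  is_q <- rownames(m) %in% qualified
  called <- is_q & completeness > params$completeness_fraction
  diagnostics <- data.frame(
    barcode = rownames(m),
    total_reads = rowSums(mm),
    completeness = completeness,
    qualified = is_q,
    called = called,
    stringsAsFactors = FALSE
  )
  structure(list(
    called_cells = rownames(m)[called],
    qualified_barcodes = qualified,
    working_amplicons = working,
    diagnostics = diagnostics,
    params = params
  ), class = "cell_calling_result")
}

#' @export
print.cell_calling_result <- function(x, ...) {
  cat(sprintf(
    "<cell_calling_result> %d/%d barcodes called (%d qualified, %d/%d working amplicons)\n",
    length(x$called_cells), nrow(x$diagnostics),
    length(x$qualified_barcodes), length(x$working_amplicons),
    length(x$working_amplicons) + 0L))
  invisible(x)
}
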