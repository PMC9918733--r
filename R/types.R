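# Core domain types: variant identifiers, amplicon panels, and the two count
# containers everything downstream consumes. All containers are validated at
# construction so stage code can assume the invariants hold.

#' Build a canonical variant identifier
#'
#' Variants are identified throughout the package by the canonical string
#' `"chrom:pos:ref/alt"` (1-based position, MAF-style coordinates). No indel
#' normalisation is attempted; the targeted panels this package serves are
#' SNV-centric.
#'
#' @param chrom Chromosome name (character).
#' @param pos 1-based genomic position (integer).
#' @param ref Reference allele string.
#' @param alt Alternate allele string; must differ from `ref`.
#' @return Character vector of canonical variant ids.
#' @examples
#' variant_id("12", 25398284, "C", "A")
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant position must be a positive integer", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  sprintf("%s:%d:%s/%s", as.character(chrom), pos, ref, alt)
}

#' Parse canonical variant ids back into their fields
#'
#' @param x Character vector of `"chrom:pos:ref/alt"` ids.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `variant`.
#' @export
parse_variant_id <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+):([^/]+)/(.+)$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    stop("malformed variant id(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    pos = as.integer(vapply(m, `[`, "", 3L)),
    ref = vapply(m, `[`, "", 4L),
    alt = vapply(m, `[`, "", 5L),
    variant = x,
    stringsAsFactors = FALSE
  )
}

#' Construct an amplicon panel table
#'
#' The panel describes the PCR-targeted intervals (~200 bp each) of the assay.
#' Coordinates are 1-based and inclusive at both ends.
#'
#' @param amplicon_id Unique amplicon identifiers.
#' @param chrom Chromosome per amplicon.
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param gene Gene symbol covered by each amplicon.
#' @return A data.frame of class `amplicon_panel`.
#' @export
amplicon_panel <- function(amplicon_id, chrom, start, end, gene) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(amplicon_id) == 0L) stop("panel must be non-empty", call. = FALSE)
  if (anyDuplicated(amplicon_id)) {
    stop("amplicon ids must be unique", call. = FALSE)
  }
  if (any(start > end)) stop("amplicon start > end", call. = FALSE)
  p <- data.frame(
    amplicon_id = as.character(amplicon_id),
    chrom = as.character(chrom),
    start = start, end = end,
    gene = as.character(gene),
    stringsAsFactors = FALSE
  )
  class(p) <- c("amplicon_panel", "data.frame")
  p
}

#' Per-cell variant count container
#'
#' Holds the two barcode-by-variant count matrices the genotyper consumes:
#' `DP` (total reads covering the site in that barcode) and `AD` (reads
#' supporting the alternate allele). Row names are barcodes, column names
#' canonical variant ids.
#'
#' @param DP,AD Integer matrices of identical shape with barcode row names and
#'   variant column names; `0 <= AD <= DP` elementwise.
#' @return An object of class `cell_variant_data` with elements `DP`, `AD`,
#'   `barcodes`, `variants`.
#' @export
cell_variant_data <- function(DP, AD) {
  DP <- as.matrix(DP); AD <- as.matrix(AD)
  if (!identical(dim(DP), dim(AD))) {
    stop("DP and AD must have identical dimensions", call. = FALSE)
  }
  if (is.null(rownames(DP)) || is.null(colnames(DP))) {
    stop("DP must carry barcode row names and variant column names",
         call. = FALSE)
  }
  if (nrow(DP) == 0L) stop("no barcodes (empty container)", call. = FALSE)
  if (anyDuplicated(rownames(DP))) stop("barcode ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(DP))) stop("variant ids must be unique", call. = FALSE)
  dimnames(AD) <- dimnames(DP)
  storage.mode(DP) <- "integer"
  storage.mode(AD) <- "integer"
  if (any(DP < 0L) || any(AD < 0L)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  viol <- which(AD > DP, arr.ind = TRUE)
  if (nrow(viol) > 0L) {
    stop(sprintf(
      "AD exceeds DP at barcode '%s', variant '%s' (AD=%d, DP=%d)",
      rownames(DP)[viol[1L, 1L]], colnames(DP)[viol[1L, 2L]],
      AD[viol[1L, , drop = FALSE]], DP[viol[1L, , drop = FALSE]]
    ), call. = FALSE)
  }
  structure(
    list(DP = DP, AD = AD,
         barcodes = rownames(DP), variants = colnames(DP)),
    class = "cell_variant_data"
  )
}

#' @export
print.cell_variant_data <- function(x, ...) {
  cat(sprintf("<cell_variant_data> %d barcodes x %d variants\n",
              length(x$barcodes), length(x$variants)))
  cat("  mean DP:", round(mean(x$DP), 2),
      " mean VAF (DP>0):",
      round(sum(x$AD) / max(1, sum(x$DP)), 4), "\n")
  invisible(x)
}

#' Subset a cell_variant_data container
#'
#' @param x A `cell_variant_data` object.
#' @param barcodes,variants Optional character or index vectors selecting rows
#'   and columns to keep.
#' @return A new `cell_variant_data` with the selected cells/variants.
#' @export
subset_cells <- function(x, barcodes = NULL, variants = NULL) {
  stopifnot(inherits(x, "cell_variant_data"))
  i <- if (is.null(barcodes)) seq_along(x$barcodes) else barcodes
  j <- if (is.null(variants)) seq_along(x$variants) else variants
  cell_variant_data(x$DP[i, j, drop = FALSE], x$AD[i, j, drop = FALSE])
}

#' Per-barcode amplicon read-count matrix
#'
#' @param counts Non-negative integer matrix, barcode rows x amplicon columns,
#'   with row and column names.
#' @return An object of class `amplicon_matrix` (the named matrix itself).
#' @export
amplicon_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry barcode row names and amplicon column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("barcode ids must be unique", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop("counts must be non-negative", call. = FALSE)
  class(counts) <- c("amplicon_matrix", class(matrix()))
  counts
}

#' @export
print.amplicon_matrix <- function(x, ...) {
  cat(sprintf("<amplicon_matrix> %d barcodes x %d amplicons, total reads %.3g\n",
              nrow(x), ncol(x), sum(as.numeric(x))))
  invisible(x)
}

# strip the S3 class for plain matrix math
unclass_matrix <- function(x) {
  x <- unclass(x)
  class(x) <- NULL
  as.matrix(x)
}
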