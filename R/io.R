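# Plain-text named-matrix container. A container is a directory holding the
# three matrices the pipeline consumes (dp.tsv, ad.tsv, amplicon_counts.tsv)
# plus the panel table and a small manifest; barcode/variant/amplicon index
# vectors travel as row and column names. TSV keeps the round trip lossless
# for integer counts and makes fixtures diffable.

CONTAINER_FILES <- c(
  dp = "dp.tsv", ad = "ad.tsv", amplicons = "amplicon_counts.tsv",
  panel = "panel.tsv", manifest = "manifest.tsv"
)

write_named_matrix <- function(m, path) {
  df <- as.data.frame(unclass_matrix(m), check.names = FALSE)
  df <- cbind(id = rownames(m), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_named_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) {
    stop("container matrix file lacks an 'id' column: ", path, call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Write a dataset container to disk
#'
#' Serialises the cell-by-variant DP/AD matrices, the barcode-by-amplicon
#' count matrix and the amplicon panel as a directory of TSV files readable
#' by [read_container()]. The write is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param cells A [cell_variant_data()] object.
#' @param amplicons An [amplicon_matrix()] object.
#' @param panel An [amplicon_panel()] table.
#' @param path Directory to create (or overwrite files within).
#' @return `path`, invisibly.
#' @export
write_container <- function(cells, amplicons, panel, path) {
  stopifnot(inherits(cells, "cell_variant_data"),
            inherits(amplicons, "amplicon_matrix"),
            inherits(panel, "amplicon_panel"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create container at ", path, call. = FALSE)
  write_named_matrix(cells$DP, file.path(path, CONTAINER_FILES[["dp"]]))
  write_named_matrix(cells$AD, file.path(path, CONTAINER_FILES[["ad"]]))
  write_named_matrix(amplicons, file.path(path, CONTAINER_FILES[["amplicons"]]))
  utils::write.table(as.data.frame(panel), file.path(path, CONTAINER_FILES[["panel"]]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(
    key = c("format", "n_barcodes", "n_variants", "n_amplicons"),
    value = c("scamp-container-v1", length(cells$barcodes),
              length(cells$variants), ncol(amplicons))
  )
  utils::write.table(manifest, file.path(path, CONTAINER_FILES[["manifest"]]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset container from disk
#'
#' @param path Directory written by [write_container()].
#' @return A list with validated elements `cells` ([cell_variant_data()]),
#'   `amplicons` ([amplicon_matrix()]) and `panel` ([amplicon_panel()]),
#'   preserving on-disk ordering.
#' @export
read_container <- function(path) {
  if (!dir.exists(path)) stop("container not found: ", path, call. = FALSE)
  for (f in CONTAINER_FILES[c("dp", "ad", "amplicons", "panel")]) {
    if (!file.exists(file.path(path, f))) {
      stop("container is missing required file: ", f, call. = FALSE)
    }
  }
  DP <- read_named_matrix(file.path(path, CONTAINER_FILES[["dp"]]))
  AD <- read_named_matrix(file.path(path, CONTAINER_FILES[["ad"]]))
  counts <- read_named_matrix(file.path(path, CONTAINER_FILES[["amplicons"]]))
  pdf <- utils::read.delim(file.path(path, CONTAINER_FILES[["panel"]]),
                           stringsAsFactors = FALSE)
  need <- c("amplicon_id", "chrom", "start", "end", "gene")
  if (!all(need %in% names(pdf))) {
    stop("panel table missing columns: ",
         paste(setdiff(need, names(pdf)), collapse = ", "), call. = FALSE)
  }
  cells <- cell_variant_data(DP, AD)
  amp <- amplicon_matrix(counts)
  if (!identical(rownames(amp), cells$barcodes)) {
    stop("barcode index of amplicon counts disagrees with DP/AD", call. = FALSE)
  }
  panel <- amplicon_panel(pdf$amplicon_id, pdf$chrom, pdf$start, pdf$end, pdf$gene)
  if (!all(colnames(amp) %in% panel$amplicon_id)) {
    stop("amplicon matrix contains amplicons absent from the panel", call. = FALSE)
  }
  list(cells = cells, amplicons = amp, panel = panel)
}

#' Read bulk-sequencing variant annotations (MAF-like TSV)
#'
#' Consumes the per-variant "fillout" values from matched bulk sequencing used
#' for germline SNP selection: one row per variant per bulk sample with the
#' bulk VAF and supporting read counts.
#'
#' Required columns: `chrom`, `pos`, `ref`, `alt`, `sample_id`, `bulk_vaf`,
#' `alt_reads`, `total_reads`, `is_normal_sample`.
#'
#' @param path Path to a tab-separated annotation table.
#' @return A data.frame of class `bulk_annotations` with a canonical
#'   `variant` id column prepended.
#' @export
read_bulk_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "sample_id", "bulk_vaf",
            "alt_reads", "total_reads", "is_normal_sample")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("bulk annotation table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    out <- cbind(data.frame(variant = character(0)), df)
    class(out) <- c("bulk_annotations", "data.frame")
    return(out)
  }
  bad <- which(!is.finite(df$bulk_vaf) | df$bulk_vaf < 0 | df$bulk_vaf > 1)
  if (length(bad)) {
    stop(sprintf("bulk_vaf out of [0,1] at line %d (value %s)",
                 bad[1L] + 1L, format(df$bulk_vaf[bad[1L]])), call. = FALSE)
  }
  bad <- which(df$total_reads > 0 &
                 abs(df$bulk_vaf - df$alt_reads / df$total_reads) > 0.01)
  if (length(bad)) {
    stop(sprintf("bulk_vaf inconsistent with alt_reads/total_reads at line %d",
                 bad[1L] + 1L), call. = FALSE)
  }
  ids <- tryCatch(
    variant_id(df$chrom, df$pos, df$ref, df$alt),
    error = function(e) stop("unparsable variant row: ", conditionMessage(e),
                             call. = FALSE)
  )
  df$is_normal_sample <- as.logical(df$is_normal_sample)
  out <- cbind(data.frame(variant = ids, stringsAsFactors = FALSE), df)
  class(out) <- c("bulk_annotations", "data.frame")
  out
}

#' Write a genotype matrix as TSV
#'
#' @param g A genotype matrix from [assign_genotypes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  write_named_matrix(g, path)
  invisible(path)
}

#' Read a genotype matrix written by [write_genotypes()]
#'
#' @param path TSV file with an `id` barcode column and one column per variant.
#' @return A character matrix with class `genotype_matrix`.
#' @export
read_genotypes <- function(path) {
  m <- read_named_matrix(path)
  ok <- m %in% c("WT", "HET", "HOM", "MISSING")
  if (!all(ok)) {
    stop("invalid genotype label(s): ",
         paste(unique(m[!ok])[1:3], collapse = ", "), call. = FALSE)
  }
  structure(m, class = c("genotype_matrix", class(matrix())))
}
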