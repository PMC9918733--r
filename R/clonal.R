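# Driver-based clonal analysis: rule-based clone assignment, genotype
# colocalization (Venn) counts, and the combined SNV + homdel feature matrix
# for multi-state clustering.

#' Declare a clone-assignment rule
#'
#' A cell matches when it carries the required driver variants (HET or HOM)
#' and is wildtype at the `required_wt` variants. `MISSING` calls satisfy
#' neither requirement. With `any_of = TRUE` carrying at least one of the
#' required carriers suffices (e.g. "any of the three drivers" definitions).
#'
#' @param clone_id Clone label.
#' @param required_carriers Variant ids the cell must carry.
#' @param required_wt Variant ids the cell must be WT at.
#' @param any_of Interpret `required_carriers` as ANY-of instead of ALL-of.
#' @return A `clone_rule` list.
#' @export
clone_rule <- function(clone_id, required_carriers = character(),
                       required_wt = character(), any_of = FALSE) {
  if (length(intersect(required_carriers, required_wt))) {
    stop("required_carriers and required_wt must be disjoint", call. = FALSE)
  }
  if (length(required_carriers) + length(required_wt) == 0L) {
    stop("rule must constrain at least one variant", call. = FALSE)
  }
  structure(list(clone_id = as.character(clone_id),
                 required_carriers = required_carriers,
                 required_wt = required_wt, any_of = isTRUE(any_of)),
            class = "clone_rule")
}

format_clone_percent <- function(fraction) {
  pct <- 100 * fraction
  ifelse(pct < 2, sprintf("%d%%", round(pct)), sprintf("%.1f%%", pct))
}

#' Assign cells to clones by ordered rules
#'
#' Rules are evaluated in order; the first matching rule claims the cell
#' (hierarchical assignment). Unmatched cells are `"unassigned"`.
#'
#' @param g A genotype matrix from [assign_genotypes()].
#' @param rules Ordered list of [clone_rule()] objects.
#' @return A `clone_assignment` list: `assignment` (named vector,
#'   cell -> clone), and `summary` (data.frame with per-clone count,
#'   fraction, and percent label formatted to one decimal, or to the nearest
#'   integer below 2%).
#' @export
assign_clones <- function(g, rules) {
  if (length(rules) == 0L) stop("no clone rules given", call. = FALSE)
  used <- unique(unlist(lapply(rules, function(r) {
    c(r$required_carriers, r$required_wt)
  })))
  miss <- setdiff(used, colnames(g))
  if (length(miss)) {
    stop("rule variant(s) absent from genotype matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(g)
  assignment <- rep("unassigned", n)
  names(assignment) <- rownames(g)
  open <- rep(TRUE, n)
  for (r in rules) {
    if (length(r$required_carriers)) {
      carr <- g[, r$required_carriers, drop = FALSE] == "HET" |
        g[, r$required_carriers, drop = FALSE] == "HOM"
      ok_carr <- if (r$any_of) rowSums(carr) >= 1L else rowSums(carr) == ncol(carr)
    } else {
      ok_carr <- rep(TRUE, n)
    }
    if (length(r$required_wt)) {
      wt <- g[, r$required_wt, drop = FALSE] == "WT"
      ok_wt <- rowSums(wt) == ncol(wt)
    } else {
      ok_wt <- rep(TRUE, n)
    }
    hit <- open & ok_carr & ok_wt
    assignment[hit] <- r$clone_id
    open <- open & !hit
  }
  labels <- c(vapply(rules, function(r) r$clone_id, character(1)), "unassigned")
  counts <- vapply(labels, function(l) sum(assignment == l), integer(1))
  summary <- data.frame(
    clone = labels, n_cells = counts, fraction = counts / n,
    percent = format_clone_percent(counts / n),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(assignment = assignment, summary = summary, n_cells = n),
            class = "clone_assignment")
}

#' @export
print.clone_assignment <- function(x, ...) {
  cat(sprintf("<clone_assignment> %d cells\n", x$n_cells))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Genotype colocalization (Venn region) counts
#'
#' For 2 or 3 query variants, counts cells by the set of variants they carry
#' (HET or HOM). Cells with a MISSING call at any query variant are excluded
#' and reported. Region names join carried variant ids with `"&"`.
#'
#' @param g A genotype matrix.
#' @param variants 2 or 3 distinct variant ids.
#' @return A `venn_counts` list: `regions` (named counts for every non-empty
#'   carrier subset), `neither`, `excluded_missing`, `n_total`.
#' @export
colocalization_counts <- function(g, variants) {
  if (anyDuplicated(variants)) stop("duplicate variant ids", call. = FALSE)
  if (!length(variants) %in% 2:3) stop("supply 2 or 3 variants", call. = FALSE)
  miss_v <- setdiff(variants, colnames(g))
  if (length(miss_v)) {
    stop("variant(s) absent from genotype matrix: ",
         paste(miss_v, collapse = ", "), call. = FALSE)
  }
  sub <- g[, variants, drop = FALSE]
  has_missing <- rowSums(sub == "MISSING") > 0L
  carrier <- (sub == "HET" | sub == "HOM")[!has_missing, , drop = FALSE]
  k <- length(variants)
  subsets <- lapply(seq_len(2^k - 1L), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
  })
  regions <- vapply(subsets, function(idx) {
    inside <- rowSums(carrier[, idx, drop = FALSE]) == length(idx)
    outside <- rowSums(carrier[, -idx, drop = FALSE]) == 0L
    sum(inside & outside)
  }, integer(1))
  names(regions) <- vapply(subsets, function(idx) {
    paste(variants[idx], collapse = "&")
  }, character(1))
  structure(list(
    regions = regions,
    neither = sum(rowSums(carrier) == 0L),
    excluded_missing = sum(has_missing),
    n_total = nrow(g),
    variants = variants
  ), class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("<venn_counts> %d cells (%d excluded for MISSING, %d carry none)\n",
              x$n_total, x$excluded_missing, x$neither))
  print(x$regions)
  invisible(x)
}

#' Build the combined SNV + homdel feature matrix
#'
#' Concatenates selected variant genotypes (4-state categorical) with
#' selected per-amplicon homozygous-deletion indicators (boolean) into a
#' single cell-by-feature data.frame suitable as input to multi-layer,
#' multi-state clustering. Feature order follows the declared order.
#'
#' @param g A genotype matrix.
#' @param variants Variant ids to include as categorical columns.
#' @param homdel Logical cell x amplicon matrix of per-cell homdel status
#'   (e.g. per-cell ploidy below the homdel threshold).
#' @param amplicons Amplicon ids to include as boolean columns.
#' @return A `multilayer_features` data.frame (cells as rows) with a
#'   `"provenance"` attribute naming each column's layer.
#' @export
build_multilayer_features <- function(g, variants, homdel, amplicons) {
  miss_v <- setdiff(variants, colnames(g))
  if (length(miss_v)) {
    stop("variant(s) absent from genotype matrix: ",
         paste(miss_v, collapse = ", "), call. = FALSE)
  }
  if (length(amplicons)) {
    miss_a <- setdiff(amplicons, colnames(homdel))
    if (length(miss_a)) {
      stop("amplicon(s) absent from homdel matrix: ",
           paste(miss_a, collapse = ", "), call. = FALSE)
    }
    if (!identical(sort(rownames(g)), sort(rownames(homdel)))) {
      stop("genotype and homdel matrices index different cell sets", call. = FALSE)
    }
    homdel <- homdel[rownames(g), , drop = FALSE]
  }
  geno_cols <- lapply(variants, function(v) {
    factor(g[, v], levels = c("WT", "HET", "HOM", "MISSING"))
  })
  names(geno_cols) <- variants
  amp_cols <- lapply(amplicons, function(a) as.logical(homdel[, a]))
  names(amp_cols) <- if (length(amplicons)) paste0("homdel_", amplicons) else character(0)
  out <- as.data.frame(c(geno_cols, amp_cols), check.names = FALSE)
  rownames(out) <- rownames(g)
  stopifnot(ncol(out) == length(variants) + length(amplicons))
  attr(out, "provenance") <- c(rep("genotype", length(variants)),
                               rep("homdel", length(amplicons)))
  class(out) <- c("multilayer_features", "data.frame")
  out
}

#' Write a multilayer feature matrix as TSV
#'
#' @param features A `multilayer_features` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  df <- cbind(cell = rownames(features), as.data.frame(features))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
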