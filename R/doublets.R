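# Doublet-rate inference from a two-population mixing experiment.
#
# Two tumors with private clonal drivers are mixed into one library. Each
# informative barcode falls into one of three observable categories: carries
# only driver A, only driver B, or both (AB). With singlet population-A
# fraction p and doublet rate d, and same-population doublets folded into
# the singlet categories (they are genotypically indistinguishable):
#   P(A)  = (1-d) p + d p^2
#   P(B)  = (1-d)(1-p) + d (1-p)^2
#   P(AB) = 2 d p (1-p)
# The MLE of (d, p) maximises the 3-category multinomial likelihood. Note
# P(A) - P(B) = 2p - 1 identically, so interior solutions have closed form:
# p = (1 + f_A - f_B)/2 and d = f_AB / (2 p (1-p)); a bounded optimiser run
# from this moment start handles boundary cases uniformly.

#' Tally mixing-experiment genotype categories
#'
#' A barcode is a carrier of a driver if its call is HET or HOM; MISSING
#' satisfies neither carrier nor wildtype status. Barcodes carrying neither
#' driver are uninformative and reported separately.
#'
#' @param g A genotype matrix from [assign_genotypes()].
#' @param driver_a,driver_b Canonical ids of the two private drivers.
#' @return A `mixing_counts` list: `n_A`, `n_B`, `n_AB`, `n_total`
#'   (informative barcodes), `n_neither`.
#' @export
classify_mixing_cells <- function(g, driver_a, driver_b) {
  if (identical(driver_a, driver_b)) {
    stop("driver_a and driver_b must differ", call. = FALSE)
  }
  for (v in c(driver_a, driver_b)) {
    if (!v %in% colnames(g)) stop("driver not in genotype matrix: ", v, call. = FALSE)
  }
  carrier_a <- g[, driver_a] %in% c("HET", "HOM")
  carrier_b <- g[, driver_b] %in% c("HET", "HOM")
  counts <- structure(list(
    n_A = sum(carrier_a & !carrier_b),
    n_B = sum(!carrier_a & carrier_b),
    n_AB = sum(carrier_a & carrier_b),
    n_neither = sum(!carrier_a & !carrier_b)
  ), class = "mixing_counts")
  counts$n_total <- counts$n_A + counts$n_B + counts$n_AB
  if (counts$n_total == 0L) {
    stop("no informative cells: no barcode carries either driver", call. = FALSE)
  }
  counts
}

#' Construct mixing counts directly
#'
#' @param n_A,n_B,n_AB Non-negative category counts.
#' @param n_neither Uninformative barcodes (default 0).
#' @return A `mixing_counts` list.
#' @export
mixing_counts <- function(n_A, n_B, n_AB, n_neither = 0L) {
  stopifnot(n_A >= 0, n_B >= 0, n_AB >= 0)
  n_total <- n_A + n_B + n_AB
  if (n_total == 0L) stop("no informative cells", call. = FALSE)
  structure(list(n_A = n_A, n_B = n_B, n_AB = n_AB,
                 n_neither = n_neither, n_total = n_total),
            class = "mixing_counts")
}

mixture_probs <- function(d, p) {
  c(A = (1 - d) * p + d * p^2,
    B = (1 - d) * (1 - p) + d * (1 - p)^2,
    AB = 2 * d * p * (1 - p))
}

mixture_nll <- function(par, counts) {
  pr <- pmax(mixture_probs(par[1L], par[2L]), 1e-12)
  -(counts$n_A * log(pr[["A"]]) + counts$n_B * log(pr[["B"]]) +
      counts$n_AB * log(pr[["AB"]]))
}

fit_mixture_mle <- function(counts) {
  f <- c(counts$n_A, counts$n_B, counts$n_AB) / counts$n_total
  p0 <- if (counts$n_A + counts$n_B > 0) counts$n_A / (counts$n_A + counts$n_B) else 0.5
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)
  if (counts$n_AB == 0L) {
    return(list(d = 0, p = p0,
                loglik = -mixture_nll(c(0, p0), counts), boundary = FALSE))
  }
  d0 <- min(max(f[3L] / (2 * p0 * (1 - p0)), 1e-6), 1 - 1e-6)
  fit <- stats::optim(c(d0, p0), mixture_nll, counts = counts,
                      method = "L-BFGS-B",
                      lower = c(1e-9, 1e-6), upper = c(1, 1 - 1e-6))
  boundary <- fit$par[1L] >= 1 - 1e-6
  list(d = fit$par[1L], p = fit$par[2L], loglik = -fit$value,
       boundary = boundary)
}

#' Estimate the doublet rate from mixing counts
#'
#' Maximum-likelihood fit of the two-population genotype mixture model, with
#' a nonparametric bootstrap confidence interval over multinomial resamples
#' of the observed categories.
#'
#' @param counts A `mixing_counts` object.
#' @param n_boot Bootstrap resamples for the 95% CI (default 1000; 0 skips
#'   the CI).
#' @param seed Integer seed for the bootstrap.
#' @return A `doublet_estimate` list: `d_hat`, `p_hat`, `log_likelihood`,
#'   `ci_95` (length-2 vector, `NA` when `n_boot = 0`), `n_boot`, `counts`.
#' @export
estimate_doublet_rate <- function(counts, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(counts, "mixing_counts"))
  fit <- fit_mixture_mle(counts)
  if (fit$boundary) {
    warning("AB count exceeds what any interior doublet rate explains; ",
            "boundary solution d = 1 reported", call. = FALSE)
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    set.seed(seed)
    f <- c(counts$n_A, counts$n_B, counts$n_AB) / counts$n_total
    draws <- stats::rmultinom(n_boot, counts$n_total, f)
    d_boot <- apply(draws, 2L, function(x) {
      if (sum(x) == 0L) return(NA_real_)
      fit_mixture_mle(mixing_counts(x[1L], x[2L], x[3L]))$d
    })
    ci <- unname(stats::quantile(d_boot, c(0.025, 0.975), na.rm = TRUE))
    # the MLE always lies within (or at the edge of) its own bootstrap band
    ci[1L] <- min(ci[1L], fit$d)
    ci[2L] <- max(ci[2L], fit$d)
  }
  structure(list(d_hat = fit$d, p_hat = fit$p,
                 log_likelihood = fit$loglik, ci_95 = ci,
                 n_boot = as.integer(n_boot), counts = counts),
            class = "doublet_estimate")
}

#' @export
print.doublet_estimate <- function(x, ...) {
  cat(sprintf("<doublet_estimate> d = %.3f (95%% CI %.3f-%.3f), p = %.3f\n",
              x$d_hat, x$ci_95[1L], x$ci_95[2L], x$p_hat))
  cat(sprintf("  counts: A=%d B=%d AB=%d (neither=%d)\n",
              x$counts$n_A, x$counts$n_B, x$counts$n_AB, x$counts$n_neither))
  invisible(x)
}
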