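#' Kendall rank correlation (tau-a) by pair enumeration
#'
#' `tau = (concordant - discordant) / (n * (n - 1) / 2)` over all pairs;
#' ties in either variable count as neither concordant nor discordant (no
#' tie correction in the denominator).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar tau in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  conc <- 0L
  disc <- 0L
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    s <- sign(dx) * sign(dy)
    conc <- conc + sum(s > 0)
    disc <- disc + sum(s < 0)
  }
  (conc - disc) / (n * (n - 1) / 2)
}

#' Benchmark Proxy Rates against reference elongation rates
#'
#' Correlates per-gene rate estimates from two methods — e.g. the Proxy
#' Rate against rates from a wavefront ("leading edge") caller consumed as
#' a plain input vector — with Pearson's correlation, Spearman's rank
#' correlation and Kendall's tau. Tau uses the tau-a convention of
#' [kendall_tau()]; p-values come from the standard large-sample references
#' of [stats::cor.test()].
#'
#' @param pairs A tibble (or data frame) with columns `reference` and
#'   `rocc`, one row per gene, no missing values, at least 3 rows.
#' @return A tibble with columns `method` (`pearson`, `spearman`,
#'   `kendall`), `estimate` and `p_value`.
#' @export
correlate_rates <- function(pairs) {
  stopifnot(all(c("reference", "rocc") %in% names(pairs)))
  x <- pairs$reference
  y <- pairs$rocc
  if (length(x) < 3) abort("need at least 3 paired rates",
                           class = "proxyrate_benchmark_error")
  if (anyNA(x) || anyNA(y)) abort("missing values in rate pairs",
                                  class = "proxyrate_benchmark_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a constant rate vector",
          class = "proxyrate_benchmark_error")
  }
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  ke <- suppressWarnings(cor.test(x, y, method = "kendall"))
  tibble::tibble(
    method = c("pearson", "spearman", "kendall"),
    estimate = c(unname(pe$estimate), unname(sp$estimate), kendall_tau(x, y)),
    p_value = c(pe$p.value, sp$p.value, ke$p.value)
  )
}
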