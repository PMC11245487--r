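#' Effective time grid for zero-intercept slope fitting
#'
#' Maps measurement times to the abscissa used for the zero-intercept
#' regression. Induced genes carry no signal before stimulation, so the 0
#' minute sample is positioned at a small positive effective time (default
#' 0.5 min); later timepoints are used as measured.
#'
#' @param timepoints Measurement times in minutes, strictly ascending
#'   (default `c(0, 5, 10)`).
#' @param t0_effective Effective time assigned to the 0 minute sample
#'   (default 0.5; must be positive and below the next timepoint).
#' @return A tibble with columns `timepoint` and `t_eff`.
#' @export
time_grid <- function(timepoints = c(0, 5, 10), t0_effective = 0.5) {
  if (is.unsorted(timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly ascending")
  }
  t_eff <- timepoints
  if (timepoints[1] == 0) {
    if (t0_effective <= 0 ||
        (length(timepoints) > 1 && t0_effective >= timepoints[2])) {
      abort("t0_effective must lie in (0, second timepoint)")
    }
    t_eff[1] <- t0_effective
  }
  tibble::tibble(timepoint = timepoints, t_eff = t_eff)
}

#' Per-bin coverage slopes by zero-intercept regression on time
#'
#' For each bin, fits the least-squares line through the origin of binned
#' coverage against effective time across all timepoints. The closed form
#' is `slope_b = sum(t * y_bt) / sum(t^2)` over effective times `t`, exact
#' for signal linear in effective time. Fixing the intercept at zero keeps
#' bins with no pre-stimulation signal interpretable.
#'
#' @param bins_by_time A list of numeric bin-value vectors (identical
#'   length), one per timepoint, in the order of `grid$timepoint`; or a
#'   matrix with bins in rows and timepoints in columns.
#' @param grid Time grid from [time_grid()].
#' @return Numeric vector of per-bin slopes (signal per bp per minute).
#' @export
rocc_global <- function(bins_by_time, grid) {
  y <- as_bin_matrix(bins_by_time)
  if (ncol(y) != nrow(grid)) {
    abort("need one bin vector per timepoint in the grid",
          class = "proxyrate_rocc_error")
  }
  t <- grid$t_eff
  drop(y %*% t) / sum(t^2)
}

#' Per-bin coverage slopes from a single timepoint
#'
#' The two-point variant: `slope_b = (y_bt - y_b0) / t`, a line through the
#' 0 minute and one later measurement. Unlike the zero-intercept fit, this
#' lets the pre-stimulation signal exert maximal influence. Signs are kept
#' here; absolute values are applied at gene-level aggregation.
#'
#' @param bins_t,bins_0 Bin-value vectors at time `t` and at 0 minutes
#'   (identical length).
#' @param t Timepoint in minutes (> 0).
#' @return Numeric vector of per-bin slopes.
#' @export
rocc_single <- function(bins_t, bins_0, t) {
  if (length(bins_t) != length(bins_0)) {
    abort("bin vectors differ in length", class = "proxyrate_rocc_error")
  }
  if (t <= 0) abort("t must be > 0", class = "proxyrate_rocc_error")
  (bins_t - bins_0) / t
}

#' Gene-level Proxy Rate from per-bin slopes
#'
#' Averages per-bin slopes over the slope-estimation region into a single
#' per-gene value. Default is the mean of absolute per-bin slopes; for
#' induced genes all slopes are nonnegative so this coincides with the
#' absolute value of the mean slope, but the two differ on noisy bins and
#' the alternative is available via `abs_before_mean = FALSE`. The Proxy
#' Rate is an elongation-rate surrogate, not a bp/min estimate.
#'
#' @param slopes Nonempty numeric vector of per-bin slopes.
#' @param abs_before_mean Take `mean(abs(slopes))` (default) rather than
#'   `abs(mean(slopes))`.
#' @return Scalar nonnegative Proxy Rate.
#' @export
gene_proxy_rate <- function(slopes, abs_before_mean = TRUE) {
  if (length(slopes) == 0L) {
    abort("empty slope vector", class = "proxyrate_rocc_error")
  }
  if (abs_before_mean) mean(abs(slopes)) else abs(mean(slopes))
}

#' Quartile-resolved Proxy Rates
#'
#' Averages absolute single-timepoint slopes within each gene-length
#' quartile. A bin belongs to the quartile containing its midpoint (in
#' gene-oriented bp from the TSS), so boundary bins are never double
#' counted; bins past the pA site fall in no quartile. An empty quartile is
#' reported as `NA` with a warning.
#'
#' @param slopes Per-bin slopes over the slope-estimation region, 5' to 3'.
#' @param gene_length Gene length in bp (TSS to pA).
#' @param region_start Gene-oriented offset of the first bin's 5' edge
#'   (default 500, the gene-body start).
#' @param bin_width Bin width in bp (default 50).
#' @param abs_before_mean See [gene_proxy_rate()].
#' @return A tibble with columns `quartile` (`"Q1"`..`"Q4"`) and `rate`.
#' @export
quartile_proxy_rate <- function(slopes, gene_length, region_start = 500,
                                bin_width = 50, abs_before_mean = TRUE) {
  mids <- region_start + (seq_along(slopes) - 0.5) * bin_width
  edges <- floor((0:4) * gene_length / 4)
  rates <- vapply(1:4, function(k) {
    sel <- mids >= edges[k] & mids < edges[k + 1]
    if (!any(sel)) return(NA_real_)
    gene_proxy_rate(slopes[sel], abs_before_mean)
  }, numeric(1))
  if (anyNA(rates)) {
    warn(paste0("quartile(s) with no bins: ",
                paste(paste0("Q", which(is.na(rates))), collapse = ", ")))
  }
  tibble::tibble(quartile = paste0("Q", 1:4), rate = rates)
}

as_bin_matrix <- function(bins_by_time) {
  if (is.matrix(bins_by_time)) return(bins_by_time)
  lens <- lengths(bins_by_time)
  if (length(unique(lens)) != 1L) {
    abort("bin counts differ across timepoints",
          class = "proxyrate_rocc_error")
  }
  do.call(cbind, bins_by_time)
}

#' Estimate Proxy Rates for a gene set from time-course coverage
#'
#' The end-to-end estimator: for each gene, extracts gene-oriented binned
#' coverage over the slope-estimation region (`TSS + pp_down` through
#' `pA + three_prime_ext`) at every timepoint, fits per-bin slopes (the
#' zero-intercept fit across all timepoints, or a two-point single-timepoint
#' fit), and averages absolute slopes into a per-gene Proxy Rate, optionally
#' resolved by gene-length quartile.
#'
#' @param tracks A tibble with columns `timepoint` and a list-column `track`
#'   of coverage tibbles (one per timepooint, e.g. one condition's slice of
#'   a [simulate_wavefront_timecourse()] result), or a list of tracks named
#'   by timepoint.
#' @param genes Gene-model tibble.
#' @param variant `"global"` (default, zero-intercept fit over all
#'   timepoints) or `"single"` (two-point fits against 0 min, one per
#'   nonzero timepoint).
#' @param timepoints Measurement times in minutes; defaults to those in
#'   `tracks`.
#' @param t0_effective Effective time of the 0 min sample for the global
#'   fit (default 0.5).
#' @param bin_width Bin width in bp (default 50).
#' @param pp_down Gene-oriented start of the slope region, bp from TSS
#'   (default 500).
#' @param three_prime_ext Extension past the pA site in bp (default 3000).
#' @param quartiles Also compute per-quartile rates (default `FALSE`;
#'   applied to single-timepoint variants, where per-quartile kinetics are
#'   interpretable).
#' @param abs_before_mean See [gene_proxy_rate()].
#' @param condition Optional condition label carried into the result.
#' @return An object of class `proxy_rate_fit` with elements `rates`
#'   (tibble: `condition`, `gene_id`, `variant`, `proxy_rate`, `n_bins`),
#'   `slopes` (long tibble of per-bin slopes), `quartiles` (tibble or
#'   `NULL`) and `params`.
#' @export
estimate_proxy_rate <- function(tracks, genes,
                                variant = c("global", "single"),
                                timepoints = NULL, t0_effective = 0.5,
                                bin_width = 50, pp_down = 500,
                                three_prime_ext = 3000, quartiles = FALSE,
                                abs_before_mean = TRUE,
                                condition = NA_character_) {
  variant <- match.arg(variant)
  validate_genes(genes)
  if (is.data.frame(tracks)) {
    stopifnot(all(c("timepoint", "track") %in% names(tracks)))
    track_list <- setNames(tracks$track, tracks$timepoint)
  } else {
    track_list <- tracks
  }
  tps <- timepoints %||% as.numeric(names(track_list))
  if (anyNA(tps)) abort("timepoints could not be inferred from tracks")
  ord <- order(tps)
  tps <- tps[ord]
  track_list <- track_list[ord]
  grid <- time_grid(tps, t0_effective)

  per_gene <- purrr::pmap(genes, function(gene_id, chrom, strand, tss, pa,
                                          length) {
    gi <- oriented_interval(tss, strand, pp_down, length + three_prime_ext)
    y <- purrr::map(track_list, function(trk) {
      bin_coverage(trk, chrom, gi[1], gi[2], strand, bin_width)$value
    })
    ymat <- as_bin_matrix(y)
    fits <- if (variant == "global") {
      list(global = rocc_global(ymat, grid))
    } else {
      later <- which(tps > 0)
      setNames(
        purrr::map(later, function(i) {
          rocc_single(ymat[, i], ymat[, which(tps == 0)[1]], tps[i])
        }),
        paste0("single_", tps[later])
      )
    }
    list(gene_id = gene_id, length = length, fits = fits)
  })

  slopes <- purrr::map_dfr(per_gene, function(g) {
    purrr::imap_dfr(g$fits, function(sl, vn) {
      tibble::tibble(condition = condition, gene_id = g$gene_id,
                     variant = vn, bin = seq_along(sl),
                     offset = pp_down + (seq_along(sl) - 1) * bin_width,
                     slope = sl)
    })
  })
  rates <- slopes |>
    dplyr::group_by(.data$condition, .data$gene_id, .data$variant) |>
    dplyr::summarise(
      proxy_rate = if (abs_before_mean) mean(abs(.data$slope)) else
        abs(mean(.data$slope)),
      n_bins = dplyr::n(),
      .groups = "drop"
    )
  quart <- NULL
  if (quartiles) {
    quart <- purrr::map_dfr(per_gene, function(g) {
      purrr::imap_dfr(g$fits, function(sl, vn) {
        quartile_proxy_rate(sl, g$length, region_start = pp_down,
                            bin_width = bin_width,
                            abs_before_mean = abs_before_mean) |>
          dplyr::mutate(condition = condition, gene_id = g$gene_id,
                        variant = vn, .before = 1)
      })
    })
  }
  structure(
    list(rates = rates, slopes = slopes, quartiles = quart,
         params = list(variant = variant, timepoints = tps,
                       t0_effective = t0_effective, bin_width = bin_width,
                       pp_down = pp_down, three_prime_ext = three_prime_ext,
                       abs_before_mean = abs_before_mean)),
    class = "proxy_rate_fit"
  )
}

#' @export
print.proxy_rate_fit <- function(x, ...) {
  cat(sprintf(
    "<proxy_rate_fit> %d gene(s), variant '%s', bin width %d bp\n",
    dplyr::n_distinct(x$rates$gene_id), x$params$variant,
    as.integer(x$params$bin_width)
  ))
  print(x$rates, n = 6)
  invisible(x)
}

#' Tidy a Proxy Rate fit
#'
#' @param x A `proxy_rate_fit`.
#' @param ... Unused.
#' @return The per-gene rate tibble (`condition`, `gene_id`, `variant`,
#'   `proxy_rate`, `n_bins`), with quartile rates joined in wide form when
#'   present.
#' @export
tidy.proxy_rate_fit <- function(x, ...) {
  out <- x$rates
  if (!is.null(x$quartiles)) {
    qw <- tidyr::pivot_wider(x$quartiles, names_from = "quartile",
                             values_from = "rate")
    out <- dplyr::left_join(out, qw,
                            by = c("condition", "gene_id", "variant"))
  }
  out
}

#' One-row summary of a Proxy Rate fit
#'
#' @param x A `proxy_rate_fit`.
#' @param ... Unused.
#' @return A tibble with one row per variant: gene count, median and mean
#'   Proxy Rate.
#' @export
glance.proxy_rate_fit <- function(x, ...) {
  x$rates |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      n_genes = dplyr::n_distinct(.data$gene_id),
      median_proxy_rate = median(.data$proxy_rate),
      mean_proxy_rate = mean(.data$proxy_rate),
      .groups = "drop"
    )
}

#' Plot per-gene Proxy Rates
#'
#' @param object A `proxy_rate_fit`.
#' @param ... Unused.
#' @return A ggplot: Tukey boxplots of Proxy Rates per variant (and
#'   condition, when labelled).
#' @export
autoplot.proxy_rate_fit <- function(object, ...) {
  d <- object$rates
  d$grp <- if (all(is.na(d$condition))) d$variant else
    paste(d$condition, d$variant)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$grp, y = .data$proxy_rate)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = "Proxy Rate (signal/bp/min)") +
    ggplot2::theme_minimal()
}
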