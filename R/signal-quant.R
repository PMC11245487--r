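#' Mean per-bp density over genomic regions
#'
#' Computes the per-bp mean signal of a coverage track over each region of a
#' region tibble (e.g. from [derive_regions()]). Equivalent to
#' [bin_coverage()] with one full-region bin, so the value is comparable
#' across regions of different widths.
#'
#' @param track Coverage-track tibble.
#' @param regions Region tibble with `gene_id`, `chrom`, `strand`, `start`,
#'   `end` and optionally `region`/`quartile` labels (carried through).
#' @return `regions` with an added `density` column (mean signal per bp,
#'   >= 0 for nonnegative tracks).
#' @export
region_density <- function(track, regions) {
  if (any(regions$end <= regions$start)) {
    abort("empty region", class = "proxyrate_quant_error")
  }
  dens <- purrr::pmap_dbl(
    list(regions$chrom, regions$start, regions$end),
    function(chrom, start, end) {
      bin_sums(track, chrom, start, end, "+", end - start, 1L,
               end - start) / (end - start)
    }
  )
  dplyr::mutate(regions, density = dens)
}

#' Log2 fold change between condition densities
#'
#' `log2((density + eps) / (reference + eps))` with a small pseudocount so
#' the ratio stays finite for zero densities; antisymmetric in its
#' arguments and zero when both densities vanish.
#'
#' @param density,reference Nonnegative density vectors (recycled).
#' @param eps Pseudocount in density units (default 0.01).
#' @return Numeric vector of log2 fold changes.
#' @export
condition_log2fc <- function(density, reference, eps = 0.01) {
  if (any(density < 0) || any(reference < 0)) {
    abort("densities must be nonnegative", class = "proxyrate_quant_error")
  }
  log2((density + eps) / (reference + eps))
}

#' Median percent change of a log2 fold-change set
#'
#' Converts each gene's log2 fold change to a percent change
#' (`(2^log2fc - 1) * 100`) and returns the median, the summary used to
#' report cluster-level occupancy or expression shifts.
#'
#' @param log2fc Nonempty numeric vector.
#' @return The median percent change (scalar).
#' @export
median_percent_change <- function(log2fc) {
  if (length(log2fc) == 0L) abort("empty log2fc vector")
  median((2^log2fc - 1) * 100)
}

#' Tukey five-number summary with whiskers and outliers
#'
#' Median and quartiles (linear-interpolation quantiles, type 7) plus Tukey
#' whiskers: the most extreme data point within 1.5 interquartile ranges of
#' the box. Values beyond the whiskers are returned as outliers.
#'
#' @param values Nonempty numeric vector.
#' @return A list with a one-row tibble `summary` (`median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`) and a numeric vector `outliers`.
#' @export
five_number_summary <- function(values) {
  if (length(values) == 0L) abort("empty vector")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(
    summary = tibble::tibble(
      median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = min(inside), whisker_high = max(inside)
    ),
    outliers = values[values < lo_fence | values > hi_fence]
  )
}

#' Scaled-body metagene matrix
#'
#' Builds a per-gene profile matrix in the scale-regions layout: an
#' upstream flank binned at `flank_bin` bp, the gene body `[TSS, pA)`
#' rescaled to `body_bins` near-equal segments (per-bp mean within each),
#' and a downstream flank. Minus-strand genes are reversed so every row
#' reads 5' to 3' left to right. Genes shorter than `body_bins` bp are
#' excluded with a warning.
#'
#' @param track Coverage-track tibble.
#' @param genes Gene-model tibble.
#' @param body_bins Number of scaled body segments (default 100).
#' @param flank Flank extent in bp on each side (default 2000).
#' @param flank_bin Flank bin width in bp (default 50).
#' @return An object of class `metagene_matrix`: a list with `profile`
#'   (long tibble: `gene_id`, `position` (bin index across the full row),
#'   `segment` (`upstream`/`body`/`downstream`), `value`) and
#'   `mean_profile` (the column-mean profile).
#' @export
metagene_matrix <- function(track, genes, body_bins = 100, flank = 2000,
                            flank_bin = 50) {
  validate_genes(genes)
  stopifnot(body_bins >= 1, flank >= 0, flank_bin >= 1)
  short <- genes$length < body_bins
  if (any(short)) {
    warn(paste0("excluding gene(s) shorter than body_bins bp: ",
                paste(genes$gene_id[short], collapse = ", ")))
    genes <- genes[!short, , drop = FALSE]
  }
  if (nrow(genes) == 0L) abort("no genes long enough for metagene")
  n_flank <- if (flank > 0) ceiling(flank / flank_bin) else 0L

  profile <- purrr::pmap_dfr(genes, function(gene_id, chrom, strand, tss,
                                             pa, length) {
    # upstream flank: gene-oriented offsets [-flank, 0)
    up <- if (n_flank > 0) {
      gi <- oriented_interval(tss, strand, -flank, 0)
      bin_coverage(track, chrom, gi[1], gi[2], strand, flank_bin)$value
    } else numeric(0)
    # body: near-equal segments with floor boundaries
    edges <- floor((0:body_bins) * length / body_bins)
    body <- vapply(seq_len(body_bins), function(k) {
      gi <- oriented_interval(tss, strand, edges[k], edges[k + 1])
      wk <- gi[2] - gi[1]
      bin_sums(track, chrom, gi[1], gi[2], strand, wk, 1L, wk) / wk
    }, numeric(1))
    dn <- if (n_flank > 0) {
      gi <- oriented_interval(tss, strand, length, length + flank)
      bin_coverage(track, chrom, gi[1], gi[2], strand, flank_bin)$value
    } else numeric(0)
    vals <- c(up, body, dn)
    tibble::tibble(
      gene_id = gene_id,
      position = seq_along(vals),
      segment = rep(c("upstream", "body", "downstream"),
                    c(length(up), body_bins, length(dn))),
      value = vals
    )
  })

  mean_profile <- profile |>
    dplyr::group_by(.data$position, .data$segment) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$position)

  structure(list(profile = profile, mean_profile = mean_profile,
                 body_bins = body_bins, flank = flank,
                 flank_bin = flank_bin),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf(
    "<metagene_matrix> %d genes, %d positions (%d body bins, %d bp flanks)\n",
    dplyr::n_distinct(x$profile$gene_id), max(x$profile$position),
    x$body_bins, x$flank
  ))
  invisible(x)
}

#' Plot a metagene profile
#'
#' @param object A `metagene_matrix`.
#' @param ... Unused.
#' @return A ggplot of the column-mean profile with segment boundaries.
#' @export
autoplot.metagene_matrix <- function(object, ...) {
  mp <- object$mean_profile
  bounds <- cumsum(rle(mp$segment)$lengths)
  ggplot2::ggplot(mp, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = utils::head(bounds, -1) + 0.5,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "metagene position (5' → 3')",
                  y = "mean signal (per bp)") +
    ggplot2::theme_minimal()
}
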