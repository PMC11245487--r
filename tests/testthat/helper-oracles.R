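# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use per-base expansion and generic
# numeric optimization, not the closed forms under test.

# Expand a track to a per-base signal vector over [start, end) in gene
# orientation (reversed for '-' strand), then average into bins.
per_base_vector <- function(track, chrom, start, end, strand = "+") {
  w <- end - start
  x <- numeric(w)
  iv <- track[track$chrom == chrom & track$end > start & track$start < end, ]
  if (nrow(iv) > 0) {
    for (i in seq_len(nrow(iv))) {
      s <- max(iv$start[i], start)
      e <- min(iv$end[i], end)
      x[(s - start + 1):(e - start)] <- x[(s - start + 1):(e - start)] + iv$value[i]
      # note: half-open, positions s..e-1, 1-based index s-start+1 .. e-start
    }
  }
  if (strand == "-") rev(x) else x
}

brute_bin_means <- function(track, chrom, start, end, strand = "+",
                            bin_width = 50) {
  x <- per_base_vector(track, chrom, start, end, strand)
  nb <- ceiling(length(x) / bin_width)
  vapply(seq_len(nb), function(k) {
    idx <- ((k - 1) * bin_width + 1):min(k * bin_width, length(x))
    mean(x[idx])
  }, numeric(1))
}

# Zero-intercept least squares via the generic QR solver (no intercept
# column), independent of the closed form under test.
numeric_origin_slope <- function(y, t) {
  unname(stats::lm.fit(x = cbind(t), y = y)$coefficients[1])
}

# Kendall tau-a by exhaustive enumeration of all unordered pairs.
brute_kendall <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- (x[j] - x[i]) * (y[j] - y[i])
    if (p > 0) conc <- conc + 1
    if (p < 0) disc <- disc + 1
  }
  (conc - disc) / choose(n, 2)
}

# Random sparse coverage track on one chromosome.
random_track <- function(n_iv = 30, span = 5000, chrom = "chr1") {
  starts <- sort(sample.int(span, n_iv))
  widths <- sample(1:80, n_iv, replace = TRUE)
  ends <- starts + widths
  # enforce non-overlap by clipping each start to the previous end
  for (i in seq_len(n_iv)[-1]) {
    if (starts[i] < ends[i - 1]) starts[i] <- ends[i - 1]
    if (starts[i] >= ends[i]) ends[i] <- starts[i] + 1
  }
  tibble::tibble(chrom = chrom, start = starts, end = ends,
                 value = round(stats::runif(n_iv, 0, 10), 3))
}

toy_genes <- function(...) make_toy_annotation(...)
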