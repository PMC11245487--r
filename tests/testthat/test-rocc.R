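test_that("time grid maps 0 min to a positive effective time", {
  g <- time_grid()
  expect_equal(g$timepoint, c(0, 5, 10))
  expect_equal(g$t_eff, c(0.5, 5, 10))
  expect_error(time_grid(c(5, 0, 10)), "ascending")
  expect_error(time_grid(c(0, 5), t0_effective = 6), "t0_effective")
  expect_error(time_grid(c(0, 5), t0_effective = 0), "t0_effective")
})

test_that("zero-intercept slopes match the closed form and numeric oracle", {
  grid <- time_grid()
  expect_equal(rocc_global(matrix(c(1, 10, 20), 1), grid), 2.0)
  expect_equal(rocc_global(matrix(0, 1, 3), grid), 0.0)
  s <- rocc_global(matrix(c(0, 5, 10), 1), grid)
  expect_equal(s, 125 / 125.25)
  expect_equal(s, numeric_origin_slope(c(0, 5, 10), grid$t_eff),
               tolerance = 1e-10)
  expect_error(rocc_global(list(1:3, 1:4), grid), "bin counts")
  expect_error(rocc_global(matrix(0, 2, 2), grid), "per timepoint")
})

test_that("zero-intercept slopes equal generic least squares on random series", {
  grid <- time_grid()
  withr::local_seed(206)
  y <- matrix(stats::runif(1000 * 3, 0, 50), 1000, 3)
  got <- rocc_global(y, grid)
  want <- apply(y, 1, numeric_origin_slope, t = grid$t_eff)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("single-timepoint slopes are two-point rises over run", {
  expect_equal(rocc_single(7, 2, 5), 1.0)
  expect_equal(rocc_single(5, 0, 10), 0.5)
  expect_equal(rocc_single(0, 5, 5), -1.0)  # sign kept until aggregation
  expect_error(rocc_single(1, 1, 0), "t must be")
  expect_error(rocc_single(1:3, 1:2, 5), "length")
})

test_that("the two variants agree in the small-effective-t0 limit", {
  withr::local_seed(9)
  y5 <- stats::runif(40, 0, 10)
  for (t0 in c(0.5, 0.05, 1e-6)) {
    g <- time_grid(c(0, 5), t0_effective = t0)
    glob <- rocc_global(cbind(0, y5), g)
    sing <- rocc_single(y5, rep(0, 40), 5)
    expect_equal(glob, sing * 25 / (t0^2 + 25))
  }
  g <- time_grid(c(0, 5), t0_effective = 1e-9)
  expect_equal(rocc_global(cbind(0, y5), g), rocc_single(y5, rep(0, 40), 5),
               tolerance = 1e-12)
})

test_that("gene proxy rate averages absolute slopes and scales linearly", {
  expect_equal(gene_proxy_rate(c(1, -1)), 1.0)
  expect_equal(gene_proxy_rate(c(1, -1), abs_before_mean = FALSE), 0.0)
  expect_equal(gene_proxy_rate(rep(0, 10)), 0.0)
  expect_error(gene_proxy_rate(numeric(0)), "empty")
  withr::local_seed(4)
  sl <- stats::rnorm(30)
  expect_equal(gene_proxy_rate(3.7 * sl), 3.7 * gene_proxy_rate(sl))
})

test_that("quartile rates assign bins by midpoint without double counting", {
  # 10-kb gene, region from +500: 250 bins of 50 bp; quartiles of 2500 bp
  slopes <- rep(1, 250)
  q <- quartile_proxy_rate(slopes, 10000)
  expect_equal(q$rate, rep(1, 4))

  mids <- 500 + (seq_along(slopes) - 0.5) * 50
  sl2 <- ifelse(mids < 2500, 2, 0.5)
  q2 <- quartile_proxy_rate(sl2, 10000)
  expect_equal(q2$rate[1], 2)
  expect_equal(q2$rate[4], 0.5)
  # every bin with midpoint inside [0, L) lands in exactly one quartile
  edges <- floor(0:4 * 10000 / 4)
  counts <- vapply(1:4, function(k)
    sum(mids >= edges[k] & mids < edges[k + 1]), numeric(1))
  expect_equal(sum(counts), sum(mids < 10000))

  expect_warning(q3 <- quartile_proxy_rate(rep(1, 2), 10000), "no bins")
  expect_true(anyNA(q3$rate))
})

test_that("correlation report covers Pearson, Spearman and tau-a", {
  perf <- tibble::tibble(reference = c(1, 2, 3), rocc = c(2, 4, 6))
  r <- correlate_rates(perf)
  expect_equal(r$estimate, rep(1, 3))
  rev_ <- tibble::tibble(reference = c(1, 2, 3), rocc = c(3, 2, 1))
  expect_equal(correlate_rates(rev_)$estimate, rep(-1, 3))

  swap <- tibble::tibble(reference = c(1, 2, 3), rocc = c(1, 3, 2))
  tau <- correlate_rates(swap)$estimate[3]
  expect_equal(tau, 1 / 3)
  expect_equal(tau, brute_kendall(swap$reference, swap$rocc))

  withr::local_seed(62)
  x <- stats::rnorm(25)
  y <- x + stats::rnorm(25)
  r2 <- correlate_rates(tibble::tibble(reference = x, rocc = y))
  expect_equal(r2$estimate[1], cor(x, y))
  expect_equal(r2$estimate[2], cor(x, y, method = "spearman"))
  expect_equal(r2$estimate[3], brute_kendall(x, y))
  expect_true(all(r2$p_value >= 0 & r2$p_value <= 1))

  expect_error(correlate_rates(tibble::tibble(reference = c(1, 1, 1),
                                              rocc = 1:3)), "constant")
  expect_error(correlate_rates(tibble::tibble(reference = 1:2, rocc = 1:2)),
               "at least 3")
})

test_that("the full estimator recovers linear-in-time signal exactly", {
  # constant plateau growing linearly in effective time: y = 2 * t_eff
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                          tss = 1000, pa = 6000, length = 5000)
  mk <- function(v) tibble::tibble(chrom = "chr1", start = 0, end = 10000,
                                   value = v)
  tracks <- tibble::tibble(
    timepoint = c(0, 5, 10),
    track = list(mk(2 * 0.5), mk(2 * 5), mk(2 * 10))
  )
  fit <- estimate_proxy_rate(tracks, genes)
  expect_equal(fit$rates$proxy_rate, 2.0)
  expect_equal(unique(fit$slopes$slope), 2.0)
  # slope region = [TSS+500, pA+3000): 7500 bp -> 150 bins
  expect_equal(fit$rates$n_bins, 150)

  # single-timepoint variant yields one fit per nonzero timepoint
  fs <- estimate_proxy_rate(tracks, genes, variant = "single")
  expect_setequal(unique(fs$rates$variant), c("single_5", "single_10"))
  expect_equal(fs$rates$proxy_rate[fs$rates$variant == "single_5"],
               (10 - 1) / 5)

  # scale equivariance of the end-to-end estimate
  tracks3 <- dplyr::mutate(tracks,
                           track = purrr::map(track, ~ dplyr::mutate(.x, value = 3 * value)))
  fit3 <- estimate_proxy_rate(tracks3, genes)
  expect_equal(fit3$rates$proxy_rate, 3 * fit$rates$proxy_rate)
})

test_that("proxy rate increases with true elongation rate on simulations", {
  genes <- toy_genes(6, seed = 2)
  rates <- purrr::map_dbl(c(500, 1000, 2000, 4000), function(v) {
    sim <- simulate_wavefront_timecourse(
      genes, tibble::tibble(condition = "c", v = v, beta = 2), seed = 1
    )
    median(estimate_proxy_rate(sim$tracks, genes)$rates$proxy_rate)
  })
  expect_true(all(diff(rates) > 0))
})

test_that("tidy, glance and quartile output expose the fit", {
  genes <- toy_genes(3, seed = 6)
  sim <- simulate_wavefront_timecourse(
    genes, tibble::tibble(condition = "c", v = 1500, beta = 2), seed = 3
  )
  fit <- estimate_proxy_rate(sim$tracks, genes, variant = "single",
                             quartiles = TRUE, condition = "c")
  td <- tidy(fit)
  expect_true(all(c("Q1", "Q2", "Q3", "Q4") %in% names(td)))
  expect_equal(nrow(td), 3 * 2)
  gl <- glance(fit)
  expect_equal(gl$n_genes, rep(3, 2))
  expect_true(all(gl$median_proxy_rate >= 0))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
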