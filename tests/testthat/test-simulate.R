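one_cond <- function(...) {
  tibble::tibble(condition = "c", v = 1000, beta = 2, ...)
}

test_that("the wavefront sits at v*t with plateau behind and basal ahead", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                          tss = 10000, pa = 20000, length = 10000)
  sim <- simulate_wavefront_timecourse(genes, one_cond(), seed = 1)
  e5 <- dplyr::filter(sim$expected, timepoint == 5)
  # v = 1000 bp/min, t = 5 -> front at 5000 bp
  expect_equal(e5$expected[e5$offset + e5$width <= 5000],
               rep(2, sum(e5$offset + e5$width <= 5000)))
  expect_equal(e5$expected[e5$offset >= 5000],
               rep(0, sum(e5$offset >= 5000)))
  # time 0 emits basal-only signal
  e0 <- dplyr::filter(sim$expected, timepoint == 0)
  expect_equal(e0$expected, rep(0, nrow(e0)))
  # noiseless: observed track equals the expectation exactly
  t5 <- sim$tracks$track[sim$tracks$timepoint == 5][[1]]
  expect_equal(bin_coverage(t5, "chr1", 10000, 23000, "+", 50)$value[1:100],
               rep(2, 100))
})

test_that("3' pileup multiplies the plateau past the pA site", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                          tss = 0, pa = 5000, length = 5000)
  sim <- simulate_wavefront_timecourse(
    genes, one_cond(pileup_gain = 3), timepoints = c(0, 10), seed = 1
  )
  e10 <- dplyr::filter(sim$expected, timepoint == 10)  # front at 10000
  expect_equal(unique(e10$expected[e10$offset >= 5000]), 6)
  expect_equal(unique(e10$expected[e10$offset + e10$width <= 5000]), 2)
})

test_that("poisson noise has the stated per-bin mean", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                          tss = 0, pa = 10000, length = 10000)
  sim <- simulate_wavefront_timecourse(
    genes, one_cond(noise = "poisson", noise_scale = 100),
    timepoints = c(0, 10), seed = 42
  )
  t10 <- sim$tracks$track[sim$tracks$timepoint == 10][[1]]
  vals <- bin_coverage(t10, "chr1", 0, 5000, "+", 50)$value  # 100 bins behind front
  # per-bin counts ~ Poisson(100); their mean over 100 bins has sd
  # sqrt(100)/sqrt(100) = 1 count, i.e. 0.02 density units
  counts <- vals * 100 / 2
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100) / sqrt(100))
  expect_lt(abs(mean(vals) - 2), 3 * 0.02)
})

test_that("identical seeds give byte-identical bedGraph output", {
  genes <- toy_genes(3, seed = 5)
  conds <- one_cond(noise = "poisson", noise_scale = 50)
  p1 <- withr::local_tempfile(fileext = ".bedGraph")
  p2 <- withr::local_tempfile(fileext = ".bedGraph")
  s1 <- simulate_wavefront_timecourse(genes, conds, seed = 99)
  s2 <- simulate_wavefront_timecourse(genes, conds, seed = 99)
  write_bedgraph(s1$tracks$track[[2]], p1)
  write_bedgraph(s2$tracks$track[[2]], p2)
  expect_identical(readLines(p1), readLines(p2))
  s3 <- simulate_wavefront_timecourse(genes, conds, seed = 100)
  expect_false(identical(s1$tracks$track[[2]], s3$tracks$track[[2]]))
})

test_that("positions above basal only ever grow with time", {
  genes <- toy_genes(4, seed = 8)
  sim <- simulate_wavefront_timecourse(genes, one_cond(), seed = 1)
  wide <- tidyr::pivot_wider(sim$expected,
                             id_cols = c("gene_id", "bin"),
                             names_from = "timepoint",
                             values_from = "expected")
  expect_true(all(wide$`5`[wide$`0` > 0] > 0))
  expect_true(all(wide$`10`[wide$`5` > 0] > 0))
})

test_that("overlapping emitted spans are rejected", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          strand = "+", tss = c(0, 5000),
                          pa = c(10000, 15000), length = 10000)
  expect_error(simulate_wavefront_timecourse(genes, one_cond(), seed = 1),
               "overlap")
})

test_that("DE tables are emitted with the requested composition", {
  spec <- tibble::tibble(label = "16fold", n = 5, lfc_min = 4, lfc_max = 5)
  de <- simulate_de_table(5, spec, seed = 1)
  cl <- assign_clusters(de$table)
  expect_equal(as.character(cl$label), rep("16fold", 5))

  empty <- simulate_de_table(0, tibble::tibble(label = character(),
                                               n = integer()), seed = 1)
  expect_equal(nrow(empty$table), 0)

  mixed <- simulate_de_table(
    20, tibble::tibble(label = c("2fold", "nonDE"), n = c(10, 10)), seed = 2
  )
  cl2 <- assign_clusters(mixed$table)
  # brute-force re-filter of the emitted table
  expect_equal(sum(mixed$table$log2fc >= 1), 10)
  expect_equal(sum(abs(mixed$table$log2fc) < log2(1.4)), 10)
  expect_equal(sum(cl2$member_2fold), 10)
  expect_equal(sum(cl2$label == "nonDE"), 10)

  expect_error(
    simulate_de_table(5, tibble::tibble(label = "16fold", n = 5,
                                        lfc_min = 1, lfc_max = 2), seed = 1),
    "inconsistent"
  )
})

test_that("toy annotations are valid, seeded and respect the length floor", {
  g <- make_toy_annotation(20, minus_fraction = 0.5, seed = 12)
  expect_silent(validate_genes(g))
  expect_identical(g, make_toy_annotation(20, minus_fraction = 0.5,
                                          seed = 12))
  n_minus <- sum(g$strand == "-")
  expect_gt(n_minus, 3)
  expect_lt(n_minus, 17)
  path <- withr::local_tempfile(fileext = ".bed")
  write_gene_bed(g, path)
  expect_equal(read_gene_bed(path), g[order(g$gene_id), ])
  expect_error(make_toy_annotation(2, length_range = c(500, 900)), "1 kb")
})
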