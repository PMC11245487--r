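#' Simulate serum-induction wavefront coverage time courses
#'
#' Generates per-timepoint coverage tracks with the structure the elongation
#' analysis assumes: genes silent (basal density) before stimulation, then a
#' polymerase wave entering the gene body and advancing at a known
#' elongation rate `v` bp/min, plateau density `beta` behind the sharp
#' front, an optional multiplicative pileup beyond the pA site, and optional
#' Poisson count noise per bin rescaled to density. The gene-oriented
#' expected density at offset `x` bp from the TSS and time `t` min is
#' `basal` if `x > v * t`, otherwise `beta` (`beta * pileup_gain` past the
#' pA site); within-bin expectations are exact integrals of this piecewise
#' profile. Identical seeds and parameters reproduce identical tracks.
#'
#' @param genes Gene-model tibble ([read_gene_bed()], [make_toy_annotation()]).
#'   Emitted gene spans (`[TSS, pA + three_prime_ext)` in gene orientation)
#'   must not overlap.
#' @param conditions A tibble with one row per condition: `condition` (name),
#'   `v` (bp/min, > 0), `beta` (plateau density, signal/bp) — either scalars
#'   or list-column entries holding one value per gene — and optionally
#'   `basal` (default 0), `pileup_gain` (>= 1, default 1), `noise`
#'   (`"none"` or `"poisson"`, default `"none"`) and `noise_scale`
#'   (expected counts per full bin at density `beta`, default 100).
#' @param timepoints Measurement times in minutes, ascending, starting at 0
#'   (default `c(0, 5, 10)`).
#' @param three_prime_ext Simulated extent past the pA site in bp
#'   (default 3000).
#' @param bin_width Simulation bin width in bp (default 50).
#' @param seed Integer seed; all randomness is local to the call.
#' @return A list with elements `tracks` (a nested tibble: `condition`,
#'   `timepoint`, list-column `track` of coverage tibbles), `truth`
#'   (per-gene/condition true parameters) and `expected` (per-bin noiseless
#'   expected density at each timepoint).
#' @export
simulate_wavefront_timecourse <- function(genes, conditions,
                                          timepoints = c(0, 5, 10),
                                          three_prime_ext = 3000,
                                          bin_width = 50, seed = 1L) {
  validate_genes(genes)
  conditions <- tibble::as_tibble(conditions)
  if (!all(c("condition", "v", "beta") %in% names(conditions))) {
    abort("conditions needs columns condition, v, beta")
  }
  defaults <- list(basal = 0, pileup_gain = 1, noise = "none",
                   noise_scale = 100)
  for (nm in names(defaults)) {
    if (!nm %in% names(conditions)) conditions[[nm]] <- defaults[[nm]]
  }
  stopifnot(all(unlist(conditions$v) > 0), all(unlist(conditions$beta) >= 0),
            all(conditions$pileup_gain >= 1),
            all(conditions$noise %in% c("none", "poisson")))
  if (is.unsorted(timepoints, strictly = TRUE) || timepoints[1] != 0) {
    abort("timepoints must be strictly ascending and include 0")
  }

  # emitted genomic spans must not collide
  spans <- purrr::pmap_dfr(genes, function(gene_id, chrom, strand, tss, pa,
                                           length) {
    gi <- oriented_interval(tss, strand, 0, length + three_prime_ext)
    tibble::tibble(gene_id = gene_id, chrom = chrom, start = gi[1],
                   end = gi[2])
  }) |> dplyr::arrange(.data$chrom, .data$start)
  same <- spans$chrom[-1] == spans$chrom[-nrow(spans)]
  if (nrow(spans) > 1L && any(same & spans$start[-1] < spans$end[-nrow(spans)])) {
    abort("emitted gene spans overlap; space genes further apart",
          class = "proxyrate_sim_error")
  }

  withr::with_seed(seed, {
    per_cond <- purrr::pmap(conditions, function(condition, v, beta, basal,
                                                 pileup_gain, noise,
                                                 noise_scale, ...) {
      # v and beta may be per-gene vectors (list-column entries) or scalars
      v_g <- rep_len(unlist(v), nrow(genes))
      beta_g <- rep_len(unlist(beta), nrow(genes))
      per_gene <- purrr::map(seq_len(nrow(genes)), function(i) {
        g <- genes[i, ]
        w_total <- g$length + three_prime_ext
        nb <- ceiling(w_total / bin_width)
        off <- (seq_len(nb) - 1) * bin_width
        wid <- pmin(bin_width, w_total - off)
        per_tp <- purrr::map(timepoints, function(t) {
          exp_d <- wavefront_bin_expectation(off, wid, v_g[i] * t, g$length,
                                             beta_g[i], basal, pileup_gain)
          if (noise == "poisson") {
            frac <- wid / bin_width
            mu <- noise_scale * (exp_d / max(beta_g[i], .Machine$double.eps)) *
              frac
            k <- rpois(nb, mu)
            obs <- k * beta_g[i] / (noise_scale * frac)
          } else {
            obs <- exp_d
          }
          list(expected = exp_d, observed = obs)
        })
        list(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             tss = g$tss, off = off, wid = wid, per_tp = per_tp)
      })
      list(condition = condition, v = v_g, beta = beta_g, basal = basal,
           pileup_gain = pileup_gain, noise = noise,
           noise_scale = noise_scale, per_gene = per_gene)
    })

    tracks <- purrr::map_dfr(per_cond, function(pc) {
      purrr::map_dfr(seq_along(timepoints), function(ti) {
        trk <- purrr::map_dfr(pc$per_gene, function(g) {
          vals <- g$per_tp[[ti]]$observed
          keep <- vals != 0
          if (!any(keep)) return(tibble::tibble())
          a <- g$off[keep]
          b <- g$off[keep] + g$wid[keep]
          if (g$strand == "+") {
            tibble::tibble(chrom = g$chrom, start = g$tss + a,
                           end = g$tss + b, value = vals[keep])
          } else {
            tibble::tibble(chrom = g$chrom, start = g$tss - b,
                           end = g$tss - a, value = vals[keep])
          }
        })
        trk <- if (nrow(trk) == 0L) {
          tibble::tibble(chrom = character(), start = numeric(),
                         end = numeric(), value = numeric())
        } else {
          fuse_runs(dplyr::arrange(trk, .data$chrom, .data$start))
        }
        tibble::tibble(condition = pc$condition, timepoint = timepoints[ti],
                       track = list(trk))
      })
    })

    truth <- purrr::map_dfr(per_cond, function(pc) {
      tibble::tibble(condition = pc$condition,
                     gene_id = vapply(pc$per_gene, `[[`, "", "gene_id"),
                     v = pc$v, beta = pc$beta, basal = pc$basal,
                     pileup_gain = pc$pileup_gain, noise = pc$noise,
                     noise_scale = pc$noise_scale, seed = seed)
    })

    expected <- purrr::map_dfr(per_cond, function(pc) {
      purrr::map_dfr(pc$per_gene, function(g) {
        purrr::map_dfr(seq_along(timepoints), function(ti) {
          tibble::tibble(condition = pc$condition, gene_id = g$gene_id,
                         timepoint = timepoints[ti],
                         bin = seq_along(g$off), offset = g$off,
                         width = g$wid, expected = g$per_tp[[ti]]$expected)
        })
      })
    })

    list(tracks = tracks, truth = truth, expected = expected)
  })
}

# Exact mean of the piecewise wavefront density over bins [off, off + wid):
# density is `beta` (or beta * pileup past the pA offset `gene_len`) behind
# the front position `front`, `basal` ahead of it.
wavefront_bin_expectation <- function(off, wid, front, gene_len, beta, basal,
                                      pileup_gain) {
  lo <- off
  hi <- off + wid
  # body sub-segment [lo, min(hi, gene_len))
  b_lo <- pmin(lo, gene_len)
  b_hi <- pmin(hi, gene_len)
  b_len <- b_hi - b_lo
  b_behind <- pmin(pmax(front - b_lo, 0), b_len)
  # pileup sub-segment [max(lo, gene_len), hi)
  p_lo <- pmax(lo, gene_len)
  p_len <- pmax(hi - p_lo, 0)
  p_behind <- pmin(pmax(front - p_lo, 0), p_len)
  sum_sig <- b_behind * beta + (b_len - b_behind) * basal +
    p_behind * beta * pileup_gain + (p_len - p_behind) * basal
  sum_sig / wid
}

#' Simulate a differential-expression table with known cluster composition
#'
#' Emits a gene-level table of log2 fold changes and expressed flags whose
#' rows, when run through [assign_clusters()], recover a requested label
#' composition exactly. Fold changes are drawn uniformly within each label's
#' band (or within a user-supplied sub-range validated against the band).
#'
#' @param n_genes Total number of genes; rows beyond the requested cluster
#'   counts are filled as non-DE.
#' @param cluster_spec A tibble with columns `label` (one of `"16fold"`,
#'   `"8fold"`, `"4fold"`, `"2fold"`, `"nonDE"`, `"other"`,
#'   `"not_expressed"`) and `n`, plus optional `lfc_min`/`lfc_max`
#'   overriding the default draw range.
#' @param seed Integer seed.
#' @param nonde_fold Width of the non-DE fold band (default 1.4).
#' @return A list with `table` (tibble `gene_id`, `log2fc`, `expressed`) and
#'   `truth` (tibble `gene_id`, `label`).
#' @export
simulate_de_table <- function(n_genes, cluster_spec, seed = 1L,
                              nonde_fold = 1.4) {
  cluster_spec <- tibble::as_tibble(cluster_spec)
  nd <- log2(nonde_fold)
  bands <- list(
    "16fold" = c(4, 6), "8fold" = c(3, 4), "4fold" = c(2, 3),
    "2fold" = c(1, 2), "nonDE" = c(-nd, nd), "other" = c(nd, 1),
    "not_expressed" = c(NA_real_, NA_real_)
  )
  if (!all(cluster_spec$label %in% names(bands))) {
    abort("unknown cluster label in cluster_spec",
          class = "proxyrate_sim_error")
  }
  if (sum(cluster_spec$n) > n_genes) {
    abort("cluster counts exceed n_genes", class = "proxyrate_sim_error")
  }
  has_rng <- all(c("lfc_min", "lfc_max") %in% names(cluster_spec))
  withr::with_seed(seed, {
    rows <- purrr::pmap_dfr(
      cluster_spec,
      function(label, n, lfc_min = NA_real_, lfc_max = NA_real_, ...) {
        band <- bands[[label]]
        if (label == "not_expressed") {
          return(tibble::tibble(label = rep(label, n), log2fc = NA_real_,
                                expressed = FALSE))
        }
        lo <- if (has_rng && !is.na(lfc_min)) lfc_min else band[1]
        hi <- if (has_rng && !is.na(lfc_max)) lfc_max else band[2]
        # half-open draws strictly inside the band's exclusive upper edge
        eps <- 1e-9
        if (lo < band[1] - eps || hi > band[2] + eps || lo > hi) {
          abort(sprintf("log2FC range [%g, %g] inconsistent with cluster %s",
                        lo, hi, label),
                class = "proxyrate_sim_error")
        }
        draw <- stats::runif(n, lo, hi)
        # keep draws off exclusive boundaries of the band
        if (label %in% c("8fold", "4fold", "2fold", "other")) {
          draw <- pmin(draw, band[2] - 1e-6)
        }
        if (label == "nonDE") {
          draw <- pmin(pmax(draw, band[1] + 1e-6), band[2] - 1e-6)
        }
        tibble::tibble(label = rep(label, n), log2fc = draw,
                       expressed = TRUE)
      }
    )
    if (nrow(rows) == 0L) {
      rows <- tibble::tibble(label = character(), log2fc = numeric(),
                             expressed = logical())
    }
    n_fill <- n_genes - nrow(rows)
    if (n_fill > 0) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        label = "nonDE",
        log2fc = stats::runif(n_fill, -nd + 1e-6, nd - 1e-6),
        expressed = TRUE
      ))
    }
    rows$gene_id <- sprintf("gene%04d", seq_len(nrow(rows)))
    list(
      table = dplyr::select(rows, "gene_id", "log2fc", "expressed"),
      truth = dplyr::select(rows, "gene_id", "label")
    )
  })
}

#' Generate a toy non-overlapping gene annotation
#'
#' Lays out `n_genes` genes along one chromosome with randomized lengths and
#' strands, spaced so that simulated coverage spans (gene plus 3' extension)
#' never collide. Deterministic under `seed`; the result passes
#' [validate_genes()] and round-trips through [write_gene_bed()] /
#' [read_gene_bed()].
#'
#' @param n_genes Number of genes.
#' @param length_range Two-element bp range for gene lengths; minimum
#'   allowed is 1000 bp.
#' @param minus_fraction Probability a gene lands on the minus strand
#'   (default 0.5).
#' @param gap Intergenic spacing in bp (default 8000; must exceed the
#'   simulated 3' extension).
#' @param chrom Chromosome name (default `"chr1"`).
#' @param seed Integer seed.
#' @return A gene-model tibble.
#' @export
make_toy_annotation <- function(n_genes, length_range = c(8000, 15000),
                                minus_fraction = 0.5, gap = 8000,
                                chrom = "chr1", seed = 1L) {
  if (min(length_range) < 1000) {
    abort("gene lengths below 1 kb are not supported",
          class = "proxyrate_sim_error")
  }
  withr::with_seed(seed, {
    lens <- round(stats::runif(n_genes, length_range[1], length_range[2]))
    strands <- ifelse(stats::runif(n_genes) < minus_fraction, "-", "+")
    starts <- 10000 + cumsum(c(0, (lens + gap)[-n_genes]))
    tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      chrom = chrom,
      strand = strands,
      tss = ifelse(strands == "+", starts, starts + lens),
      pa = ifelse(strands == "+", starts + lens, starts),
      length = lens
    )
  })
}

#' Write gene models as BED6
#'
#' @param genes Gene-model tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  validate_genes(genes)
  start <- pmin(genes$tss, genes$pa)
  end <- pmax(genes$tss, genes$pa)
  out <- tibble::tibble(
    chrom = genes$chrom,
    start = format(start, scientific = FALSE, trim = TRUE),
    end = format(end, scientific = FALSE, trim = TRUE),
    name = genes$gene_id,
    score = 0L,
    strand = genes$strand
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
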