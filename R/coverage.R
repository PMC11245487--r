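#' Read a bedGraph coverage track
#'
#' Reads a 4-column bedGraph (chrom, start, end, value; tab-separated,
#' 0-based half-open) into a coverage-track tibble. Records are validated
#' (numeric value, start < end, no overlapping intervals within a
#' chromosome) and sorted by chromosome and start. Positions not covered by
#' any interval have implicit value 0.
#'
#' @param path Path to a bedGraph file.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  trk <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "value"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      value = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(is.na(trk$value)) || any(is.na(trk$start)) || any(is.na(trk$end))) {
    abort("non-numeric start/end/value field in bedGraph",
          class = "proxyrate_track_error")
  }
  validate_track(trk)
}

#' Write a coverage track as bedGraph
#'
#' @param track Coverage-track tibble (`chrom`, `start`, `end`, `value`).
#' @param path Output file path.
#' @return `path`, invisibly. Writing then reading a canonical (sorted,
#'   non-overlapping) track reproduces it exactly.
#' @export
write_bedgraph <- function(track, path) {
  track <- validate_track(track)
  out <- tibble::tibble(
    chrom = track$chrom,
    start = format(track$start, scientific = FALSE, trim = TRUE),
    end = format(track$end, scientific = FALSE, trim = TRUE),
    value = track$value
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Validate and canonicalize a coverage track
#'
#' Sorts by chromosome and start and checks the track invariants:
#' `start < end` everywhere and no overlapping intervals within a
#' chromosome (the first offending pair is named in the error).
#'
#' @param track Coverage-track tibble.
#' @return The sorted track tibble.
#' @export
validate_track <- function(track) {
  needed <- c("chrom", "start", "end", "value")
  missing <- setdiff(needed, names(track))
  if (length(missing) > 0L) {
    abort(paste0("track lacks column(s): ", paste(missing, collapse = ", ")),
          class = "proxyrate_track_error")
  }
  if (any(track$start >= track$end)) {
    abort("track interval with start >= end", class = "proxyrate_track_error")
  }
  track <- dplyr::arrange(track, .data$chrom, .data$start)
  same <- track$chrom[-1] == track$chrom[-nrow(track)]
  ovl <- which(same & track$start[-1] < track$end[-nrow(track)])
  if (nrow(track) > 1L && length(ovl) > 0L) {
    i <- ovl[1]
    abort(
      sprintf(
        "overlapping intervals on %s: [%s, %s) and [%s, %s)",
        track$chrom[i], format(track$start[i], scientific = FALSE),
        format(track$end[i], scientific = FALSE),
        format(track$start[i + 1], scientific = FALSE),
        format(track$end[i + 1], scientific = FALSE)
      ),
      class = "proxyrate_track_error"
    )
  }
  track
}

#' Extract gene-oriented binned signal from a coverage track
#'
#' Averages per-bp signal within consecutive fixed-width bins across a
#' genomic region, ordered 5' to 3' in gene orientation (reversed genomic
#' order on the minus strand). The number of bins is
#' `ceiling(width / bin_width)`; the final (3'-most) bin may be truncated
#' and is averaged over its actual width, so constant coverage `c` yields
#' every bin equal to `c`. Uncovered positions contribute 0.
#'
#' @param track Coverage-track tibble.
#' @param chrom Chromosome name.
#' @param start,end Genomic region, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param bin_width Bin width in bp (default 50).
#' @return A tibble with columns `bin` (1-based, 5'->3'), `offset`
#'   (gene-oriented bp of the bin's 5' edge from the region's 5' end),
#'   `width` and `value` (mean signal per bp).
#' @export
bin_coverage <- function(track, chrom, start, end, strand = "+",
                         bin_width = 50) {
  stopifnot(length(chrom) == 1L, end > start, bin_width >= 1)
  if (start < 0) {
    warn("region extends beyond chromosome start; padding with zero signal")
  }
  w <- end - start
  nb <- ceiling(w / bin_width)
  offs0 <- (seq_len(nb) - 1) * bin_width
  widths <- pmin(bin_width, w - offs0)
  sums <- bin_sums(track, chrom, start, end, strand, bin_width, nb, w)
  tibble::tibble(bin = seq_len(nb), offset = offs0, width = widths,
                 value = sums / widths)
}

# Per-bin signal sums by interval-clipping arithmetic (no per-base
# expansion). Offsets are gene-oriented: on '-' strand offset 0 is the
# region's genomic end.
bin_sums <- function(track, chrom, start, end, strand, bin_width, nb, w) {
  sums <- numeric(nb)
  iv <- track[track$chrom == chrom & track$end > start & track$start < end, ,
              drop = FALSE]
  if (nrow(iv) == 0L) return(sums)
  s <- pmax(iv$start, start)
  e <- pmin(iv$end, end)
  if (strand == "+") {
    a <- s - start
    b <- e - start
  } else {
    a <- end - e
    b <- end - s
  }
  for (i in seq_along(a)) {
    k <- (floor(a[i] / bin_width) : floor((b[i] - 1) / bin_width))
    lo <- pmax(a[i], k * bin_width)
    hi <- pmin(b[i], (k + 1) * bin_width)
    sums[k + 1] <- sums[k + 1] + iv$value[i] * (hi - lo)
  }
  sums
}

#' Normalize a count track to RPKM or CPM
#'
#' Treats interval values as read counts per `bin_width` window and rescales
#' them by sequencing depth: CPM divides by `total / 1e6`; RPKM additionally
#' divides by the window length in kb, so with `total = 1e6` and
#' `bin_width = 1000` RPKM is the identity on counts.
#'
#' @param track Coverage-track tibble of counts.
#' @param total_mapped_reads Library size (> 0).
#' @param mode `"RPKM"` or `"CPM"`.
#' @param bin_width Window length in bp over which counts were tallied
#'   (default 50).
#' @return The track with rescaled `value`.
#' @export
normalize_track <- function(track, total_mapped_reads,
                            mode = c("RPKM", "CPM"), bin_width = 50) {
  mode <- match.arg(mode)
  if (!is.numeric(total_mapped_reads) || total_mapped_reads <= 0) {
    abort("total_mapped_reads must be > 0", class = "proxyrate_norm_error")
  }
  denom <- total_mapped_reads / 1e6
  if (mode == "RPKM") denom <- denom * (bin_width / 1000)
  dplyr::mutate(track, value = .data$value / denom)
}

#' Spike-in scaling factors
#'
#' Computes between-sample scaling factors from exogenous (e.g. Drosophila)
#' spike-in read counts: `factor_i = min(counts) / counts_i`, so the sample
#' with the fewest spike-in reads gets factor 1 and applying the factors
#' equalizes expected spike-in signal across samples.
#'
#' @param counts Named (or unnamed) vector of positive spike-in read counts,
#'   or a data frame with columns `sample` and `count`.
#' @return A tibble with columns `sample`, `count`, `factor`.
#' @export
spike_in_factors <- function(counts) {
  if (is.data.frame(counts)) {
    smp <- counts$sample
    cnt <- counts$count
  } else {
    smp <- names(counts) %||% paste0("sample", seq_along(counts))
    cnt <- unname(counts)
  }
  if (any(cnt <= 0)) {
    abort("all spike-in counts must be > 0 (zero count indicates spike-in failure)",
          class = "proxyrate_spikein_error")
  }
  tibble::tibble(sample = smp, count = cnt, factor = min(cnt) / cnt)
}

#' Merge replicate coverage tracks
#'
#' Per-base mean of two or more tracks carrying the same normalization. A
#' chromosome absent from some replicates contributes zero signal for those
#' replicates, with a warning.
#'
#' @param tracks A list of coverage-track tibbles (length >= 1).
#' @return A merged coverage-track tibble (zero-value runs dropped, adjacent
#'   equal-value intervals fused).
#' @export
merge_replicates <- function(tracks) {
  if (!is.list(tracks) || length(tracks) == 0L || is.data.frame(tracks)) {
    abort("tracks must be a non-empty list of track tibbles",
          class = "proxyrate_track_error")
  }
  tracks <- lapply(tracks, validate_track)
  n <- length(tracks)
  chroms <- sort(unique(unlist(lapply(tracks, function(t) unique(t$chrom)))))
  partial <- chroms[vapply(
    chroms,
    function(ch) !all(vapply(tracks, function(t) ch %in% t$chrom, logical(1))),
    logical(1)
  )]
  if (length(partial) > 0L) {
    warn(paste0("chromosome(s) absent from some replicates (treated as zero): ",
                paste(partial, collapse = ", ")))
  }
  purrr::map_dfr(chroms, function(ch) {
    ivs <- purrr::map(tracks, ~ dplyr::filter(.x, .data$chrom == ch))
    edges <- sort(unique(unlist(lapply(ivs, function(t) c(t$start, t$end)))))
    if (length(edges) < 2L) return(tibble::tibble())
    seg_start <- edges[-length(edges)]
    seg_end <- edges[-1]
    total <- numeric(length(seg_start))
    for (t in ivs) {
      if (nrow(t) == 0L) next
      idx <- findInterval(seg_start, t$start)
      hit <- idx >= 1L & seg_start < t$end[pmax(idx, 1L)]
      total[hit] <- total[hit] + t$value[idx[hit]]
    }
    val <- total / n
    keep <- val != 0
    out <- tibble::tibble(chrom = ch, start = seg_start[keep],
                          end = seg_end[keep], value = val[keep])
    fuse_runs(out)
  })
}

# Fuse adjacent intervals with identical values (canonical run-length form).
fuse_runs <- function(track) {
  if (nrow(track) < 2L) return(track)
  new_run <- c(TRUE, !(track$start[-1] == track$end[-nrow(track)] &
                         track$value[-1] == track$value[-nrow(track)] &
                         track$chrom[-1] == track$chrom[-nrow(track)]))
  grp <- cumsum(new_run)
  track |>
    dplyr::group_by(grp2 = grp) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      value = dplyr::first(.data$value),
      .groups = "drop"
    ) |>
    dplyr::select("chrom", "start", "end", "value")
}
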