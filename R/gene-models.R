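#' Read gene models from a BED6 file
#'
#' Parses a six-column BED file into a tibble of gene models with
#' strand-aware transcription start site (TSS) and polyadenylation (pA) site
#' coordinates. BED coordinates are 0-based, half-open; for a `+` strand gene
#' the TSS is the BED start and the pA site the BED end, and vice versa on
#' the `-` strand.
#'
#' @param path Path to a tab-separated BED6 file
#'   (chrom, start, end, name, score, strand).
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`, `pa`
#'   and `length` (`abs(pa - tss)` in bp), one row per gene.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10000\t20000\tFOS\t0\t+", bed)
#' read_gene_bed(bed)
#' @export
read_gene_bed <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      name = readr::col_character(),
      score = readr::col_character(),
      strand = readr::col_character()
    ),
    progress = FALSE
  )
  if (nrow(raw) == 0L) {
    abort("no records in BED file", class = "proxyrate_bed_error")
  }
  bad <- which(!(raw$strand %in% c("+", "-")))
  if (length(bad) > 0L) {
    abort(
      paste0("missing or invalid strand in BED record(s): ",
             paste(bad, collapse = ", ")),
      class = "proxyrate_bed_error"
    )
  }
  bad <- which(!(raw$start < raw$end))
  if (length(bad) > 0L) {
    abort(
      paste0("malformed BED record(s) with start >= end: ",
             paste(bad, collapse = ", ")),
      class = "proxyrate_bed_error"
    )
  }
  dup <- unique(raw$name[duplicated(raw$name)])
  if (length(dup) > 0L) {
    abort(
      paste0("duplicate gene_id(s): ", paste(dup, collapse = ", ")),
      class = "proxyrate_bed_error"
    )
  }
  raw |>
    dplyr::transmute(
      gene_id = .data$name,
      chrom = .data$chrom,
      strand = .data$strand,
      tss = dplyr::if_else(.data$strand == "+", .data$start, .data$end),
      pa = dplyr::if_else(.data$strand == "+", .data$end, .data$start),
      length = abs(.data$pa - .data$tss)
    )
}

#' Validate a gene-model tibble
#'
#' Checks the invariants of the gene-model representation used throughout
#' the package: unique ids, valid strands, TSS and pA ordered consistently
#' with strand, positive length.
#'
#' @param genes A tibble as returned by [read_gene_bed()].
#' @return `genes`, invisibly, after validation.
#' @export
validate_genes <- function(genes) {
  needed <- c("gene_id", "chrom", "strand", "tss", "pa", "length")
  missing <- setdiff(needed, names(genes))
  if (length(missing) > 0L) {
    abort(paste0("gene table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) abort("gene_id values must be unique")
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  plus <- genes$strand == "+"
  if (!all(genes$tss[plus] < genes$pa[plus]) ||
      !all(genes$tss[!plus] > genes$pa[!plus])) {
    abort("tss/pa ordering inconsistent with strand")
  }
  if (!all(genes$length == abs(genes$pa - genes$tss)) || any(genes$length <= 0)) {
    abort("length must equal abs(pa - tss) and be positive")
  }
  invisible(genes)
}

# Map a gene-oriented half-open offset interval [a, b) (bp from the TSS,
# positive downstream) to genomic half-open coordinates. On the minus strand
# the interval is mirrored about the TSS: [tss - b, tss - a).
oriented_interval <- function(tss, strand, a, b) {
  if (strand == "+") c(tss + a, tss + b) else c(tss - b, tss - a)
}

#' Derive promoter-proximal, gene-body and 3'-end regions
#'
#' For each gene, derives the three quantitation regions in gene-oriented
#' offsets from the TSS: promoter-proximal (PP) spans `[-pp_up, pp_down)`,
#' gene body (GB) spans `[pp_down, length)`, and the 3' end spans
#' `[length, length + three_prime_ext)` (pA site downstream). The region in
#' which per-bin coverage slopes are estimated (`rocc`) is the union of GB
#' and 3' end. All intervals are emitted as genomic 0-based half-open
#' coordinates, mirrored about the TSS on the minus strand.
#'
#' Genes no longer than `pp_down` would have an empty gene body; they are
#' dropped with a warning rather than silently.
#'
#' @param genes Gene-model tibble ([read_gene_bed()]).
#' @param pp_up,pp_down Upstream/downstream extent of the PP window in bp
#'   (defaults 100 and 500).
#' @param three_prime_ext 3'-end window length downstream of the pA site in
#'   bp (default 3000).
#' @return A tibble in long form: `gene_id`, `chrom`, `strand`, `region`
#'   (one of `"pp"`, `"gb"`, `"three_prime"`, `"rocc"`), `start`, `end`.
#' @examples
#' genes <- tibble::tibble(gene_id = "FOS", chrom = "chr1", strand = "+",
#'                         tss = 10000, pa = 20000, length = 10000)
#' derive_regions(genes)
#' @export
derive_regions <- function(genes, pp_up = 100, pp_down = 500,
                           three_prime_ext = 3000) {
  validate_genes(genes)
  short <- genes$length <= pp_down
  if (any(short)) {
    warn(paste0(
      "excluding gene(s) with length <= pp_down (empty gene body): ",
      paste(genes$gene_id[short], collapse = ", ")
    ))
    genes <- genes[!short, , drop = FALSE]
  }
  purrr::pmap_dfr(genes, function(gene_id, chrom, strand, tss, pa, length) {
    offs <- list(
      pp = c(-pp_up, pp_down),
      gb = c(pp_down, length),
      three_prime = c(length, length + three_prime_ext),
      rocc = c(pp_down, length + three_prime_ext)
    )
    purrr::imap_dfr(offs, function(ab, nm) {
      gi <- oriented_interval(tss, strand, ab[1], ab[2])
      tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                     region = nm, start = gi[1], end = gi[2])
    })
  })
}

#' Split gene bodies into length quartiles
#'
#' Partitions each gene's `[TSS, pA)` span into four contiguous quartiles
#' Q1..Q4 ordered 5' to 3'. Boundaries fall at `floor(k * length / 4)` bp
#' from the TSS (k = 1..3), so quartile widths differ by at most 1 bp and a
#' 10-kb gene yields four exact 2.5-kb quartiles.
#'
#' @param genes Gene-model tibble; all lengths must be at least 4 bp.
#' @return A tibble: `gene_id`, `chrom`, `strand`, `quartile`
#'   (`"Q1"`..`"Q4"`), `start`, `end` (genomic, half-open), and the
#'   gene-oriented offsets `off_start`, `off_end` in bp from the TSS.
#' @export
split_quartiles <- function(genes) {
  validate_genes(genes)
  if (any(genes$length < 4)) {
    abort("gene length must be >= 4 bp to split into quartiles")
  }
  purrr::pmap_dfr(genes, function(gene_id, chrom, strand, tss, pa, length) {
    edges <- floor((0:4) * length / 4)
    purrr::map_dfr(1:4, function(k) {
      gi <- oriented_interval(tss, strand, edges[k], edges[k + 1])
      tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                     quartile = paste0("Q", k), start = gi[1], end = gi[2],
                     off_start = edges[k], off_end = edges[k + 1])
    })
  })
}

#' Export derived regions as BED
#'
#' Writes a region tibble (from [derive_regions()] or [split_quartiles()])
#' as a BED6 file with names like `<gene>_PP`, `<gene>_GB`, `<gene>_3p` or
#' `<gene>_Q1`..`<gene>_Q4`.
#'
#' @param regions Region tibble with `gene_id`, `chrom`, `strand`, `start`,
#'   `end` and either a `region` or a `quartile` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  label_col <- if ("quartile" %in% names(regions)) {
    regions$quartile
  } else {
    c(pp = "PP", gb = "GB", three_prime = "3p", rocc = "ROCC")[regions$region]
  }
  out <- tibble::tibble(
    chrom = regions$chrom,
    start = format(regions$start, scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE),
    name = paste0(regions$gene_id, "_", label_col),
    score = 0L,
    strand = regions$strand
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
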