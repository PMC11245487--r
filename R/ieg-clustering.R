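#' Flag expressed genes from a count matrix
#'
#' A gene is called expressed when at least `min_samples` samples have at
#' least `min_count` counts (both comparisons inclusive). The defaults match
#' common RNA-Seq filtering (10 counts in 6 samples); for TT-Seq-style data
#' use 50 counts in 4 samples.
#'
#' @param counts Matrix or data frame of nonnegative integer counts, genes
#'   in rows, samples in columns. Row names (or a `gene_id` column) identify
#'   genes.
#' @param min_count Per-sample count threshold (inclusive; default 10).
#' @param min_samples Number of samples required to pass (inclusive;
#'   default 6).
#' @return A tibble with columns `gene_id` and `expressed`.
#' @export
expression_filter <- function(counts, min_count = 10, min_samples = 6) {
  if (is.data.frame(counts) && "gene_id" %in% names(counts)) {
    ids <- counts$gene_id
    counts <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  } else {
    counts <- as.matrix(counts)
    ids <- rownames(counts) %||% sprintf("gene%d", seq_len(nrow(counts)))
  }
  if (any(counts < 0)) abort("counts must be nonnegative")
  if (min_samples > ncol(counts)) {
    abort("min_samples exceeds the number of samples",
          class = "proxyrate_cluster_error")
  }
  tibble::tibble(
    gene_id = ids,
    expressed = rowSums(counts >= min_count) >= min_samples
  )
}

#' Log2 fold change from a count matrix (stand-in)
#'
#' A plain log2 ratio of mean normalized counts between two sample groups
#' with a pseudocount, provided as a simple stand-in when no model-based
#' differential-expression output is available. It is not a replacement for
#' a proper DE model.
#'
#' @param counts Count matrix (genes x samples) with gene row names.
#' @param treated,reference Column indices or names of the two groups.
#' @param pseudocount Added to both means (default 0.5).
#' @return A tibble with `gene_id` and `log2fc`.
#' @export
naive_log2fc <- function(counts, treated, reference, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  ids <- rownames(counts) %||% sprintf("gene%d", seq_len(nrow(counts)))
  m1 <- rowMeans(counts[, treated, drop = FALSE])
  m0 <- rowMeans(counts[, reference, drop = FALSE])
  tibble::tibble(gene_id = ids,
                 log2fc = log2((m1 + pseudocount) / (m0 + pseudocount)))
}

#' Classify genes into induction clusters from log2 fold changes
#'
#' Assigns each gene the immediate-early-gene (IEG) induction classes used
#' for serum-response analysis. Cluster membership is cumulative on
#' up-regulation: an expressed gene with `log2fc >= 4` belongs to the
#' 16-fold, 8-fold, 4-fold and 2-fold clusters (thresholds inclusive,
#' default log2FC cutoffs 4, 3, 2, 1). Expressed genes within the
#' `nonde_fold` band (`|log2fc| < log2(1.4)` by default) are non-DE;
#' remaining expressed genes (including down-regulated ones) are `other`;
#' unexpressed genes are `not_expressed`. The reported `label` is the
#' highest cluster a gene reaches.
#'
#' @param table A tibble with columns `gene_id`, `log2fc`, `expressed`.
#' @param thresholds Named or unnamed vector of the four IEG log2FC cutoffs,
#'   descending (default `c(4, 3, 2, 1)` for 16/8/4/2-fold).
#' @param nonde_fold Fold bound of the non-DE band (default 1.4).
#' @return The input with added logical membership columns
#'   `member_16fold`..`member_2fold` and a `label` factor giving the top
#'   class.
#' @export
assign_clusters <- function(table, thresholds = c(4, 3, 2, 1),
                            nonde_fold = 1.4) {
  stopifnot(all(c("gene_id", "log2fc", "expressed") %in% names(table)))
  if (anyDuplicated(table$gene_id)) abort("gene_id values must be unique")
  if (length(thresholds) != 4 || is.unsorted(rev(thresholds), strictly = TRUE)) {
    abort("thresholds must be four descending log2FC cutoffs")
  }
  if (any(table$expressed & !is.finite(table$log2fc))) {
    abort("expressed gene with missing log2fc",
          class = "proxyrate_cluster_error")
  }
  nd <- log2(nonde_fold)
  lfc <- table$log2fc
  expressed <- table$expressed
  memb <- purrr::map(thresholds, ~ expressed & !is.na(lfc) & lfc >= .x)
  labels <- c("16fold", "8fold", "4fold", "2fold")
  out <- table
  for (i in 1:4) out[[paste0("member_", labels[i])]] <- memb[[i]]
  top <- dplyr::case_when(
    !expressed ~ "not_expressed",
    memb[[1]] ~ "16fold",
    memb[[2]] ~ "8fold",
    memb[[3]] ~ "4fold",
    memb[[4]] ~ "2fold",
    abs(lfc) < nd ~ "nonDE",
    TRUE ~ "other"
  )
  out$label <- factor(top, levels = c(labels, "nonDE", "other",
                                      "not_expressed"))
  out
}

#' Cluster sizes, cumulative by definition
#'
#' @param assignment Output of [assign_clusters()].
#' @return A tibble with `cluster` and `n`; IEG cluster counts are nested
#'   (`n(16fold) <= n(8fold) <= n(4fold) <= n(2fold)`).
#' @export
cluster_sizes <- function(assignment) {
  memb_cols <- grep("^member_", names(assignment), value = TRUE)
  ieg <- tibble::tibble(
    cluster = sub("member_", "", memb_cols),
    n = vapply(memb_cols, function(cl) sum(assignment[[cl]]), integer(1))
  )
  rest <- assignment |>
    dplyr::filter(.data$label %in% c("nonDE", "other", "not_expressed")) |>
    dplyr::count(cluster = as.character(.data$label))
  dplyr::bind_rows(ieg, rest)
}

#' Draw a random non-DE comparison gene set
#'
#' Samples `n` genes from the non-DE class of a cluster assignment, as a
#' size-matched background for induced-gene contrasts.
#'
#' @param assignment Output of [assign_clusters()].
#' @param n Number of genes to draw.
#' @param seed Integer seed.
#' @return A character vector of gene ids.
#' @export
sample_nonde <- function(assignment, n, seed = 1L) {
  pool <- assignment$gene_id[assignment$label == "nonDE"]
  if (n > length(pool)) abort("fewer non-DE genes than requested")
  withr::with_seed(seed, sample(pool, n))
}
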