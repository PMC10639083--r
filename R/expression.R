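# Cell-type expression and splicing metrics: per-feature z-scores across all
# replicates summarized per cell type, the top-half-median group score,
# splicing efficiency and retention with junction-support weighting, and
# paired gene-set comparisons between cell types.

#' Per-feature z-scores across all samples, summarized per cell type
#'
#' Each feature (gene or intron) is standardized across all samples (mean 0,
#' sample sd with n - 1); features constant across samples have no defined
#' z-score and are excluded and listed. Each cell type is then summarized by
#' the mean of its replicates' z-scores.
#'
#' @param matrix numeric matrix, features x samples (already normalized).
#' @param design data frame with columns `sample` (matching the matrix
#'   columns) and `cell_type`.
#' @return list of class `zscore_matrix`: `z` (standardized matrix),
#'   `cell_type_mean` (features x cell types), `excluded_features`.
#' @export
zscore_by_feature <- function(matrix, design) {
  stopifnot(ncol(matrix) >= 2, all(colnames(matrix) == design$sample))
  sds <- apply(matrix, 1, sd)
  excluded <- rownames(matrix)[sds == 0 | is.na(sds)]
  keep <- setdiff(rownames(matrix), excluded)
  m <- matrix[keep, , drop = FALSE]
  z <- (m - rowMeans(m)) / apply(m, 1, sd)
  types <- unique(design$cell_type)
  ctm <- do.call(cbind, lapply(types, function(ct) {
    rowMeans(z[, design$cell_type == ct, drop = FALSE])
  }))
  dimnames(ctm) <- list(rownames(z), types)
  structure(list(z = z, cell_type_mean = ctm, excluded_features = excluded),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf("z-score matrix: %d features x %d samples (%d excluded)\n",
              nrow(x$z), ncol(x$z), length(x$excluded_features)))
  invisible(x)
}

#' Group score: median of the top half of z-scores
#'
#' Sorts descending, keeps the top ceiling(n/2) values and returns their
#' median.
#'
#' @param z numeric vector of z-scores for a gene set within one cell type
#'   (length >= 2).
#' @return scalar group score.
#' @export
group_score <- function(z) {
  if (length(z) < 2) stop_param("group_score needs at least 2 values")
  top <- sort(z, decreasing = TRUE)[seq_len(ceiling(length(z) / 2))]
  median(top)
}

junction_weights <- function(ie_mean, ee, scheme = c("sum", "product")) {
  scheme <- match.arg(scheme)
  if (scheme == "sum") ie_mean + ee else ie_mean * ee
}

#' Splicing efficiency from junction read counts
#'
#' Per sample and intron, efficiency = EE / (EE + mean(IE_left, IE_right)).
#' Sample-intron pairs with fewer than `min_reads` reads on the exon-exon
#' junction or on either intron-exon junction are excluded. Within each cell
#' type, the replicate efficiencies of an intron are combined as a weighted
#' mean with weight mean(IE) + EE (or their product with
#' `weight_scheme = "product"`); introns with no surviving replicate in a
#' cell type are reported as NA.
#'
#' @param junctions data frame with columns `intron_id`, `replicate`,
#'   `IE_left`, `IE_right`, `EE` (as from [generate_junction_table()]).
#' @param design optional data frame `replicate` -> `cell_type`; by default
#'   all replicates form one cell type "all".
#' @param min_reads read-support filter (default 5).
#' @param weight_scheme "sum" (default) or "product".
#' @return list of class `splicing_metrics`: `per_sample` (with efficiency
#'   and weight per surviving sample) and `per_cell_type` (weighted mean
#'   efficiency per intron and cell type).
#' @export
splicing_efficiency <- function(junctions, design = NULL, min_reads = 5,
                                weight_scheme = c("sum", "product")) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(all(junctions$IE_left >= 0), all(junctions$IE_right >= 0),
            all(junctions$EE >= 0))
  x <- junctions
  x$cell_type <- if (is.null(design)) "all" else {
    design$cell_type[match(x$replicate, design$replicate)]
  }
  x$ie_mean <- (x$IE_left + x$IE_right) / 2
  x$pass <- x$EE >= min_reads & x$IE_left >= min_reads &
    x$IE_right >= min_reads
  x$efficiency <- ifelse(x$EE + x$ie_mean > 0,
                         x$EE / (x$EE + x$ie_mean), NA_real_)
  x$weight <- junction_weights(x$ie_mean, x$EE, weight_scheme)
  surv <- x[x$pass & !is.na(x$efficiency), , drop = FALSE]
  combos <- unique(x[, c("intron_id", "cell_type")])
  per_ct <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    s <- surv[surv$intron_id == combos$intron_id[i] &
                surv$cell_type == combos$cell_type[i], , drop = FALSE]
    data.frame(
      intron_id = combos$intron_id[i], cell_type = combos$cell_type[i],
      n_replicates = nrow(s),
      efficiency = if (nrow(s) && sum(s$weight) > 0) {
        sum(s$weight * s$efficiency) / sum(s$weight)
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(per_sample = x, per_cell_type = per_ct,
                 weight_scheme = weight_scheme),
            class = "splicing_metrics")
}

#' Weighted mean intron retention per cell type
#'
#' Retention values are consumed (from an external retention caller) with
#' their junction support; rows flagged "LowSplicing" or "LowCover" are
#' dropped, and the surviving replicates are combined with the same
#' junction-support weighting as [splicing_efficiency()].
#'
#' @param retention data frame with columns `intron_id`, `replicate`,
#'   `retention`, `IE_left`, `IE_right`, `EE`, optionally `flag` and
#'   `cell_type`.
#' @param weight_scheme "sum" (default) or "product".
#' @return data frame: `intron_id`, `cell_type`, `n_replicates`,
#'   `retention` (weighted mean).
#' @export
retention_weighted_mean <- function(retention,
                                    weight_scheme = c("sum", "product")) {
  weight_scheme <- match.arg(weight_scheme)
  x <- retention
  if (!"cell_type" %in% names(x)) x$cell_type <- "all"
  if ("flag" %in% names(x)) {
    x <- x[!(x$flag %in% c("LowSplicing", "LowCover")), , drop = FALSE]
  }
  x$weight <- junction_weights((x$IE_left + x$IE_right) / 2, x$EE,
                               weight_scheme)
  x <- x[x$weight > 0, , drop = FALSE]
  combos <- unique(x[, c("intron_id", "cell_type")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    s <- x[x$intron_id == combos$intron_id[i] &
             x$cell_type == combos$cell_type[i], , drop = FALSE]
    data.frame(
      intron_id = combos$intron_id[i], cell_type = combos$cell_type[i],
      n_replicates = nrow(s),
      retention = sum(s$weight * s$retention) / sum(s$weight),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Paired gene-set expression comparison between cell types
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-gene expression
#' values of a gene set in two cell types, Benjamini-Hochberg-corrected
#' across all requested cell-type pairs.
#'
#' @param means numeric matrix of per-gene per-cell-type mean expression
#'   (genes x cell types).
#' @param gene_set character vector of gene ids (rows of `means`), >= 4.
#' @param pairs optional 2-column matrix of cell-type pairs; all pairs by
#'   default.
#' @return data frame: `cell_type_A`, `cell_type_B`, `p`, `q`.
#' @export
geneset_paired_comparison <- function(means, gene_set, pairs = NULL) {
  if (!all(gene_set %in% rownames(means))) {
    stop_param("gene_set contains genes absent from the matrix")
  }
  if (length(gene_set) < 4) {
    stop_param("need at least 4 paired genes for the signed-rank test")
  }
  if (is.null(pairs)) {
    pairs <- t(combn(colnames(means), 2))
  }
  p <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- means[gene_set, pairs[i, 1]]
    b <- means[gene_set, pairs[i, 2]]
    if (all(a == b)) return(1)
    suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
  }, numeric(1))
  data.frame(cell_type_A = pairs[, 1], cell_type_B = pairs[, 2], p = p,
             q = p.adjust(p, "BH"), stringsAsFactors = FALSE)
}
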