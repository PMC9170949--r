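# Gene-set module scoring with expression-matched control genes, and
# pairwise between-group score comparisons.

#' Log-normalize a raw count matrix
#'
#' Per-cell library-size scaling to `scale_factor` total counts followed by
#' `log1p`, the standard normalization expected by [module_score()].
#'
#' @param counts cells x genes matrix (raw counts)
#' @param scale_factor target per-cell total (default 10000)
#' @return cells x genes sparse matrix of log-normalized expression
#' @export
normalize_expression <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::rowSums(counts)
  sf <- ifelse(totals > 0, scale_factor / totals, 0)
  out <- Matrix::Diagonal(x = sf) %*% counts
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  methods::as(out, "CsparseMatrix")
}

#' Gene-set module score per cell
#'
#' For every gene-set gene, `n_ctrl` control genes are drawn uniformly with
#' replacement from the gene's expression bin (genes are binned into
#' `n_bins` equal-frequency bins by average expression across cells). The
#' score of a cell is its mean expression over the gene set minus its mean
#' expression over the pooled control draws (duplicates retained), so a
#' positive score means set expression above what genes of comparable
#' abundance show in that cell.
#'
#' @param expr cells x genes matrix of log-normalized expression
#' @param gene_set character vector of gene identifiers; genes absent from
#'   the matrix are dropped (the intersection size is reported as an
#'   attribute)
#' @param n_bins number of average-expression bins (default 24)
#' @param n_ctrl control genes drawn per set gene (default 100)
#' @param seed integer seed making the control draw reproducible (required)
#' @return data.frame with `barcode` and `score`; attributes `n_used`
#'   (gene-set genes found) and `n_missing`
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100, seed) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (n_ctrl < 1) stop("n_ctrl must be at least 1")
  if (missing(seed)) stop("a seed is required for the control-gene draw")
  genes <- colnames(expr)
  used <- intersect(gene_set, genes)
  if (length(used) == 0)
    stop("gene set has empty intersection with the expression matrix")
  avg <- Matrix::colMeans(expr)
  # equal-frequency binning by average expression (ties broken by rank)
  nb <- min(n_bins, length(genes))
  bin <- ceiling(rank(avg, ties.method = "first") / (length(genes) / nb))
  bin_members <- split(seq_along(genes), bin)
  ctrl_idx <- with_seed(seed, {
    unlist(lapply(used, function(g) {
      b <- bin[[match(g, genes)]]
      pool <- bin_members[[as.character(b)]]
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }), use.names = FALSE)
  })
  set_mean <- Matrix::rowMeans(expr[, used, drop = FALSE])
  # control mean with duplicates retained: average of the drawn columns
  ctrl_tab <- table(ctrl_idx)
  w <- as.numeric(ctrl_tab) / length(ctrl_idx)
  cols <- as.integer(names(ctrl_tab))
  ctrl_mean <- as.vector(expr[, cols, drop = FALSE] %*% w)
  out <- data.frame(barcode = rownames(expr), score = set_mean - ctrl_mean,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_used") <- length(used)
  attr(out, "n_missing") <- length(setdiff(gene_set, genes))
  out
}

# Holm step-down and Holm-Sidak step-down family-wise adjustments
adjust_family <- function(p, method = c("holm", "holm_sidak")) {
  method <- match.arg(method)
  if (method == "holm") return(stats::p.adjust(p, method = "holm"))
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Pairwise between-group comparison of module scores
#'
#' All pairwise two-sided Wilcoxon rank-sum tests between group score
#' distributions, with family-wise adjustment by the Holm or Holm-Sidak
#' step-down procedure. Groups with fewer than 2 observations are excluded
#' with a warning.
#'
#' @param scores data.frame with a `score` column
#' @param group vector of group labels, parallel to `scores`
#' @param test only `"rank_sum"` is available
#' @param adjust `"holm_sidak"` (default) or `"holm"`
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `n1`, `n2`, `statistic` (rank-sum W), `p_value`, `p_adjusted`
#' @export
compare_groups <- function(scores, group, test = "rank_sum",
                           adjust = c("holm_sidak", "holm")) {
  test <- match.arg(test, "rank_sum")
  adjust <- match.arg(adjust)
  group <- as.character(group)
  stopifnot(length(group) == nrow(scores))
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding group(s) with fewer than 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !group %in% small
    scores <- scores[keep, , drop = FALSE]
    group <- group[keep]
  }
  gl <- sort(unique(group))
  if (length(gl) < 2) stop("need at least 2 groups with >= 2 observations")
  pairs <- utils::combn(gl, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    x <- scores$score[group == g1]
    y <- scores$score[group == g2]
    wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                             correct = TRUE)
    data.frame(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_family(out$p_value, adjust)
  out
}
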