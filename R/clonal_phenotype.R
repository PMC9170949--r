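# Joins clonotypes to phenotype clusters: entropy-based pairwise transition
# indices, cluster composition tables, and gene-usage associations with
# clone size.

#' Pairwise clonal transition index between two clusters
#'
#' Restricts to clones with at least one cell in either cluster and at
#' least `min_cells` cells across the two. For each such clone with
#' `n_i` cells in `cluster_i` and `n_j` in `cluster_j`, the binary Shannon
#' entropy of the split `p = n_i / (n_i + n_j)` is computed (0 log 0 = 0)
#' and clones are combined with cell-count weights
#' `w = (n_i + n_j) / sum(n_i + n_j)`. The index lies in [0, 1]: 0 when no
#' clone spans both clusters, 1 when every qualifying clone splits evenly —
#' read as shared differentiation potential between the two phenotypes.
#'
#' @param cells data.frame with columns `clone_id` and `cluster`
#' @param cluster_i,cluster_j distinct cluster labels
#' @param min_cells minimum cells a clone must have across the two clusters
#'   (default 2)
#' @param weighting `"cell"` (default; cell-count weights) or `"clone"`
#'   (each qualifying clone weighted equally)
#' @return list with `index` (`NA` when no clone qualifies), `n_clones`,
#'   `n_cells`
#' @export
transition_index <- function(cells, cluster_i, cluster_j, min_cells = 2,
                             weighting = c("cell", "clone")) {
  weighting <- match.arg(weighting)
  stopifnot(cluster_i != cluster_j)
  x <- cells[cells$cluster %in% c(cluster_i, cluster_j), , drop = FALSE]
  if (nrow(x) == 0)
    return(list(index = NA_real_, n_clones = 0L, n_cells = 0L))
  ni <- tapply(x$cluster == cluster_i, x$clone_id, sum)
  nj <- tapply(x$cluster == cluster_j, x$clone_id, sum)
  tot <- ni + nj
  q <- tot >= min_cells
  if (!any(q))
    return(list(index = NA_real_, n_clones = 0L, n_cells = 0L))
  p <- ni[q] / tot[q]
  h <- ifelse(p %in% c(0, 1), 0,
              -p * log2(p) - (1 - p) * log2(1 - p))
  w <- if (weighting == "cell") tot[q] / sum(tot[q])
       else rep(1 / sum(q), sum(q))
  list(index = sum(w * h), n_clones = sum(q), n_cells = sum(tot[q]))
}

#' Pairwise transition-index matrix over all cluster pairs
#'
#' @param cells data.frame with columns `clone_id` and `cluster`
#' @param clusters cluster labels to include (default: all observed, in
#'   order of appearance)
#' @inheritParams transition_index
#' @return list with `index` (symmetric matrix, `NA` diagonal and `NA`
#'   where no clone qualifies) and `n_clones` (supporting-clone counts)
#' @export
transition_matrix <- function(cells, clusters = NULL, min_cells = 2,
                              weighting = c("cell", "clone")) {
  weighting <- match.arg(weighting)
  if (is.null(clusters)) clusters <- unique(cells$cluster)
  k <- length(clusters)
  stopifnot(k >= 2)
  idx <- matrix(NA_real_, k, k, dimnames = list(clusters, clusters))
  nc <- matrix(NA_integer_, k, k, dimnames = list(clusters, clusters))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- transition_index(cells, clusters[i], clusters[j],
                            min_cells = min_cells, weighting = weighting)
      idx[i, j] <- idx[j, i] <- r$index
      nc[i, j] <- nc[j, i] <- r$n_clones
    }
  }
  list(index = idx, n_clones = nc)
}

#' Per-sample cluster composition frequencies
#'
#' @param metadata cell metadata with `sample_id` and `cluster` columns
#' @param group_col grouping column (default `"sample_id"`)
#' @return data.frame with `group`, `cluster`, `count`, `frequency`
#'   (sums to 1 within each group); cells without a cluster label are
#'   excluded with a warning
#' @export
cluster_composition <- function(metadata, group_col = "sample_id") {
  miss <- is.na(metadata$cluster) | metadata$cluster == ""
  if (any(miss)) {
    warning(sum(miss), " cell(s) lack a cluster label and were excluded")
    metadata <- metadata[!miss, , drop = FALSE]
  }
  tab <- table(metadata[[group_col]], metadata$cluster)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "cluster", "count")
  tot <- rowSums(tab)
  out$frequency <- ifelse(tot[out$group] > 0,
                          out$count / as.vector(tot[out$group]), 0)
  rownames(out) <- NULL
  out
}

#' Cluster distribution by gene usage, with homogeneity test
#'
#' Splits cells by which gene of `genes` their clone uses in `gene_slot`
#' and tabulates the cluster distribution of each gene group; a chi-squared
#' test of homogeneity across gene groups is attached. The test is skipped
#' (with a recorded reason) when any gene group has fewer than 2 cells.
#'
#' @param cells data.frame with `cluster` and the gene-slot column
#' @param gene_slot one of `"va"`, `"ja"`, `"vb"`, `"jb"`
#' @param genes character vector of gene names defining the groups
#' @return list with `freq` (data.frame `gene`, `cluster`, `count`,
#'   `frequency`; frequencies sum to 1 per gene), `chisq` (`htest` or
#'   `NULL`), `test_skipped_reason`
#' @export
usage_by_gene <- function(cells, gene_slot = c("jb", "vb", "ja", "va"),
                          genes) {
  gene_slot <- match.arg(gene_slot)
  g <- cells[[gene_slot]]
  absent <- setdiff(genes, g)
  if (length(absent) > 0)
    warning("gene(s) not observed in data: ", paste(absent, collapse = ", "))
  x <- cells[g %in% genes & !is.na(cells$cluster), , drop = FALSE]
  tab <- table(factor(x[[gene_slot]], levels = genes), x$cluster)
  freq <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(freq) <- c("gene", "cluster", "count")
  tot <- rowSums(tab)
  freq$frequency <- ifelse(tot[freq$gene] > 0,
                           freq$count / as.vector(tot[freq$gene]), 0)
  rownames(freq) <- NULL
  chisq <- NULL; reason <- NULL
  if (any(tot < 2)) {
    reason <- "at least one gene group has fewer than 2 cells"
  } else if (nrow(tab) < 2 || ncol(tab) < 2) {
    reason <- "need at least 2 gene groups and 2 clusters"
  } else {
    chisq <- suppressWarnings(stats::chisq.test(tab))
  }
  list(freq = freq, chisq = chisq, test_skipped_reason = reason)
}

#' Logistic regression of gene usage on clone size
#'
#' Fits, among clones with at least `min_clone_size` cells, the logistic
#' model `uses_gene ~ log2(size)` by maximum likelihood (iteratively
#' reweighted least squares) and tests the size effect with a 1-df
#' likelihood-ratio test against the intercept-only model. Complete
#' separation is detected and flagged rather than silently diverging.
#'
#' @param clone_set `clone_set`
#' @param gene_slot one of `"jb"`, `"vb"`, `"ja"`, `"va"`
#' @param gene gene whose usage is the binary response
#' @param min_clone_size minimum clone size analysed (default 2,
#'   non-singlet clones)
#' @return list with `gene`, `n`, `intercept`, `slope` (log-odds per
#'   doubling of clone size), `se_intercept`, `se_slope`, `z`, `lrt_stat`,
#'   `p_value`, `separation` (logical), `converged`
#' @export
gene_usage_logistic <- function(clone_set,
                                gene_slot = c("jb", "vb", "ja", "va"),
                                gene, min_clone_size = 2) {
  gene_slot <- match.arg(gene_slot)
  cl <- clone_set$clones[clone_set$clones$size >= min_clone_size, ,
                         drop = FALSE]
  cl <- cl[!is.na(cl[[gene_slot]]), , drop = FALSE]
  if (nrow(cl) < 10)
    stop("need at least 10 qualifying clones, have ", nrow(cl))
  y <- as.integer(cl[[gene_slot]] == gene)
  xs <- log2(cl$size)
  fit <- suppressWarnings(
    stats::glm(y ~ xs, family = stats::binomial(),
               control = list(epsilon = 1e-10, maxit = 100)))
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  lrt <- as.numeric(null_fit$deviance - fit$deviance)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  mu <- fit$fitted.values
  separation <- !fit$converged || any(abs(cf) > 15) ||
    all(mu[y == 1] > 1 - 1e-8) && all(mu[y == 0] < 1e-8)
  list(gene = gene, n = nrow(cl),
       intercept = unname(cf[1]), slope = unname(cf[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]),
       z = unname(cf[2] / se[2]), lrt_stat = lrt,
       p_value = max(p, .Machine$double.xmin),
       separation = separation, converged = fit$converged)
}
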