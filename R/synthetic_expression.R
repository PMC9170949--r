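# Synthetic expression-matrix generator: per-gene negative-binomial counts
# with planted gene-set effects in designated cell groups, mitochondrial
# genes, and low-quality / apoptotic cells so the QC filters have work to
# do.

# designated targets of each planted gene set: clusters (either tissue's
# label set) or a beta J gene
GENESET_TARGETS <- list(
  effector_set = list(clusters = c("effector", "cx3cr1_effector")),
  progenitor_set = list(clusters = c("progenitor", "central_memory",
                                     "effector_memory", "bystander")),
  exhausted_set = list(clusters = c("effector", "exhausted")),
  tcr_signaling_set = list(jb = "TRBJ2-2")
)

#' Generate a synthetic expression matrix with planted gene-set effects
#'
#' Counts are negative binomial with per-gene means; four planted gene
#' sets (20 genes each) are up-regulated on the log scale by
#' `config$geneset_delta` in their designated cell groups: effector,
#' progenitor/memory and exhaustion programmes keyed to phenotype
#' clusters, and a TCR-signaling programme keyed to cells of TRBJ2-2
#' clones. Mitochondrial genes (`mt-` prefix) are present at a baseline
#' fraction, with a small apoptotic subpopulation exceeding the
#' conventional 5% threshold and a low-quality subpopulation with reduced
#' library complexity.
#'
#' @param config [sim_config()]
#' @param cells per-cell table carrying `barcode`, `cluster` and `jb`
#'   columns (the `truth$cells` table of [generate_repertoire()], or any
#'   metadata with those columns)
#' @param seed integer seed
#' @return list with `counts` (cells x genes sparse matrix),
#'   `gene_sets` (named list of planted gene-identifier vectors) and
#'   `truth` (per-set delta and targets, per-cell scale factors)
#' @export
generate_expression <- function(config, cells, seed = config$seed) {
  cfg <- config
  n_cells <- nrow(cells)
  set_names <- names(GENESET_TARGETS)
  n_set_genes <- 10L
  gene_sets <- lapply(seq_along(set_names), function(k) {
    sprintf("%s_g%02d", sub("_set$", "", set_names[k]), seq_len(n_set_genes))
  })
  names(gene_sets) <- set_names
  mito_genes <- sprintf("mt-Gene%d", seq_len(cfg$n_mito))
  n_filler <- cfg$n_genes - length(mito_genes) -
    n_set_genes * length(set_names)
  stopifnot(n_filler > 0)
  filler <- sprintf("Gene%04d", seq_len(n_filler))
  genes <- c(unlist(gene_sets, use.names = FALSE), mito_genes, filler)

  with_seed(seed, {
    # set-gene baseline means follow the same law as the neutral
    # background, so expression-matched control bins are mostly neutral
    # (a set whose genes dominate their own abundance bins would become
    # its own control and attenuate every score)
    n_nonmito <- cfg$n_genes - length(mito_genes)
    nonmito_means <- exp(stats::rnorm(n_nonmito, log(cfg$filler_gene_mean),
                                      cfg$gene_mean_log_sd))
    base_mean <- c(
      nonmito_means[seq_len(n_set_genes * length(set_names))],
      rep(cfg$mito_gene_mean, length(mito_genes)),
      nonmito_means[-seq_len(n_set_genes * length(set_names))])
    cell_scale <- rep(1, n_cells)
    lowq <- stats::runif(n_cells) < cfg$lowq_rate
    cell_scale[lowq] <- 0.15
    apop <- stats::runif(n_cells) < cfg$apoptotic_rate
    mito_scale <- rep(1, n_cells)
    mito_scale[apop] <- 4

    # per-cell multiplicative effect per gene set; per-set deltas default
    # to the global one
    deltas <- stats::setNames(rep(cfg$geneset_delta, length(set_names)),
                              set_names)
    if (!is.null(cfg$geneset_deltas))
      deltas[names(cfg$geneset_deltas)] <- cfg$geneset_deltas
    eff <- matrix(1, n_cells, length(set_names))
    for (k in seq_along(set_names)) {
      tgt <- GENESET_TARGETS[[set_names[k]]]
      hit <- rep(FALSE, n_cells)
      if (!is.null(tgt$clusters)) hit <- cells$cluster %in% tgt$clusters
      if (!is.null(tgt$jb)) hit <- !is.na(cells$jb) & cells$jb %in% tgt$jb
      eff[hit, k] <- exp(deltas[k])
    }

    counts <- matrix(0L, n_cells, length(genes))
    for (g in seq_along(genes)) {
      mu <- base_mean[g] * cell_scale
      if (g <= n_set_genes * length(set_names)) {
        k <- ceiling(g / n_set_genes)
        mu <- mu * eff[, k]
      } else if (genes[g] %in% mito_genes) {
        mu <- mu * mito_scale
      }
      counts[, g] <- stats::rnbinom(n_cells, mu = mu, size = cfg$nb_size)
    }
    dimnames(counts) <- list(cells$barcode, genes)
    list(
      counts = Matrix::Matrix(counts, sparse = TRUE),
      gene_sets = gene_sets,
      truth = list(delta = cfg$geneset_delta, targets = GENESET_TARGETS,
                   lowq = lowq, apoptotic = apop)
    )
  })
}

#' Write gene-set files
#'
#' One plain-text file per gene set (one identifier per line, `#` header
#' comment), the format of [read_gene_list()].
#'
#' @param gene_sets named list of gene-identifier vectors
#' @param dir output directory
#' @return paths of the written files, invisibly
#' @export
write_gene_sets <- function(gene_sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(gene_sets), function(nm) {
    p <- file.path(dir, paste0(nm, ".txt"))
    writeLines(c(paste0("# gene set: ", nm), gene_sets[[nm]]), p)
    p
  }, character(1))
  invisible(paths)
}
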