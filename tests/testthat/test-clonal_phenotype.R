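mk_cells <- function(clone_id, cluster)
  data.frame(clone_id = clone_id, cluster = cluster,
             stringsAsFactors = FALSE)

test_that("transition index hits its boundary cases", {
  # no clone spans both clusters -> 0
  x <- mk_cells(c("a", "a", "b", "b"), c("p", "p", "e", "e"))
  expect_equal(transition_index(x, "p", "e")$index, 0)
  # one clone split exactly 50/50 -> 1
  y <- mk_cells(c("a", "a", "a", "a"), c("p", "p", "e", "e"))
  expect_equal(transition_index(y, "p", "e")$index, 1)
  # no qualifying clone -> missing, not zero
  z <- mk_cells("a", "p")
  expect_true(is.na(transition_index(z, "p", "e")$index))
  expect_error(transition_index(x, "p", "p"))
})

test_that("transition index equals a brute-force entropy computation", {
  # 5-clone hand fixture
  x <- mk_cells(
    rep(c("c1", "c2", "c3", "c4", "c5"), c(4, 3, 2, 6, 2)),
    c("p", "p", "e", "e",   "p", "e", "e",   "p", "p",
      "e", "e", "e", "e", "e", "p",   "x", "e"))
  got <- transition_index(x, "p", "e")$index
  expect_equal(got, brute_transition(x, "p", "e"), tolerance = 1e-12)

  # random small fixtures against the independent script
  set.seed(21)
  for (i in 1:30) {
    n_clones <- sample(3:20, 1)
    cells <- mk_cells(
      sample(paste0("c", seq_len(n_clones)), 60, TRUE),
      sample(c("p", "e", "q"), 60, TRUE))
    got <- transition_index(cells, "p", "e")$index
    want <- brute_transition(cells, "p", "e")
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
    if (!is.na(got)) expect_true(got >= 0 && got <= 1)
    # symmetry
    rev <- transition_index(cells, "e", "p")$index
    expect_equal(got, rev)
  }
})

test_that("transition index is invariant to duplicating every cell", {
  set.seed(5)
  cells <- mk_cells(sample(paste0("c", 1:8), 40, TRUE),
                    sample(c("p", "e"), 40, TRUE))
  a <- transition_index(cells, "p", "e")$index
  b <- transition_index(rbind(cells, cells), "p", "e")$index
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("clone-uniform weighting is offered and differs when clones are unbalanced", {
  x <- mk_cells(rep(c("big", "sm"), c(20, 2)),
                c(rep("p", 10), rep("e", 10), "p", "e"))
  cellw <- transition_index(x, "p", "e", weighting = "cell")$index
  clonew <- transition_index(x, "p", "e", weighting = "clone")$index
  expect_equal(cellw, 1)  # both clones split 50/50
  expect_equal(clonew, 1)
  x2 <- mk_cells(rep(c("big", "sm"), c(20, 2)),
                 c(rep("p", 19), "e", "p", "e"))
  expect_true(abs(transition_index(x2, "p", "e", weighting = "cell")$index -
                    transition_index(x2, "p", "e",
                                     weighting = "clone")$index) > 0.1)
})

test_that("transition matrices are symmetric and respect relabeling", {
  set.seed(9)
  cells <- mk_cells(sample(paste0("c", 1:10), 80, TRUE),
                    sample(c("p", "e", "q"), 80, TRUE))
  tm <- transition_matrix(cells, c("p", "e", "q"))
  expect_equal(tm$index, t(tm$index))
  expect_true(all(is.na(diag(tm$index))))
  tm2 <- transition_matrix(cells, c("q", "p", "e"))
  expect_equal(tm2$index["p", "e"], tm$index["p", "e"])

  # disjoint clone sets across clusters -> all-zero off-diagonal
  dis <- mk_cells(rep(c("a", "b", "c"), each = 4),
                  rep(c("p", "e", "q"), each = 4))
  tmd <- transition_matrix(dis, c("p", "e", "q"))
  expect_true(all(tmd$index[upper.tri(tmd$index)] == 0))
})

test_that("the planted progenitor-effector coupling dominates the islet matrix", {
  # scaled-down version of the acceptance check (3 seeds, default
  # study-scale conditions)
  hits <- 0; n_seeds <- 3
  for (sd in 1:n_seeds) {
    rep <- generate_repertoire(sim_config(), seed = sd)
    tc <- rep$truth$cells
    x <- tc[tc$tetramer == "pos" & tc$tissue == "islet", ]
    ids <- paste0(x$experiment, "_", x$truth_clone_id)
    tm <- transition_matrix(mk_cells(ids, x$cluster))$index
    hits <- hits + (tm["progenitor", "effector"] == max(tm, na.rm = TRUE))
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("cluster composition frequencies sum to one and track a planted multinomial", {
  meta <- data.frame(sample_id = "s1", cluster = "only")
  cc <- cluster_composition(meta[rep(1, 5), ])
  expect_equal(cc$frequency, 1)

  meta2 <- data.frame(sample_id = rep(c("s1", "s2"), each = 4),
                      cluster = c("a", "a", "b", NA, "b", "b", "b", "a"))
  expect_warning(cc2 <- cluster_composition(meta2), "lack a cluster")
  for (g in unique(cc2$group))
    expect_equal(sum(cc2$frequency[cc2$group == g]), 1)

  # planted multinomial without clone coupling: frequencies within 3 SE
  probs <- c(0.1, 0.15, 0.2, 0.25, 0.2, 0.1)
  cfg <- tiny_config(cluster_noise_sd = 0, progeff_bonus = 0,
                     j22_effector_bonus = 0, size_effector_coef = 0,
                     p_progeff = 0,
                     base_cluster_probs = list(islet_tetpos = probs,
                                               islet_tetneg = probs,
                                               spleen_tetpos = probs))
  rep <- generate_repertoire(cfg, seed = 6)
  m <- rep$metadata[rep$metadata$sample_id == "e1_islet_tetneg", ]
  cc3 <- cluster_composition(m)
  n <- nrow(m)
  outside <- 0
  for (k in seq_along(cfg$islet_clusters)) {
    p <- probs[k]
    f <- cc3$frequency[cc3$cluster == cfg$islet_clusters[k]]
    outside <- outside + (abs(f - p) >= 3 * sqrt(p * (1 - p) / n))
  }
  # 3-SE per category; allow one chance exceedance across the 6 categories
  expect_lte(outside, 1)
})

test_that("usage-by-gene tables are per-gene distributions with a guarded test", {
  cells <- data.frame(
    jb = rep(c("TRBJ2-2", "TRBJ2-4"), each = 40),
    cluster = rep(c("eff", "prog"), 40), stringsAsFactors = FALSE)
  u <- usage_by_gene(cells, "jb", c("TRBJ2-2", "TRBJ2-4"))
  for (g in unique(u$freq$gene))
    expect_equal(sum(u$freq$frequency[u$freq$gene == g]), 1)
  # identical distributions: p near 1
  expect_gt(u$chisq$p.value, 0.95)

  # degenerate input: test skipped with a reason, not an error
  cells2 <- data.frame(jb = c("TRBJ2-2", "TRBJ2-4"),
                       cluster = c("eff", "prog"))
  u2 <- usage_by_gene(cells2, "jb", c("TRBJ2-2", "TRBJ2-4"))
  expect_null(u2$chisq)
  expect_match(u2$test_skipped_reason, "fewer than 2")
  expect_warning(usage_by_gene(cells, "jb", c("TRBJ2-2", "TRBJX")),
                 "not observed")
})

test_that("planted effector enrichment is detected with high power", {
  # direct power simulation of the statistic at a planted logit bonus
  hits <- 0; n_sims <- 60
  for (i in 1:n_sims) {
    set.seed(i + 400)
    n <- 900
    jb <- sample(c("TRBJ2-2", "TRBJ2-4", "TRBJ2-7"), n, TRUE)
    base <- c(eff = 0.3, prog = 0.4, other = 0.3)
    cl <- vapply(jb, function(g) {
      p <- base
      if (g == "TRBJ2-2") p["eff"] <- p["eff"] * exp(1)
      sample(names(p), 1, prob = p / sum(p))
    }, character(1))
    u <- usage_by_gene(data.frame(jb = jb, cluster = cl), "jb",
                       c("TRBJ2-2", "TRBJ2-4", "TRBJ2-7"))
    f <- u$freq[u$freq$cluster == "eff", ]
    top <- f$frequency[f$gene == "TRBJ2-2"] >
      max(f$frequency[f$gene != "TRBJ2-2"])
    hits <- hits + (top && u$chisq$p.value < 0.01)
  }
  expect_gte(hits / n_sims, 0.95)
})

mk_logit_set <- function(size, jb) {
  structure(list(definition = "paired_nt",
                 clones = data.frame(
                   clone_id = sprintf("c%04d", seq_along(size)),
                   size = size, jb = jb, stringsAsFactors = FALSE)),
            class = "clone_set")
}

test_that("gene-usage logistic regression honors symmetry and detects planted slopes", {
  # symmetric construction: same size multiset in both usage groups
  sizes <- rep(c(2, 3, 5, 9, 17), 2)
  jb <- rep(c("TRBJ2-2", "TRBJ2-4"), each = 5)
  fit <- gene_usage_logistic(mk_logit_set(sizes, jb), "jb", "TRBJ2-2")
  expect_lt(abs(fit$slope), 1e-8)

  expect_error(gene_usage_logistic(mk_logit_set(c(2, 3), c("a", "b")),
                                   "jb", "a"), "at least 10")

  # planted slope recovery (full criterion in the acceptance suite)
  set.seed(31)
  ok <- 0
  for (i in 1:10) {
    sz <- pmin(rgeom(1000, 0.25) + 2, 200)
    eta <- -1.5 + 0.8 * log2(sz)
    use <- rbinom(1000, 1, plogis(eta))
    fit <- gene_usage_logistic(
      mk_logit_set(sz, ifelse(use == 1, "TRBJ2-2", "other")),
      "jb", "TRBJ2-2")
    ok <- ok + (abs(fit$slope - 0.8) <= 2 * fit$se_slope)
  }
  expect_gte(ok, 9)
})

test_that("logistic LRT agrees with the contingency-table chi-squared on a collapsed toy", {
  # binary size classes: clones of size 2 vs size 16
  set.seed(12)
  n <- 400
  big <- rbinom(n, 1, 0.5)
  use <- rbinom(n, 1, ifelse(big == 1, 0.7, 0.3))
  cs <- mk_logit_set(ifelse(big == 1, 16, 2),
                     ifelse(use == 1, "TRBJ2-2", "other"))
  fit <- gene_usage_logistic(cs, "jb", "TRBJ2-2")
  tab <- table(big, use)
  cq <- chisq.test(tab, correct = FALSE)
  # same direction and comparable magnitude (LRT vs Pearson chi-squared)
  expect_gt(fit$slope, 0)
  expect_equal(fit$lrt_stat, unname(cq$statistic), tolerance = 0.1)
  expect_lt(fit$p_value, 0.001)
})

test_that("complete separation is flagged rather than silently diverging", {
  sz <- c(rep(2, 10), rep(50, 10))
  jb <- rep(c("other", "TRBJ2-2"), each = 10)
  fit <- gene_usage_logistic(mk_logit_set(sz, jb), "jb", "TRBJ2-2")
  expect_true(fit$separation)
})

test_that("null LRT p-values are approximately uniform", {
  # reduced-size version of the acceptance uniformity check
  set.seed(8)
  pvals <- vapply(1:200, function(i) {
    sz <- pmin(rgeom(300, 0.3) + 2, 150)
    use <- rbinom(300, 1, 0.4)
    gene_usage_logistic(
      mk_logit_set(sz, ifelse(use == 1, "TRBJ2-2", "other")),
      "jb", "TRBJ2-2")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
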