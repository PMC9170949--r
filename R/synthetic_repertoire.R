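# Synthetic paired scTCR-seq repertoire generator with full planted-truth
# bookkeeping. Emulates two pooled tetramer-sorting experiments with three
# sorted samples each (islet tetramer-negative, islet tetramer-positive,
# spleen tetramer-positive), restricted gene usage and planted CDR3
# amino-acid motifs among tetramer-positive clones, heavy-tailed clone
# sizes, clone-cluster coupling, and controlled between-experiment clone
# sharing.

#' Simulation configuration
#'
#' All defaults emulate the study conditions of two independent pooled
#' experiments of tetramer-sorted CD8 T cells: per-sample cell counts at
#' the recovered-cell scale, one dominant alpha V/J and beta V gene among
#' tetramer-positive cells, a beta J distribution concentrated on
#' TRBJ2-2/2-4/2-7, heavy-tailed clone sizes with tetramer-positive clones
#' far more expanded, planted CDR3 amino-acid motifs per beta J family plus
#' a dominant alpha-chain motif, clone-cluster coupling (progenitor-
#' effector sharing, a TRBJ2-2 effector bonus, a clone-size effector
#' coupling), explicit between-experiment shared-clone counts, and a
#' negative-binomial expression model with planted gene-set effects.
#'
#' @param n_experiments number of pooled experiments
#' @param cells_per_sample matrix (experiments x sample types
#'   `islet_tetneg`, `islet_tetpos`, `spleen_tetpos`) of cell counts
#' @param clone_size_law `"power_law"` (discrete, exponent parameters) or
#'   `"geometric"` (probability parameters)
#' @param size_param_tetpos,size_param_tetneg law parameter per tetramer
#'   status
#' @param size_max_tetpos,size_max_tetneg clone-size truncation points
#' @param p_av,p_aj,p_bv probabilities of the dominant TRAV16N / TRAJ42 /
#'   TRBV13-3 genes among tetramer-positive clones
#' @param jb_probs_tetpos target cell-level beta J usage among
#'   tetramer-positive cells (`other` is spread over the remaining panel);
#'   the clone-level base logits are solved deterministically so this
#'   target holds in expectation under the size coupling
#' @param jb_size_coef per-gene log-odds shift of beta J choice per
#'   doubling of clone size (the planted usage-expansion association:
#'   positive for TRBJ2-2, negative for TRBJ2-7)
#' @param n_insert_mean mean of the geometric N-insertion length law (nt)
#' @param d_len_range min/max nt taken from a D gene in beta junctions
#' @param p_alpha_motif probability that a TRAV16N/TRAJ42 clone carries the
#'   planted alpha motif `RDSG`
#' @param beta_motifs planted beta motif (possibly with `-` wildcards) and
#'   planting probability per dominant beta J family
#' @param p_tetneg_family probability a tetramer-negative clone belongs to
#'   the planted convergent family (`E-RGS` alpha / `RGQSN` beta motifs,
#'   restricted gene usage)
#' @param unpaired_rate fraction of cells recovering only one chain
#' @param alpha_only_frac fraction of unpaired cells that are alpha-only
#' @param multi_alpha_rate fraction of alpha-bearing cells with a secondary
#'   productive alpha contig (always at lower UMI count)
#' @param unproductive_rate fraction of cells with an extra unproductive
#'   contig
#' @param syn_clone_rate fraction of tetramer-positive clones generated as
#'   synonymous twins of another clone (same amino acids, different
#'   nucleotides)
#' @param n_shared_paired,n_shared_alpha,n_shared_beta tetramer-positive
#'   clones of later experiments sharing, with experiment 1, both chains /
#'   the alpha chain only / the beta chain only
#' @param n_shared_tetneg tetramer-negative clones shared between
#'   experiments
#' @param islet_clusters,spleen_clusters phenotypic cluster label sets
#' @param base_cluster_probs baseline cluster probabilities per
#'   (tissue, tetramer) context
#' @param p_progeff probability a tetramer-positive clone is planted on the
#'   progenitor-effector axis
#' @param progeff_bonus logit bonus on islet progenitor and effector for
#'   axis clones
#' @param j22_effector_bonus logit bonus on effector phenotypes for
#'   TRBJ2-2 clones
#' @param size_effector_coef effector/mitotic logit shift per doubling of
#'   clone size
#' @param cluster_noise_sd sd of per-clone cluster-logit noise
#' @param n_genes,nb_size,filler_gene_mean,gene_mean_log_sd,n_mito,
#'   mito_gene_mean expression model: gene count, negative-binomial size
#'   (inverse dispersion), log-normal law of baseline gene means (shared
#'   by gene-set genes and background so controls are abundance-matched),
#'   mitochondrial gene count/mean
#' @param geneset_delta planted log-scale gene-set effect in designated
#'   clusters
#' @param geneset_deltas optional named vector of per-set deltas overriding
#'   `geneset_delta` (e.g. to plant a single programme; simultaneously
#'   planted programmes contaminate each other's expression-matched
#'   controls, as correlated programmes do in real data)
#' @param apoptotic_rate,lowq_rate rates of high-mitochondrial and
#'   low-complexity cells (exercise the QC filters)
#' @param seed master seed; all randomness is derived from it via named
#'   streams
#' @return list of class `sim_config`
#' @export
sim_config <- function(
    n_experiments = 2,
    cells_per_sample = rbind(
      e1 = c(islet_tetneg = 5550, islet_tetpos = 1011, spleen_tetpos = 2959),
      e2 = c(islet_tetneg = 8495, islet_tetpos = 1585, spleen_tetpos = 2361)),
    clone_size_law = "power_law",
    size_param_tetpos = 1.5, size_param_tetneg = 2.2,
    size_max_tetpos = 400, size_max_tetneg = 250,
    p_av = 0.99, p_aj = 0.89, p_bv = 0.90,
    jb_probs_tetpos = c(`TRBJ2-2` = 0.40, `TRBJ2-4` = 0.30,
                        `TRBJ2-7` = 0.25, other = 0.05),
    jb_size_coef = c(`TRBJ2-2` = 0.15, `TRBJ2-4` = 0.05, `TRBJ2-7` = -0.10),
    n_insert_mean = 4, d_len_range = c(0, 7),
    p_alpha_motif = 0.80,
    beta_motifs = list(
      `TRBJ2-2` = list(motif = "SDP", prob = 0.78),
      `TRBJ2-4` = list(motif = "GDN", prob = 0.29),
      `TRBJ2-7` = list(motif = "S-DW", prob = 0.24)),
    p_tetneg_family = 0.015,
    unpaired_rate = 0.396, alpha_only_frac = 0.35,
    multi_alpha_rate = 0.06, unproductive_rate = 0.02,
    syn_clone_rate = 0.03,
    n_shared_paired = 7, n_shared_alpha = 16, n_shared_beta = 4,
    n_shared_tetneg = 2,
    islet_clusters = c("bystander", "progenitor", "effector",
                       "recently_activated", "mitotic", "anergic"),
    spleen_clusters = c("effector_memory", "AY036118", "central_memory",
                        "cx3cr1_effector", "exhausted", "anergic"),
    base_cluster_probs = list(
      islet_tetpos = c(0.14, 0.06, 0.10, 0.22, 0.24, 0.24),
      islet_tetneg = c(0.45, 0.20, 0.10, 0.12, 0.05, 0.08),
      spleen_tetpos = c(0.25, 0.15, 0.20, 0.20, 0.10, 0.10)),
    p_progeff = 0.35, progeff_bonus = 3.5,
    j22_effector_bonus = 1.0, size_effector_coef = 0.25,
    cluster_noise_sd = 2.5,
    n_genes = 600, nb_size = 4,
    filler_gene_mean = 2, gene_mean_log_sd = 0.8,
    n_mito = 8, mito_gene_mean = 4.8,
    geneset_delta = 0.5, geneset_deltas = NULL,
    apoptotic_rate = 0.02, lowq_rate = 0.02,
    seed = 1) {
  cfg <- as.list(environment())
  stopifnot(nrow(cfg$cells_per_sample) == n_experiments,
            all(cfg$cells_per_sample > 0),
            abs(sum(jb_probs_tetpos) - 1) < 1e-9,
            clone_size_law %in% c("power_law", "geometric"))
  structure(cfg, class = "sim_config")
}

# draw clone sizes from the configured law until `budget` cells are
# covered; the last clone is truncated to fit exactly
draw_clone_sizes <- function(law, param, kmax, budget) {
  sizes <- if (law == "power_law") {
    k <- seq_len(kmax)
    p <- k^(-param); p <- p / sum(p)
    sample(k, budget, replace = TRUE, prob = p)
  } else {
    pmin(stats::rgeom(budget, param) + 1L, kmax)
  }
  cum <- cumsum(sizes)
  n <- which(cum >= budget)[1]
  sizes <- sizes[seq_len(n)]
  sizes[n] <- sizes[n] - (cum[n] - budget)
  sizes[sizes > 0]
}

# Solve clone-level base logits of the beta J softmax so that the
# expected CELL-level usage matches the configured target under the clone
# size law and size coupling. Deterministic fixed-point iteration over the
# size pmf; no RNG.
solve_jb_base <- function(cfg) {
  cats <- names(cfg$jb_probs_tetpos)
  target <- cfg$jb_probs_tetpos
  coef <- stats::setNames(rep(0, length(cats)), cats)
  coef[names(cfg$jb_size_coef)] <- cfg$jb_size_coef
  k <- seq_len(cfg$size_max_tetpos)
  pk <- if (cfg$clone_size_law == "power_law") k^(-cfg$size_param_tetpos)
        else stats::dgeom(k - 1, cfg$size_param_tetpos)
  pk <- pk / sum(pk)
  w <- k * pk / sum(k * pk)  # cell-level weight of each clone size
  shift <- outer(log2(k) - 1, coef)
  base <- log(target)
  for (it in 1:80) {
    lg <- shift + matrix(base, length(k), length(cats), byrow = TRUE)
    pr <- exp(lg); pr <- pr / rowSums(pr)
    cell_share <- colSums(pr * w)
    base <- base + 0.5 * log(target / cell_share)
    base <- base - base[1]
  }
  stats::setNames(base, cats)
}

# instantiate `-` wildcards of a motif pattern with random residues
instantiate_motifs <- function(patterns) {
  vapply(patterns, function(p) {
    if (is.na(p)) return(NA_character_)
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    wild <- ch == "-"
    if (any(wild)) ch[wild] <- sample(AA_ALPHABET, sum(wild), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Build `n` CDR3 nucleotide sequences: germline V prefix + N insertions
# (+ D segment + N for beta) + germline J suffix, with planted amino-acid
# motifs placed codon-aligned at the start of the junction for motif
# clones. Returns nt, aa, and the planted segment boundary lengths.
# Consumes RNG state; resamples junctions containing stop codons.
build_cdr3_batch <- function(vpart, jpart, motif_aa, cfg,
                             d_seqs = NULL) {
  n <- length(vpart)
  has_motif <- !is.na(motif_aa)
  vlen_full <- nchar(vpart)
  jlen_full <- nchar(jpart)
  use_d <- !is.null(d_seqs) && cfg$d_len_range[2] >= 3
  geo_p <- if (cfg$n_insert_mean > 0) 1 / (1 + cfg$n_insert_mean) else 1

  gen <- function(idx) {
    m <- length(idx)
    mot <- has_motif[idx]
    v_take <- ifelse(mot, 9L,
                     vlen_full[idx] - sample(0:4, m, replace = TRUE))
    j_trim <- ifelse(mot, 0L, sample(0:4, m, replace = TRUE))
    # junction amino acids for motif clones: the motif plus 0-2 filler
    # residues, reverse-translated so the motif is codon-aligned
    filler_n <- ifelse(mot, sample(0:2, m, replace = TRUE), 0L)
    jx_aa <- rep("", m)
    if (any(mot)) {
      fill <- vapply(filler_n[mot], function(k)
        paste(sample(AA_ALPHABET, k, replace = TRUE), collapse = ""),
        character(1))
      jx_aa[mot] <- paste0(motif_aa[idx][mot], fill)
    }
    n1_len <- ifelse(mot, 3L * nchar(jx_aa),
                     stats::rgeom(m, geo_p))
    d_len <- rep(0L, m); d_from <- rep(1L, m); d_pick <- rep(1L, m)
    if (use_d) {
      d_len <- sample(cfg$d_len_range[1]:cfg$d_len_range[2], m,
                      replace = TRUE)
      d_len[d_len < 3] <- 0L
      d_pick <- sample(length(d_seqs), m, replace = TRUE)
      room <- nchar(d_seqs)[d_pick] - d_len
      d_from <- floor(stats::runif(m) * (room + 1)) + 1L
    }
    n2_len <- if (use_d) stats::rgeom(m, max(geo_p, 0.4)) else rep(0L, m)
    j_take <- jlen_full[idx] - j_trim
    deficit <- (3 - ((v_take + n1_len + d_len + n2_len + j_take) %% 3)) %% 3
    if (cfg$n_insert_mean > 0 || use_d) {
      if (use_d) n2_len <- n2_len + deficit else n1_len <- n1_len + deficit
    } else {
      # pure V+J construction stays pure: trim the frame remainder off J
      j_take <- j_take - (3 - deficit) %% 3
    }
    n1 <- rep("", m)
    n1[mot] <- reverse_translate(jx_aa[mot])
    n1[!mot] <- random_nt_strings(n1_len[!mot])
    d_str <- if (use_d)
      ifelse(d_len > 0, substring(d_seqs[d_pick], d_from,
                                  d_from + d_len - 1), "")
    else rep("", m)
    n2 <- random_nt_strings(n2_len)
    nt <- paste0(substring(vpart[idx], 1, v_take), n1, d_str, n2,
                 substring(jpart[idx], jlen_full[idx] - j_take + 1))
    list(nt = nt, v_len = v_take, n1_len = n1_len, d_len = d_len,
         n2_len = n2_len, j_len = j_take)
  }

  res <- gen(seq_len(n))
  out_nt <- res$nt
  bounds <- data.frame(v_len = res$v_len, n1_len = res$n1_len,
                       d_len = res$d_len, n2_len = res$n2_len,
                       j_len = res$j_len)
  aa <- translate_cdr3(out_nt)
  bad <- grepl("*", aa, fixed = TRUE)
  tries <- 0
  while (any(bad) && tries < 50) {
    idx <- which(bad)
    r <- gen(idx)
    out_nt[idx] <- r$nt
    bounds[idx, ] <- data.frame(r$v_len, r$n1_len, r$d_len, r$n2_len,
                                r$j_len)
    aa[idx] <- translate_cdr3(r$nt)
    bad[idx] <- grepl("*", aa[idx], fixed = TRUE)
    tries <- tries + 1
  }
  if (any(bad))
    stop("could not build a productive junction for ", sum(bad),
         " clone(s); motif/germline combination may be infeasible")
  list(nt = out_nt, aa = aa, bounds = bounds)
}

# Build the clone table of one (experiment, tetramer-status) pool.
build_clone_pool <- function(cfg, germline, status, sizes, pool_id) {
  n <- length(sizes)
  glook <- stats::setNames(germline$seq, germline$gene)
  pick_genes <- function(dominant, panel, p_dom) {
    dom <- stats::runif(n) < p_dom
    out <- rep(dominant, n)
    others <- setdiff(panel, dominant)
    out[!dom] <- sample(others, sum(!dom), replace = TRUE)
    out
  }
  av_panel <- names(GERMLINE_PANEL$av); aj_panel <- names(GERMLINE_PANEL$aj)
  bv_panel <- names(GERMLINE_PANEL$bv); bj_panel <- names(GERMLINE_PANEL$bj)

  if (status == "tetpos") {
    va <- pick_genes("TRAV16N", av_panel, cfg$p_av)
    ja <- pick_genes("TRAJ42", aj_panel, cfg$p_aj)
    vb <- pick_genes("TRBV13-3", bv_panel, cfg$p_bv)
    # beta J via size-coupled softmax over {J2-2, J2-4, J2-7, other}
    cats <- names(cfg$jb_probs_tetpos)
    base_logit <- solve_jb_base(cfg)
    coef <- stats::setNames(rep(0, length(cats)), cats)
    coef[names(cfg$jb_size_coef)] <- cfg$jb_size_coef
    lg <- outer(log2(pmax(sizes, 1)) - 1, coef) +
      matrix(base_logit, n, length(cats), byrow = TRUE)
    pr <- exp(lg); pr <- pr / rowSums(pr)
    u <- stats::runif(n)
    cum <- pr
    for (k in seq_len(ncol(pr))[-1]) cum[, k] <- cum[, k - 1] + pr[, k]
    jb_cat <- cats[max.col(cum >= u, ties.method = "first")]
    jb <- jb_cat
    other_bj <- setdiff(bj_panel, setdiff(cats, "other"))
    jb[jb_cat == "other"] <- sample(other_bj, sum(jb_cat == "other"),
                                    replace = TRUE)
    family <- ifelse(jb %in% names(cfg$beta_motifs), jb, "none")
    alpha_motif <- rep(NA_character_, n)
    am <- va == "TRAV16N" & ja == "TRAJ42" &
      stats::runif(n) < cfg$p_alpha_motif
    alpha_motif[am] <- "RDSG"
    beta_motif <- rep(NA_character_, n)
    for (fam in names(cfg$beta_motifs)) {
      in_fam <- jb == fam & stats::runif(n) < cfg$beta_motifs[[fam]]$prob
      beta_motif[in_fam] <- cfg$beta_motifs[[fam]]$motif
    }
  } else {
    fam_flag <- stats::runif(n) < cfg$p_tetneg_family
    va <- sample(av_panel, n, replace = TRUE)
    ja <- sample(aj_panel, n, replace = TRUE)
    vb <- sample(bv_panel, n, replace = TRUE)
    jb <- sample(bj_panel, n, replace = TRUE)
    va[fam_flag] <- "TRAV4D-3"; ja[fam_flag] <- "TRAJ18"
    vb[fam_flag] <- "TRBV13-1"
    jb[fam_flag] <- sample(c("TRBJ1-4", "TRBJ1-1"), sum(fam_flag),
                           replace = TRUE)
    family <- ifelse(fam_flag, "tetneg_convergent", "none")
    alpha_motif <- ifelse(fam_flag, "E-RGS", NA_character_)
    beta_motif <- ifelse(fam_flag, "RGQSN", NA_character_)
  }

  v_bound <- stats::setNames(germline$cdr3_boundary, germline$gene)
  vpart_a <- substring(glook[va], v_bound[va])
  jpart_a <- substring(glook[ja], 1, v_bound[ja])
  vpart_b <- substring(glook[vb], v_bound[vb])
  jpart_b <- substring(glook[jb], 1, v_bound[jb])
  d_seqs <- glook[grepl("^TRBD", names(glook))]

  a <- build_cdr3_batch(vpart_a, jpart_a, instantiate_motifs(alpha_motif),
                        cfg, d_seqs = NULL)
  b <- build_cdr3_batch(vpart_b, jpart_b, instantiate_motifs(beta_motif),
                        cfg, d_seqs = unname(d_seqs))
  db <- rep(NA_character_, n)
  db[b$bounds$d_len > 0] <- "TRBD1"

  # synonymous twins: recode another clone's junction so the amino-acid
  # sequences match but the nucleotide sequences differ
  syn_of <- rep(NA_integer_, n)
  if (status == "tetpos" && cfg$syn_clone_rate > 0 && n > 2) {
    tw <- which(stats::runif(n) < cfg$syn_clone_rate)
    tw <- tw[tw > 1]
    for (i in tw) {
      donor <- sample(i - 1, 1)
      a$aa[i] <- a$aa[donor]; b$aa[i] <- b$aa[donor]
      a$nt[i] <- reverse_translate(a$aa[i])
      b$nt[i] <- reverse_translate(b$aa[i])
      if (a$nt[i] == a$nt[donor] && b$nt[i] == b$nt[donor]) next
      va[i] <- va[donor]; ja[i] <- ja[donor]
      vb[i] <- vb[donor]; jb[i] <- jb[donor]; db[i] <- db[donor]
      family[i] <- family[donor]
      alpha_motif[i] <- alpha_motif[donor]
      beta_motif[i] <- beta_motif[donor]
      a$bounds[i, ] <- NA; b$bounds[i, ] <- NA  # recoded: no planted bounds
      syn_of[i] <- donor
    }
  }

  data.frame(
    truth_clone_id = sprintf("%s_c%04d", pool_id, seq_len(n)),
    tetramer = if (status == "tetpos") "pos" else "neg",
    size = sizes, va = va, ja = ja, vb = vb, db = db, jb = jb,
    cdr3a_nt = a$nt, cdr3a_aa = a$aa, cdr3b_nt = b$nt, cdr3b_aa = b$aa,
    a_v_len = a$bounds$v_len, a_n1_len = a$bounds$n1_len,
    a_j_len = a$bounds$j_len,
    b_v_len = b$bounds$v_len, b_n1_len = b$bounds$n1_len,
    b_d_len = b$bounds$d_len, b_n2_len = b$bounds$n2_len,
    b_j_len = b$bounds$j_len,
    family = family, alpha_motif = alpha_motif, beta_motif = beta_motif,
    syn_of = syn_of, shared_with = NA_character_,
    progeff = FALSE,
    stringsAsFactors = FALSE
  )
}

# copy chains of experiment-1 clones into later-experiment clones to plant
# exact between-experiment overlap counts
plant_sharing <- function(pools, cfg) {
  chain_cols <- list(
    alpha = c("va", "ja", "cdr3a_nt", "cdr3a_aa", "a_v_len", "a_n1_len",
              "a_j_len", "alpha_motif"),
    beta = c("vb", "db", "jb", "cdr3b_nt", "cdr3b_aa", "b_v_len",
             "b_n1_len", "b_d_len", "b_n2_len", "b_j_len", "beta_motif")
  )
  for (e in seq_along(pools)[-1]) {
    for (status in c("tetpos", "tetneg")) {
      donor <- pools[[1]][[status]]
      recv <- pools[[e]][[status]]
      plan <- if (status == "tetpos")
        c(paired = cfg$n_shared_paired, alpha = cfg$n_shared_alpha,
          beta = cfg$n_shared_beta)
      else c(paired = cfg$n_shared_tetneg, alpha = 0, beta = 0)
      don_ok <- which(donor$size >= 2)
      rec_ok <- which(recv$size >= 2 & is.na(recv$syn_of))
      need <- sum(plan)
      if (length(don_ok) < need || length(rec_ok) < need) {
        warning("not enough non-singlet clones to plant all shared clones",
                " in experiment ", e, " (", status, ")")
        next
      }
      # prefer expanded clones so planted sharing survives tissue
      # splitting and chain-recovery attenuation in per-sample overlaps
      pick_pref <- function(ok, sizes) {
        pref <- ok[sizes[ok] >= 8]
        pref <- pref[sample.int(length(pref))]
        rest <- setdiff(ok, pref)[sample.int(length(setdiff(ok, pref)))]
        c(pref, rest)[seq_len(need)]
      }
      don_pick <- pick_pref(don_ok, donor$size)
      rec_pick <- pick_pref(rec_ok, recv$size)
      kinds <- rep(names(plan), plan)
      for (t in seq_len(need)) {
        cols <- switch(kinds[t],
                       paired = unlist(chain_cols, use.names = FALSE),
                       alpha = chain_cols$alpha, beta = chain_cols$beta)
        recv[rec_pick[t], cols] <- donor[don_pick[t], cols]
        recv$shared_with[rec_pick[t]] <-
          paste0(kinds[t], ":", donor$truth_clone_id[don_pick[t]])
      }
      pools[[e]][[status]] <- recv
    }
  }
  pools
}

softmax_draw <- function(logits) {
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  u <- stats::runif(nrow(p))
  cum <- p
  for (k in seq_len(ncol(p))[-1]) cum[, k] <- cum[, k - 1] + p[, k]
  max.col(cum >= u, ties.method = "first")
}

#' Generate a synthetic paired scTCR-seq repertoire
#'
#' Draws clone pools per experiment and tetramer status under the
#' configured clone-size law and gene-usage tables, builds CDR3 nucleotide
#' sequences as germline-V prefix + N insertions (+ D + N for beta) +
#' germline-J suffix with planted motifs, plants between-experiment shared
#' clones, assigns cells to sorted samples and phenotypic clusters, and
#' injects unpaired cells, secondary alpha contigs and unproductive
#' contigs. All cells of a clone share identical CDR3 nucleotide
#' sequences.
#'
#' @param config [sim_config()]
#' @param seed master seed (default: the config's)
#' @return list with `contigs` (contig records in [read_contig_table()]
#'   layout, all samples), `metadata` (per-cell table), `germline`, and
#'   `truth` (list: `clones` with planted boundaries/motifs/sharing,
#'   `cells` with planted clone id, chain presence and cluster)
#' @export
generate_repertoire <- function(config = sim_config(), seed = config$seed) {
  cfg <- config
  germline <- generate_germline(derive_seed(seed, "germline"))

  pools <- list()
  for (e in seq_len(cfg$n_experiments)) {
    budget <- cfg$cells_per_sample[e, ]
    pools[[e]] <- with_seed(derive_seed(seed, paste0("clones_e", e)), {
      list(
        tetpos = build_clone_pool(
          cfg, germline, "tetpos",
          draw_clone_sizes(cfg$clone_size_law, cfg$size_param_tetpos,
                           cfg$size_max_tetpos,
                           budget[["islet_tetpos"]] +
                             budget[["spleen_tetpos"]]),
          sprintf("e%d_tetpos", e)),
        tetneg = build_clone_pool(
          cfg, germline, "tetneg",
          draw_clone_sizes(cfg$clone_size_law, cfg$size_param_tetneg,
                           cfg$size_max_tetneg, budget[["islet_tetneg"]]),
          sprintf("e%d_tetneg", e))
      )
    })
  }
  pools <- with_seed(derive_seed(seed, "sharing"), plant_sharing(pools, cfg))

  # clone-level phenotype couplings
  pools <- with_seed(derive_seed(seed, "archetypes"), {
    for (e in seq_along(pools)) {
      tp <- pools[[e]]$tetpos
      tp$progeff <- stats::runif(nrow(tp)) < cfg$p_progeff
      pools[[e]]$tetpos <- tp
    }
    pools
  })

  cells_list <- list(); clones_list <- list()
  for (e in seq_len(cfg$n_experiments)) {
    budget <- cfg$cells_per_sample[e, ]
    for (status in c("tetpos", "tetneg")) {
      cl <- pools[[e]][[status]]
      cl$experiment <- sprintf("e%d", e)
      clones_list[[paste0(e, status)]] <- cl
      idx <- rep(seq_len(nrow(cl)), cl$size)
      cells <- data.frame(clone_row = idx, stringsAsFactors = FALSE)
      cells$truth_clone_id <- cl$truth_clone_id[idx]
      cells$tetramer <- if (status == "tetpos") "pos" else "neg"
      cells$experiment <- sprintf("e%d", e)
      cells <- with_seed(derive_seed(seed, paste0("tissue_e", e, status)), {
        if (status == "tetpos") {
          # clone-specific tissue propensity (U-shaped): most clones live
          # mainly in one tissue, expanded clones still span both
          prop <- stats::rbeta(nrow(cl), 0.8, 0.8)
          w <- prop[cells$clone_row]
          isl <- sample(nrow(cells), budget[["islet_tetpos"]],
                        prob = pmax(w, 1e-6))
          cells$tissue <- "spleen"
          cells$tissue[isl] <- "islet"
        } else {
          cells$tissue <- "islet"
        }
        cells
      })
      cells$sample_id <- sprintf("e%d_%s_%s", e, cells$tissue,
                                 ifelse(cells$tetramer == "pos", "tetpos",
                                        "tetneg"))
      # cluster assignment from clone-coupled logits
      cells <- with_seed(derive_seed(seed, paste0("clust_e", e, status)), {
        noise_i <- matrix(stats::rnorm(nrow(cl) * 6, 0,
                                       cfg$cluster_noise_sd), nrow(cl))
        noise_s <- matrix(stats::rnorm(nrow(cl) * 6, 0,
                                       cfg$cluster_noise_sd), nrow(cl))
        # axis clones: progenitor and effector noise move together, so the
        # planted progenitor-effector split stays balanced
        if (status == "tetpos") {
          pc <- match("progenitor", cfg$islet_clusters)
          ec <- match("effector", cfg$islet_clusters)
          noise_i[cl$progeff, pc] <- noise_i[cl$progeff, ec]
        }
        cells$cluster <- NA_character_
        for (tis in unique(cells$tissue)) {
          rows <- which(cells$tissue == tis)
          labs <- if (tis == "islet") cfg$islet_clusters
                  else cfg$spleen_clusters
          ctx <- paste0(tis, "_", ifelse(status == "tetpos", "tetpos",
                                         "tetneg"))
          base <- log(cfg$base_cluster_probs[[ctx]])
          lg <- matrix(base, length(rows), 6, byrow = TRUE) +
            (if (tis == "islet") noise_i else noise_s)[cells$clone_row[rows],
                                                       , drop = FALSE]
          eff_col <- match(if (tis == "islet") "effector"
                           else "cx3cr1_effector", labs)
          sz <- cl$size[cells$clone_row[rows]]
          lg[, eff_col] <- lg[, eff_col] +
            cfg$size_effector_coef * (log2(sz) - 1) +
            cfg$j22_effector_bonus *
              (cl$jb[cells$clone_row[rows]] == "TRBJ2-2")
          if (tis == "islet") {
            mit_col <- match("mitotic", labs)
            lg[, mit_col] <- lg[, mit_col] +
              cfg$size_effector_coef * (log2(sz) - 1)
            pe <- cl$progeff[cells$clone_row[rows]]
            pcol <- match("progenitor", labs)
            lg[, pcol] <- lg[, pcol] + cfg$progeff_bonus * pe +
              cfg$size_effector_coef * (log2(sz) - 1) * pe
            lg[, eff_col] <- lg[, eff_col] + cfg$progeff_bonus * pe
          }
          cells$cluster[rows] <- labs[softmax_draw(lg)]
        }
        cells
      })
      cells_list[[paste0(e, status)]] <- cells
    }
  }
  clones <- do.call(rbind, clones_list)
  cells <- do.call(rbind, cells_list)
  rownames(clones) <- rownames(cells) <- NULL

  # barcodes and chain recovery
  cells <- with_seed(derive_seed(seed, "cells"), {
    n <- nrow(cells)
    repeat {
      chars <- sample(c("A", "C", "G", "T"), 16 * n, replace = TRUE)
      bc <- do.call(paste0, as.data.frame(matrix(chars, ncol = 16),
                                          stringsAsFactors = FALSE))
      if (!anyDuplicated(bc)) break
    }
    cells$barcode <- paste0(bc, "-1")
    unpaired <- stats::runif(n) < cfg$unpaired_rate
    a_only <- stats::runif(n) < cfg$alpha_only_frac
    cells$has_alpha <- !unpaired | a_only
    cells$has_beta <- !unpaired | !a_only
    cells
  })

  ci <- match(cells$truth_clone_id, clones$truth_clone_id)
  cells$jb <- clones$jb[ci]
  cells$clone_size <- clones$size[ci]

  contigs <- with_seed(derive_seed(seed, "contigs"), {
    mk_rows <- function(which_chain, rows) {
      n <- length(rows)
      if (n == 0) return(NULL)
      i <- ci[rows]
      umis <- stats::rpois(n, if (which_chain == "a") 3 else 5) + 2L
      data.frame(
        barcode = cells$barcode[rows], sample_id = cells$sample_id[rows],
        locus = if (which_chain == "a") "TRA" else "TRB",
        v_gene = if (which_chain == "a") clones$va[i] else clones$vb[i],
        d_gene = if (which_chain == "a") NA_character_ else clones$db[i],
        j_gene = if (which_chain == "a") clones$ja[i] else clones$jb[i],
        cdr3_aa = if (which_chain == "a") clones$cdr3a_aa[i]
                  else clones$cdr3b_aa[i],
        cdr3_nt = if (which_chain == "a") clones$cdr3a_nt[i]
                  else clones$cdr3b_nt[i],
        productive = TRUE, umis = umis,
        reads = umis * sample(40:60, n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    out <- list(mk_rows("a", which(cells$has_alpha)),
                mk_rows("b", which(cells$has_beta)))
    # secondary productive alpha contigs at strictly lower UMI count
    wa <- which(cells$has_alpha)
    sec <- wa[stats::runif(length(wa)) < cfg$multi_alpha_rate]
    if (length(sec) > 0) {
      prim <- out[[1]][match(sec, which(cells$has_alpha)), , drop = FALSE]
      glook <- stats::setNames(germline$seq, germline$gene)
      vb2 <- stats::setNames(germline$cdr3_boundary, germline$gene)
      va2 <- sample(names(GERMLINE_PANEL$av), length(sec), replace = TRUE)
      ja2 <- sample(names(GERMLINE_PANEL$aj), length(sec), replace = TRUE)
      alt <- build_cdr3_batch(substring(glook[va2], vb2[va2]),
                              substring(glook[ja2], 1, vb2[ja2]),
                              rep(NA_character_, length(sec)), cfg)
      out[[3]] <- data.frame(
        barcode = prim$barcode, sample_id = prim$sample_id, locus = "TRA",
        v_gene = va2, d_gene = NA_character_, j_gene = ja2,
        cdr3_aa = alt$aa, cdr3_nt = alt$nt, productive = TRUE,
        umis = pmax(1L, prim$umis -
                      (stats::rpois(length(sec), 1) + 1L)),
        reads = prim$reads %/% 2L, stringsAsFactors = FALSE)
    }
    # unproductive extra beta contigs (frameshifted: length not a
    # multiple of 3, no amino-acid call)
    wb <- which(cells$has_beta)
    up <- wb[stats::runif(length(wb)) < cfg$unproductive_rate]
    if (length(up) > 0) {
      i <- ci[up]
      out[[4]] <- data.frame(
        barcode = cells$barcode[up], sample_id = cells$sample_id[up],
        locus = "TRB", v_gene = clones$vb[i], d_gene = clones$db[i],
        j_gene = clones$jb[i], cdr3_aa = clones$cdr3b_aa[i],
        cdr3_nt = substring(clones$cdr3b_nt[i], 2), productive = FALSE,
        umis = 1L, reads = 40L, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    res[order(res$sample_id, res$barcode, res$locus), , drop = FALSE]
  })
  rownames(contigs) <- NULL

  metadata <- data.frame(
    barcode = cells$barcode, sample_id = cells$sample_id,
    tissue = cells$tissue, tetramer = cells$tetramer,
    cluster = cells$cluster, experiment = cells$experiment,
    stringsAsFactors = FALSE)
  metadata <- metadata[order(metadata$sample_id, metadata$barcode), ,
                       drop = FALSE]
  rownames(metadata) <- NULL

  cells$clone_row <- NULL
  list(contigs = contigs, metadata = metadata, germline = germline,
       truth = list(clones = clones, cells = cells, config = cfg,
                    seed = seed))
}
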