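# One-shot pipeline: simulate -> write fixtures -> read back -> clonotype
# -> repertoire statistics -> motifs -> module scores -> transitions, with
# an artifact manifest and an echoed configuration.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Simulates a repertoire and expression data under `config` (unless
#' `simulate = FALSE`, in which case previously written fixtures in
#' `out_dir/fixtures` are reused), writes all fixtures, reads them back
#' through the package's own readers, and runs clonotyping, overlap and
#' expansion statistics, V-J usage, motif analysis, module scoring with
#' between-group tests, and the cluster transition matrix. Every artifact
#' is listed in a manifest with its MD5 checksum; reruns with the same
#' configuration and seed are bit-identical.
#'
#' @param config [sim_config()]
#' @param out_dir output directory
#' @param seed master seed (default: the config's)
#' @param simulate set `FALSE` to reuse fixtures already in
#'   `out_dir/fixtures`
#' @return invisibly, a list with `manifest` (data.frame of files and MD5
#'   checksums) and `results` (the computed summary statistics)
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         seed = config$seed, simulate = TRUE) {
  fx <- file.path(out_dir, "fixtures")
  res_dir <- file.path(out_dir, "results")
  dir.create(fx, showWarnings = FALSE, recursive = TRUE)
  dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)

  if (simulate) {
    stage("synthetic_data", {
      rep <- generate_repertoire(config, seed)
      for (s in unique(rep$contigs$sample_id))
        write_contig_table(rep$contigs[rep$contigs$sample_id == s, ],
                           file.path(fx, paste0(s, "_contigs.csv")))
      write_cell_metadata(rep$metadata, file.path(fx, "metadata.tsv"))
      write_germline_fasta(rep$germline, file.path(fx, "germline.fa"))
      expr <- generate_expression(config, rep$truth$cells,
                                  derive_seed(seed, "expression"))
      write_expression_mtx(expr$counts, file.path(fx, "expression"))
      write_gene_sets(expr$gene_sets, file.path(fx, "gene_sets"))
    })
  }

  # ---- read everything back through the package readers ----
  inputs <- stage("io_formats", {
    contig_files <- list.files(fx, pattern = "_contigs\\.csv$",
                               full.names = TRUE)
    if (length(contig_files) == 0)
      stop("no contig tables found under ", fx)
    contigs <- do.call(rbind, lapply(contig_files, function(p)
      read_contig_table(p, sub("_contigs\\.csv$", "", basename(p)))))
    meta <- read_cell_metadata(file.path(fx, "metadata.tsv"))
    germ <- read_germline_fasta(file.path(fx, "germline.fa"))
    counts <- read_expression_mtx(file.path(fx, "expression"))
    sets <- lapply(list.files(file.path(fx, "gene_sets"),
                              full.names = TRUE), read_gene_list)
    names(sets) <- sub("\\.txt$", "",
                       list.files(file.path(fx, "gene_sets")))
    list(contigs = contigs, meta = meta, germ = germ, counts = counts,
         sets = sets)
  })

  meta <- inputs$meta
  results <- list()

  # ---- clonotyping ----
  cl <- stage("clonotyping", {
    profiles <- consolidate_cell_chains(inputs$contigs)
    mi <- match(paste(profiles$sample_id, profiles$barcode),
                paste(meta$sample_id, meta$barcode))
    profiles$experiment <- meta$experiment[mi]
    profiles$tetramer <- meta$tetramer[mi]
    profiles$tissue <- meta$tissue[mi]
    profiles$cluster <- meta$cluster[mi]
    pr <- pairing_rate(profiles)
    exps <- sort(unique(profiles$experiment))
    per_exp <- lapply(exps, function(e) {
      p <- profiles[profiles$experiment == e, ]
      stats::setNames(lapply(CLONE_DEFINITIONS, function(d)
        call_clones(p, d)), CLONE_DEFINITIONS)
    })
    names(per_exp) <- exps
    clones_tab <- do.call(rbind, lapply(exps, function(e) {
      x <- per_exp[[e]]$paired_nt$clones
      x$experiment <- e
      x
    }))
    write_tsv(clones_tab, file.path(res_dir, "clones_paired_nt.tsv"))
    list(profiles = profiles, per_exp = per_exp, pairing = pr)
  })
  results$pairing_percent <- cl$pairing$percent
  results$n_cells <- cl$pairing$total

  profiles <- cl$profiles
  exps <- names(cl$per_exp)

  # ---- repertoire statistics ----
  results <- c(results, stage("repertoire_stats", {
    out <- list()
    if (length(exps) >= 2) {
      sub2 <- function(e, def, samples)
        subset_clone_set(cl$per_exp[[e]][[def]], samples = samples)
      samp <- function(e, tis, tet)
        sprintf("%s_%s_%s", e, tis, tet)
      ov <- function(def, samples_of) {
        sets <- lapply(exps[1:2], function(e)
          sub2(e, def, samples_of(e)))
        clone_overlap(sets[[1]], sets[[2]], labels = exps[1:2])
      }
      out$overlap_islet_tetpos <- ov("paired_nt", function(e)
        samp(e, "islet", "tetpos"))
      out$overlap_islet_tetneg <- ov("paired_nt", function(e)
        samp(e, "islet", "tetneg"))
      out$overlap_spleen_tetpos <- ov("paired_nt", function(e)
        samp(e, "spleen", "tetpos"))
      out$overlap_combined <- ov("paired_nt", function(e) NULL)
      out$overlap_alpha <- ov("alpha_nt", function(e) NULL)
      out$overlap_beta <- ov("beta_nt", function(e) NULL)
      upset <- multiset_overlap(stats::setNames(
        lapply(exps[1:2], function(e) cl$per_exp[[e]]$paired_nt), exps[1:2]))
      write_tsv(upset, file.path(res_dir, "overlap_patterns.tsv"))
    }
    pool_clones <- function(tet) {
      do.call(rbind, lapply(exps, function(e) {
        s <- cl$per_exp[[e]]$paired_nt
        s$clones[s$clones$clone_id %in%
                   s$members$clone_id[s$members$sample_id %in%
                     meta$sample_id[meta$tetramer == tet]], ]
      }))
    }
    tp <- pool_clones("pos"); tn <- pool_clones("neg")
    out$mean_size_tetpos <- mean(tp$size[tp$size >= 2])
    out$mean_size_tetneg <- mean(tn$size[tn$size >= 2])
    use_cells <- profiles[profiles$paired & profiles$tetramer == "pos", ]
    ua <- vj_usage(data.frame(va = use_cells$va, ja = use_cells$ja,
                              vb = use_cells$vb, jb = use_cells$jb),
                   "TRA", "cell")
    ub <- vj_usage(data.frame(va = use_cells$va, ja = use_cells$ja,
                              vb = use_cells$vb, jb = use_cells$jb),
                   "TRB", "cell")
    write_tsv(as.data.frame(ua$joint), file.path(res_dir,
                                                 "usage_tra_tetpos.tsv"))
    write_tsv(as.data.frame(ub$joint), file.path(res_dir,
                                                 "usage_trb_tetpos.tsv"))
    out$usage_trav16n <- unname(ua$v_marginal["TRAV16N"])
    out$usage_traj42 <- unname(ua$j_marginal["TRAJ42"])
    out$usage_trbv13_3 <- unname(ub$v_marginal["TRBV13-3"])
    out$usage_trbj_dominant <- sum(ub$j_marginal[
      c("TRBJ2-2", "TRBJ2-4", "TRBJ2-7")], na.rm = TRUE)
    out$tetpos_clones <- tp
    out$tetneg_clones <- tn
    out
  }))

  # ---- motif analysis ----
  results <- c(results, stage("motif_junction", {
    out <- list()
    tp <- results$tetpos_clones
    tp2 <- tp[tp$size >= 2, ]
    out$n_motif_clones <- nrow(tp2)
    out$motif_rdsg <- motif_frequency(tp2, "RDSG", "alpha")
    out$motif_ssdp <- motif_frequency(tp2, "SSDP", "beta")
    out$motif_gdn <- motif_frequency(tp2, "GDN", "beta")
    out$motif_sdw <- motif_frequency(tp2, "S-DW", "beta")
    fake_set <- structure(list(definition = "paired_nt", clones = tp2),
                          class = "clone_set")
    origins <- attribute_clone_segments(fake_set, inputs$germ)
    grp_src <- tp2[order(-tp2$size), ][seq_len(min(nrow(tp2), 120)), ]
    groups <- cluster_motif_groups(
      structure(list(definition = "paired_nt", clones = grp_src),
                class = "clone_set"),
      cut_height = 60, origins = origins)
    out$n_motif_groups <- length(groups)
    gs <- data.frame(
      group = names(groups),
      n_clones = vapply(groups, function(g) g$size, numeric(1)),
      consensus_a = vapply(groups, function(g) g$consensus_a, character(1)),
      consensus_b = vapply(groups, function(g) g$consensus_b, character(1)))
    write_tsv(gs, file.path(res_dir, "motif_groups.tsv"))
    out
  }))

  # ---- gene-usage association ----
  results <- c(results, stage("usage_association", {
    out <- list()
    tp_set <- structure(list(definition = "paired_nt",
                             clones = results$tetpos_clones),
                        class = "clone_set")
    for (g in c("TRBJ2-2", "TRBJ2-4", "TRBJ2-7")) {
      out[[paste0("logit_", g)]] <-
        gene_usage_logistic(tp_set, "jb", g)
    }
    islet_pos <- profiles[profiles$paired & profiles$tetramer == "pos" &
                            profiles$tissue == "islet", ]
    out$usage_by_jb <- usage_by_gene(islet_pos, "jb",
                                     c("TRBJ2-2", "TRBJ2-4", "TRBJ2-7"))
    write_tsv(out$usage_by_jb$freq,
              file.path(res_dir, "cluster_by_trbj.tsv"))
    out
  }))

  # ---- module scores ----
  results <- c(results, stage("phenotype_scores", {
    out <- list()
    filt <- filter_cells(inputs$counts)
    out$qc <- filt$report
    norm <- normalize_expression(filt$expr)
    keep <- rownames(norm)
    mi <- match(keep, meta$barcode)
    pi <- match(keep, profiles$barcode)
    groups <- data.frame(barcode = keep, cluster = meta$cluster[mi],
                         tetramer = meta$tetramer[mi],
                         tissue = meta$tissue[mi],
                         jb = profiles$jb[pi], stringsAsFactors = FALSE)
    score_tabs <- list()
    for (nm in names(inputs$sets)) {
      sc <- module_score(norm, inputs$sets[[nm]],
                         seed = derive_seed(seed, paste0("score_", nm)))
      sc <- cbind(sc, groups[match(sc$barcode, groups$barcode),
                             -1, drop = FALSE])
      score_tabs[[nm]] <- sc
    }
    out$scores <- score_tabs
    ts <- score_tabs$tcr_signaling_set
    ts <- ts[!is.na(ts$jb) & ts$jb %in% c("TRBJ2-2", "TRBJ2-4", "TRBJ2-7") &
               ts$tetramer == "pos" & ts$tissue == "islet", ]
    out$tcr_signaling_by_jb <- tapply(ts$score, ts$jb, mean)
    out$tcr_signaling_tests <- compare_groups(ts, ts$jb)
    write_tsv(out$tcr_signaling_tests,
              file.path(res_dir, "tcr_signaling_tests.tsv"))
    out
  }))

  # ---- transitions ----
  results <- c(results, stage("clonal_phenotype", {
    out <- list()
    tp_cells <- do.call(rbind, lapply(exps, function(e) {
      s <- cl$per_exp[[e]]$paired_nt
      m <- s$members
      mi <- match(paste(m$sample_id, m$barcode),
                  paste(meta$sample_id, meta$barcode))
      data.frame(clone_id = paste0(e, "_", m$clone_id),
                 cluster = paste(meta$tissue[mi], meta$cluster[mi],
                                 sep = ":"),
                 tetramer = meta$tetramer[mi], stringsAsFactors = FALSE)
    }))
    tp_cells <- tp_cells[tp_cells$tetramer == "pos" &
                           !is.na(tp_cells$cluster), ]
    tm <- transition_matrix(tp_cells)
    write_tsv(as.data.frame(tm$index),
              file.path(res_dir, "transition_matrix.tsv"))
    out$transitions <- tm
    comp <- cluster_composition(meta)
    write_tsv(comp, file.path(res_dir, "cluster_composition.tsv"))
    out
  }))

  # ---- manifest and config echo ----
  cfg_path <- file.path(out_dir, "config.yaml")
  cfg_echo <- config
  cfg_echo$cells_per_sample <- apply(config$cells_per_sample, 1, as.list,
                                     simplify = FALSE)
  yaml::write_yaml(c(list(seed = seed), unclass(cfg_echo)), cfg_path)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- data.frame(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(manifest = manifest, results = results))
}
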