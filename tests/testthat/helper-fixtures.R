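# Shared fixture builders and independent oracles.

# small contig table builder
contig_row <- function(barcode, chain, v = "TRAV16N", j = "TRAJ42",
                       cdr3 = "CAVSNAKLTF",
                       cdr3_nt = "TGTGCTGTGAGCAACGCCAAGCTGACCTTT",
                       productive = "True", umis = 5, reads = 200,
                       d = "None") {
  data.frame(barcode = barcode, chain = chain, v_gene = v, d_gene = d,
             j_gene = j, cdr3 = cdr3, cdr3_nt = cdr3_nt,
             productive = productive, umis = umis, reads = reads,
             stringsAsFactors = FALSE)
}

write_contig_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# a scaled-down configuration: ~2,000 cells over two experiments
tiny_config <- function(...) {
  sim_config(
    cells_per_sample = rbind(
      e1 = c(islet_tetneg = 400, islet_tetpos = 250, spleen_tetpos = 350),
      e2 = c(islet_tetneg = 400, islet_tetpos = 250, spleen_tetpos = 350)),
    n_shared_paired = 3, n_shared_alpha = 5, n_shared_beta = 2,
    n_shared_tetneg = 1, size_max_tetpos = 100, size_max_tetneg = 60, ...)
}

# expected clone partition from planted truth: group eligible cells by the
# planted CDR3 key of the definition (independent of call_clones internals)
truth_partition <- function(truth, definition) {
  cells <- truth$cells
  cl <- truth$clones[match(cells$truth_clone_id, truth$clones$truth_clone_id), ]
  key <- switch(definition,
    paired_nt = paste(cl$cdr3a_nt, cl$cdr3b_nt, sep = "+"),
    paired_aa = paste(cl$cdr3a_aa, cl$cdr3b_aa, sep = "+"),
    alpha_nt = cl$cdr3a_nt,
    beta_nt = cl$cdr3b_nt)
  elig <- switch(definition,
    paired_nt = , paired_aa = cells$has_alpha & cells$has_beta,
    alpha_nt = cells$has_alpha,
    beta_nt = cells$has_beta)
  data.frame(cell = paste(cells$sample_id, cells$barcode)[elig],
             key = key[elig], stringsAsFactors = FALSE)
}

# partitions-as-sets comparison: same grouping of the same cells?
same_partition <- function(cells_a, keys_a, cells_b, keys_b) {
  if (length(cells_a) != length(cells_b)) return(FALSE)
  if (!setequal(cells_a, cells_b)) return(FALSE)
  ga <- split(cells_a, keys_a)
  gb <- split(cells_b, keys_b)
  setequal(lapply(ga, sort), lapply(gb, sort))
}

# independent brute-force transition index: plain loops, no shared code
brute_transition <- function(cells, ci, cj, min_cells = 2) {
  ids <- unique(cells$clone_id)
  num <- 0; den <- 0; terms <- c()
  for (id in ids) {
    sub <- cells[cells$clone_id == id, ]
    ni <- sum(sub$cluster == ci)
    nj <- sum(sub$cluster == cj)
    if (ni + nj >= min_cells) {
      p <- ni / (ni + nj)
      h <- 0
      if (p > 0 && p < 1) h <- -p * log2(p) - (1 - p) * log2(1 - p)
      terms <- c(terms, (ni + nj) * h)
      den <- den + (ni + nj)
    }
  }
  if (den == 0) return(NA_real_)
  sum(terms) / den
}

# BLOSUM62 matrix for distance oracles
blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
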