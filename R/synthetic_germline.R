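# Synthetic germline V/D/J reference construction. Gene names mirror murine
# TCR nomenclature; every V gene carries a conserved Cys codon at its CDR3
# boundary and every J gene a conserved Phe codon at its boundary, so
# junction attribution behaves as on real references.

# CDR3-contributing amino acids per gene (V genes from the Cys; J genes up
# to the conserved Phe). The dominant genes of the tetramer-positive
# repertoire (TRAV16N, TRAJ42, TRBV13-3, TRBJ2-2/2-4/2-7) head each panel.
GERMLINE_PANEL <- list(
  av = c(TRAV16N = "CAVS", `TRAV4D-3` = "CAAE", `TRAV3-3` = "CAMR",
         `TRAV6-5` = "CALG", `TRAV9N-3` = "CAVN", `TRAV12-1` = "CALS",
         `TRAV14-2` = "CAAS", TRAV19 = "CAAG"),
  aj = c(TRAJ42 = "SNAKLTF", TRAJ18 = "GSALGRF", TRAJ27 = "NTGKLTF",
         TRAJ31 = "SNNRIFF", TRAJ37 = "GNTGKLF", TRAJ53 = "GGSNYKF",
         TRAJ56 = "GGNNKLF", TRAJ9 = "NMGYKLF"),
  bv = c(`TRBV13-3` = "CASS", `TRBV13-1` = "CASR", TRBV1 = "CTCS",
         TRBV5 = "CASQ", TRBV19 = "CAST", TRBV29 = "CASN",
         TRBV2 = "CASG", TRBV16 = "CASL"),
  bj = c(`TRBJ2-2` = "NTGQLYF", `TRBJ2-4` = "SQNTLYF", `TRBJ2-7` = "SYEQYF",
         `TRBJ1-1` = "NTEVFF", `TRBJ1-4` = "SNERLFF", `TRBJ2-1` = "NYAEQFF",
         `TRBJ2-3` = "SAETLYF", `TRBJ2-5` = "NQDTQYF"),
  d = c(TRBD1 = "GGGACAGGGGGC", TRBD2 = "GGGACTGGGGGGGC")
)

# codon options per amino acid, padded to a rectangular matrix for
# vectorized sampling
codon_table <- local({
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc_tab), unname(gc_tab))
  by_aa <- by_aa[names(by_aa) != "*"]
  width <- max(lengths(by_aa))
  mat <- t(vapply(by_aa, function(x) rep(x, length.out = width),
                  character(width)))
  list(mat = mat, n = lengths(by_aa))
})

# vectorized reverse translation with uniformly sampled synonymous codons;
# consumes RNG state
reverse_translate <- function(aa) {
  n_aa <- nchar(aa)
  if (sum(n_aa) == 0) return(rep("", length(aa)))
  letters <- unlist(strsplit(aa, "", fixed = TRUE), use.names = FALSE)
  idx <- match(letters, rownames(codon_table$mat))
  if (anyNA(idx))
    stop("cannot reverse-translate character(s): ",
         paste(unique(letters[is.na(idx)]), collapse = ", "))
  nopt <- codon_table$n[idx]
  pick <- floor(stats::runif(length(idx)) * nopt) + 1
  codons <- codon_table$mat[cbind(idx, pick)]
  grp <- rep(seq_along(aa), n_aa)
  out <- rep("", length(aa))
  have <- tapply(codons, factor(grp, levels = seq_along(aa)), paste,
                 collapse = "")
  out[n_aa > 0] <- have[n_aa > 0]
  unname(out)
}

random_nt <- function(total) {
  if (total <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), total, replace = TRUE)
}

# split `total` random nucleotides into strings of the given lengths
random_nt_strings <- function(lens) {
  out <- rep("", length(lens))
  tot <- sum(lens)
  if (tot == 0) return(out)
  nts <- random_nt(tot)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  s <- paste(nts, collapse = "")
  ifelse(lens > 0, substring(s, starts, ends), "")
}

#' Generate a synthetic germline V/D/J reference
#'
#' Builds nucleotide sequences for a murine-style gene panel: each V gene is
#' random upstream sequence followed by its CDR3 contribution starting at a
#' conserved Cys codon (the annotated boundary); each J gene is its CDR3
#' contribution ending at a conserved Phe codon (the annotated boundary)
#' followed by random downstream sequence; D genes are short G-rich
#' sequences with boundary 0. Byte-identical output for identical seeds.
#'
#' @param seed integer seed
#' @return germline data.frame (`gene`, `seq`, `cdr3_boundary`), the format
#'   of [read_germline_fasta()]
#' @export
generate_germline <- function(seed = 1) {
  with_seed(seed, {
    rows <- list()
    up_len <- 30L
    for (g in names(GERMLINE_PANEL$av)) {
      part <- reverse_translate(GERMLINE_PANEL$av[[g]])
      rows[[g]] <- data.frame(
        gene = g, seq = paste0(paste(random_nt(up_len), collapse = ""), part),
        cdr3_boundary = up_len + 1L, stringsAsFactors = FALSE)
    }
    for (g in names(GERMLINE_PANEL$bv)) {
      part <- reverse_translate(GERMLINE_PANEL$bv[[g]])
      rows[[g]] <- data.frame(
        gene = g, seq = paste0(paste(random_nt(up_len), collapse = ""), part),
        cdr3_boundary = up_len + 1L, stringsAsFactors = FALSE)
    }
    for (g in c(names(GERMLINE_PANEL$aj), names(GERMLINE_PANEL$bj))) {
      aa <- c(GERMLINE_PANEL$aj, GERMLINE_PANEL$bj)[[g]]
      part <- reverse_translate(aa)
      rows[[g]] <- data.frame(
        gene = g,
        seq = paste0(part, paste(random_nt(24L), collapse = "")),
        cdr3_boundary = nchar(part), stringsAsFactors = FALSE)
    }
    for (g in names(GERMLINE_PANEL$d)) {
      rows[[g]] <- data.frame(gene = g, seq = GERMLINE_PANEL$d[[g]],
                              cdr3_boundary = 0L, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
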