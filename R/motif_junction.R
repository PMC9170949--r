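# CDR3 amino-acid distances, motif-group clustering with position-frequency
# matrices, V(D)J junction segment-origin attribution, and motif-frequency
# reporting.

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

#' Parameters of the CDR3 amino-acid distance
#'
#' The distance follows the conventions of sequence-similarity-weighted
#' TCR clustering: a BLOSUM62-derived per-residue mismatch penalty capped
#' at `cap`, a flat per-position gap cost, a CDR3 region weight, and a
#' number of residues trimmed from each CDR3 terminus before scoring (the
#' termini are germline-invariant and carry little specificity signal).
#'
#' @param cap mismatch penalty cap (default 4)
#' @param gap_cost cost of a gap position (default 4)
#' @param weight multiplier applied to the summed CDR3 cost (default 3)
#' @param trim residues trimmed from each terminus before scoring
#'   (default 2)
#' @param sub_mat 20 x 20 integer amino-acid similarity matrix
#'   (default BLOSUM62)
#' @return object of class `distance_params`
#' @export
distance_params <- function(cap = 4, gap_cost = 4, weight = 3, trim = 2,
                            sub_mat = NULL) {
  stopifnot(cap > 0, gap_cost > 0, weight > 0, trim >= 0)
  if (is.null(sub_mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    sub_mat <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  structure(list(cap = cap, gap_cost = gap_cost, weight = weight,
                 trim = trim, sub_mat = sub_mat),
            class = "distance_params")
}

# insert a single contiguous gap block at the midpoint of `x` (character
# codes vector) so its length becomes `target`; left-biased on odd lengths
center_gap <- function(x, target) {
  g <- target - length(x)
  if (g <= 0) return(x)
  pre <- length(x) %/% 2
  c(x[seq_len(pre)], rep(NA_integer_, g),
    if (pre < length(x)) x[(pre + 1):length(x)] else integer(0))
}

aa_codes <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(ch, AA_ALPHABET)
  if (anyNA(idx))
    stop("CDR3 contains non-amino-acid character(s): ",
         paste(unique(ch[is.na(idx)]), collapse = ", "))
  idx
}

#' CDR3 amino-acid distance between two sequences
#'
#' After trimming `params$trim` residues from each terminus, the shorter
#' sequence receives one contiguous centered gap block to equalise lengths.
#' Identical aligned residues cost 0, mismatches cost
#' `min(cap, cap - similarity)`, gap positions cost `gap_cost`; the summed
#' cost is multiplied by `weight`. Symmetric and non-negative; the triangle
#' inequality is not guaranteed.
#'
#' @param a,b CDR3 amino-acid strings (non-empty)
#' @param params `distance_params`
#' @return non-negative numeric distance
#' @export
cdr3_distance <- function(a, b, params = distance_params()) {
  stopifnot(nzchar(a), nzchar(b))
  ca <- aa_codes(a); cb <- aa_codes(b)
  tr <- params$trim
  trim_seq <- function(x) {
    if (length(x) <= 2 * tr) return(integer(0))
    x[(tr + 1):(length(x) - tr)]
  }
  ca <- trim_seq(ca); cb <- trim_seq(cb)
  L <- max(length(ca), length(cb))
  if (L == 0) return(0)
  ca <- center_gap(ca, L); cb <- center_gap(cb, L)
  gap <- is.na(ca) | is.na(cb)
  cost <- numeric(L)
  cost[gap] <- params$gap_cost
  ng <- which(!gap)
  if (length(ng) > 0) {
    sim <- params$sub_mat[cbind(ca[ng], cb[ng])]
    cost[ng] <- ifelse(ca[ng] == cb[ng], 0, pmin(params$cap,
                                                 params$cap - sim))
  }
  params$weight * sum(cost)
}

#' Paired-chain distance between two clones
#'
#' Sum of [cdr3_distance()] over the alpha and beta CDR3s.
#'
#' @param clone_a,clone_b lists or one-row data.frames carrying `cdr3a_aa`
#'   and `cdr3b_aa`
#' @param params `distance_params`
#' @return numeric distance
#' @export
paired_clone_distance <- function(clone_a, clone_b,
                                  params = distance_params()) {
  for (cl in list(clone_a, clone_b))
    if (is.null(cl$cdr3a_aa) || is.na(cl$cdr3a_aa) ||
        is.null(cl$cdr3b_aa) || is.na(cl$cdr3b_aa))
      stop("clone lacks an alpha or beta CDR3 amino-acid sequence")
  cdr3_distance(clone_a$cdr3a_aa, clone_b$cdr3a_aa, params) +
    cdr3_distance(clone_a$cdr3b_aa, clone_b$cdr3b_aa, params)
}

# full pairwise paired-chain distance matrix over the rows of a clone table
paired_distance_matrix <- function(clones, params = distance_params()) {
  n <- nrow(clones)
  D <- matrix(0, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- paired_clone_distance(clones[i, ], clones[j, ],
                                                    params)
      }
    }
  }
  dimnames(D) <- list(clones$clone_id, clones$clone_id)
  D
}

# position-frequency matrix over 20 aa + gap for a set of gapped sequences
# (character vectors with NA = gap), plus consensus string
pfm_consensus <- function(aligned, consensus_threshold = 0.6) {
  L <- length(aligned[[1]])
  symbols <- c(AA_ALPHABET, "-")
  pfm <- matrix(0, nrow = 21, ncol = L, dimnames = list(symbols, NULL))
  for (s in aligned) {
    sym <- ifelse(is.na(s), 21L, s)
    for (p in seq_len(L)) pfm[sym[p], p] <- pfm[sym[p], p] + 1
  }
  pfm <- pfm / length(aligned)
  cons <- vapply(seq_len(L), function(p) {
    m <- which.max(pfm[, p])
    if (pfm[m, p] >= consensus_threshold && m != 21L) symbols[m] else "-"
  }, character(1))
  list(pfm = pfm, consensus = paste(cons, collapse = ""))
}

# majority origin label per aligned position; "mixed" when no strict
# majority among non-gap members
origin_profile <- function(origin_strings, aligned) {
  L <- length(aligned[[1]])
  labs <- vapply(seq_len(L), function(p) {
    v <- character(0)
    for (k in seq_along(aligned)) {
      if (!is.na(aligned[[k]][p])) {
        s <- origin_strings[[k]]
        pos <- sum(!is.na(aligned[[k]][seq_len(p)]))
        v <- c(v, substr(s, pos, pos))
      }
    }
    if (length(v) == 0) return("-")
    tab <- sort(table(v), decreasing = TRUE)
    if (tab[1] / length(v) > 0.5) names(tab)[1] else "mixed"
  }, character(1))
  labs
}

#' Cluster clones into CDR3 motif groups
#'
#' Agglomerative clustering on the paired-chain CDR3 distance, cut at
#' `cut_height`. Restricted to clones with at least `min_clone_size` member
#' cells. Each resulting group carries, per chain, a gapped alignment of
#' its members (single centered gap block padding to the longest member), a
#' position-frequency matrix over the 20 amino acids plus gap, a consensus
#' pattern (letter where the modal residue frequency reaches
#' `consensus_threshold`, `-` otherwise) and, when per-clone segment-origin
#' strings are supplied, a per-position origin label in
#' `{V, N, D, J, mixed}`.
#'
#' A negative `cut_height` places every clone in its own group;
#' `cut_height = 0` merges only clones at distance zero (identical paired
#' CDR3 amino-acid sequences).
#'
#' @param clone_set `clone_set`
#' @param params `distance_params`
#' @param linkage `"average"`, `"complete"` or `"single"`
#' @param cut_height tree cut height
#' @param min_clone_size minimum clone size analysed (default 2)
#' @param origins optional data.frame (`clone_id`, `origin_a`, `origin_b`)
#'   from [attribute_clone_segments()]
#' @param consensus_threshold modal-frequency threshold for consensus
#'   letters (default 0.6)
#' @return list of motif groups, each a list with `clone_ids`, `size`
#'   (number of clones), and per chain `alignment`, `pfm`, `consensus`,
#'   `origin`
#' @export
cluster_motif_groups <- function(clone_set, params = distance_params(),
                                 linkage = c("average", "complete", "single"),
                                 cut_height = 50, min_clone_size = 2,
                                 origins = NULL,
                                 consensus_threshold = 0.6) {
  linkage <- match.arg(linkage)
  cl <- clone_set$clones[clone_set$clones$size >= min_clone_size, ,
                         drop = FALSE]
  ok <- !is.na(cl$cdr3a_aa) & !is.na(cl$cdr3b_aa)
  cl <- cl[ok, , drop = FALSE]
  if (nrow(cl) < 2) stop("need at least 2 clones to cluster")
  if (cut_height < 0) {
    groups <- seq_len(nrow(cl))
  } else {
    D <- paired_distance_matrix(cl, params)
    hc <- stats::hclust(stats::as.dist(D), method = linkage)
    groups <- stats::cutree(hc, h = cut_height)
  }
  out <- lapply(split(seq_len(nrow(cl)), groups), function(idx) {
    g <- list(clone_ids = cl$clone_id[idx], size = length(idx))
    for (chain in c("a", "b")) {
      seqs <- cl[[paste0("cdr3", chain, "_aa")]][idx]
      codes <- lapply(seqs, aa_codes)
      L <- max(vapply(codes, length, integer(1)))
      aligned <- lapply(codes, center_gap, target = L)
      pc <- pfm_consensus(aligned, consensus_threshold)
      g[[paste0("alignment_", chain)]] <- vapply(aligned, function(x)
        paste(ifelse(is.na(x), "-", AA_ALPHABET[x]), collapse = ""),
        character(1))
      g[[paste0("pfm_", chain)]] <- pc$pfm
      g[[paste0("consensus_", chain)]] <- pc$consensus
      if (!is.null(origins)) {
        os <- origins[[paste0("origin_", chain)]][
          match(cl$clone_id[idx], origins$clone_id)]
        if (!anyNA(os))
          g[[paste0("origin_", chain)]] <- origin_profile(as.list(os),
                                                          aligned)
      }
    }
    g
  })
  names(out) <- paste0("motif_group_", seq_along(out))
  out
}

longest_common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  ca <- strsplit(substr(a, 1, n), "")[[1]]
  cb <- strsplit(substr(b, 1, n), "")[[1]]
  neq <- which(ca != cb)
  if (length(neq) == 0) n else neq[1] - 1L
}

reverse_chars <- function(s)
  paste(rev(strsplit(s, "")[[1]]), collapse = "")

#' Attribute each CDR3 position to its germline or junctional origin
#'
#' The V label covers the longest prefix of the CDR3 nucleotide sequence
#' matching the germline V gene from its annotated CDR3 boundary onward;
#' the J label covers the longest suffix matching the germline J gene up to
#' its boundary. If the two candidate matches would overlap, the total
#' match is already maximal for any split, and V takes the contested
#' positions. Within the remaining middle, the longest match of at least
#' 3 nt to any D gene is labeled D (ties broken leftmost, then by D list
#' order); everything else is labeled N (non-templated). Per-amino-acid
#' labels are the majority origin of the 3 codon nucleotides, ties going
#' to N.
#'
#' @param cdr3_nt CDR3 nucleotide string
#' @param v_seq,j_seq germline V and J nucleotide sequences
#' @param v_boundary 1-based start of the V gene's conserved Cys codon
#' @param j_boundary 1-based end of the J gene's conserved Phe/Trp codon
#' @param d_seqs character vector of D gene sequences (empty for TRA)
#' @return list with `nt_labels` (character vector over
#'   `{"V","N","D","J"}`), `aa_labels`, `v_len`, `j_len`, `d_start`,
#'   `d_len`
#' @export
attribute_segments <- function(cdr3_nt, v_seq, v_boundary, j_seq, j_boundary,
                               d_seqs = character(0)) {
  L <- nchar(cdr3_nt)
  germ_v <- substr(v_seq, v_boundary, nchar(v_seq))
  germ_j <- substr(j_seq, 1, j_boundary)
  lv <- longest_common_prefix(cdr3_nt, germ_v)
  lj <- longest_common_prefix(reverse_chars(cdr3_nt), reverse_chars(germ_j))
  if (lv + lj > L) {
    lv <- min(lv, L)
    lj <- L - lv
  }
  labels <- rep("N", L)
  if (lv > 0) labels[seq_len(lv)] <- "V"
  if (lj > 0) labels[(L - lj + 1):L] <- "J"
  d_start <- NA_integer_; d_len <- 0L
  mid_from <- lv + 1; mid_to <- L - lj
  if (length(d_seqs) > 0 && mid_to - mid_from + 1 >= 3) {
    middle <- substr(cdr3_nt, mid_from, mid_to)
    ml <- nchar(middle)
    found <- FALSE
    max_len <- min(ml, max(nchar(d_seqs)))
    for (len in (if (max_len >= 3) seq(max_len, 3) else integer(0))) {
      for (start in seq_len(ml - len + 1)) {
        sub <- substr(middle, start, start + len - 1)
        for (d in d_seqs) {
          if (grepl(sub, d, fixed = TRUE)) {
            d_start <- mid_from + start - 1L
            d_len <- as.integer(len)
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (found) break
    }
    if (found) labels[d_start:(d_start + d_len - 1)] <- "D"
  }
  aa_labels <- NULL
  if (L %% 3 == 0) {
    aa_labels <- vapply(seq_len(L %/% 3), function(i) {
      tri <- labels[(3 * i - 2):(3 * i)]
      tab <- sort(table(tri), decreasing = TRUE)
      if (tab[1] >= 2) names(tab)[1] else "N"
    }, character(1))
  }
  list(nt_labels = labels, aa_labels = aa_labels,
       v_len = as.integer(lv), j_len = as.integer(lj),
       d_start = d_start, d_len = d_len)
}

#' Attribute segment origins for every clone of a clone set
#'
#' @param clone_set `clone_set` whose clones carry gene calls and CDR3
#'   nucleotide sequences
#' @param germline germline reference ([read_germline_fasta()])
#' @return data.frame with `clone_id`, `origin_a`, `origin_b` (per-amino-
#'   acid origin label strings, e.g. `"VVVNNJJ"`)
#' @export
attribute_clone_segments <- function(clone_set, germline) {
  cl <- clone_set$clones
  lookup <- function(genes) {
    idx <- match(genes, germline$gene)
    bad <- unique(genes[is.na(idx) & !is.na(genes)])
    if (length(bad) > 0)
      stop("gene(s) not in germline reference: ", paste(bad, collapse = ", "))
    idx
  }
  iva <- lookup(cl$va); ija <- lookup(cl$ja)
  ivb <- lookup(cl$vb); ijb <- lookup(cl$jb)
  d_idx <- which(grepl("^TRBD", germline$gene))
  d_seqs <- germline$seq[d_idx]
  one <- function(nt, iv, ij, ds) {
    if (is.na(nt) || is.na(iv) || is.na(ij)) return(NA_character_)
    r <- attribute_segments(nt, germline$seq[iv], germline$cdr3_boundary[iv],
                            germline$seq[ij], germline$cdr3_boundary[ij], ds)
    if (is.null(r$aa_labels)) NA_character_
    else paste(r$aa_labels, collapse = "")
  }
  data.frame(
    clone_id = cl$clone_id,
    origin_a = vapply(seq_len(nrow(cl)), function(i)
      one(cl$cdr3a_nt[i], iva[i], ija[i], character(0)), character(1)),
    origin_b = vapply(seq_len(nrow(cl)), function(i)
      one(cl$cdr3b_nt[i], ivb[i], ijb[i], d_seqs), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Frequency of clones carrying a CDR3 amino-acid motif
#'
#' The pattern is matched as a contiguous substring of the chain's CDR3
#' amino-acid sequence; `-` matches any single residue (e.g. `"S-DW"`
#' matches `"CASSQDWGF"`).
#'
#' @param clone_set `clone_set` (or a clone data.frame)
#' @param pattern motif over the 20 amino-acid letters and `-`
#' @param chain `"alpha"` or `"beta"`
#' @param min_clone_size minimum clone size counted (default 1: all clones)
#' @return list with `count`, `total`, `percent` (round-half-up, one
#'   decimal)
#' @export
motif_frequency <- function(clone_set, pattern, chain = c("alpha", "beta"),
                            min_clone_size = 1) {
  chain <- match.arg(chain)
  if (!nzchar(pattern)) stop("empty motif pattern")
  chars <- strsplit(pattern, "")[[1]]
  if (!all(chars %in% c(AA_ALPHABET, "-")))
    stop("pattern may contain only amino-acid letters and '-'")
  cl <- if (inherits(clone_set, "clone_set")) clone_set$clones else clone_set
  cl <- cl[cl$size >= min_clone_size, , drop = FALSE]
  seqs <- if (chain == "alpha") cl$cdr3a_aa else cl$cdr3b_aa
  seqs <- seqs[!is.na(seqs)]
  rx <- gsub("-", ".", pattern, fixed = TRUE)
  hit <- grepl(rx, seqs)
  list(count = sum(hit), total = length(seqs),
       percent = if (length(seqs) == 0) NA_real_
                 else pct1(sum(hit), length(seqs)))
}
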