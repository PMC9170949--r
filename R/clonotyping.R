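# Chain consolidation per cell and clone calling under selectable clone
# definitions.

#' Consolidate contig records into one paired receptor per cell
#'
#' For each `(barcode, sample_id)` at most one TRA and one TRB contig is
#' selected. Among multiple productive candidates of a locus the winner is
#' the contig with the most UMIs, ties broken by read count, then by
#' lexicographically smallest CDR3 nucleotide sequence, so consolidation is
#' deterministic. Cells with more than one productive candidate are flagged
#' via `multi_alpha` / `multi_beta`.
#'
#' @param contigs contig record data.frame ([read_contig_table()])
#' @param keep_unproductive if `TRUE`, unproductive contigs compete for
#'   selection too (they always lose to productive ones)
#' @return data.frame, one row per cell, with the chosen chains
#'   (`cdr3a_nt`, `cdr3a_aa`, `va`, `ja`, `cdr3b_nt`, `cdr3b_aa`, `vb`,
#'   `db`, `jb`; `NA` when absent), `paired`, `multi_alpha`, `multi_beta`
#' @export
consolidate_cell_chains <- function(contigs, keep_unproductive = FALSE) {
  x <- contigs
  if (!keep_unproductive) x <- x[x$productive, , drop = FALSE]
  if (nrow(x) == 0) {
    return(data.frame(barcode = character(0), sample_id = character(0),
                      cdr3a_nt = character(0), cdr3a_aa = character(0),
                      va = character(0), ja = character(0),
                      cdr3b_nt = character(0), cdr3b_aa = character(0),
                      vb = character(0), db = character(0), jb = character(0),
                      paired = logical(0), multi_alpha = logical(0),
                      multi_beta = logical(0), stringsAsFactors = FALSE))
  }
  cell <- paste(x$sample_id, x$barcode, sep = "\r")
  # rank candidates within (cell, locus): productive first, then umis desc,
  # reads desc, cdr3_nt asc
  reads <- ifelse(is.na(x$reads), 0L, x$reads)
  ord <- order(cell, x$locus, !x$productive, -x$umis, -reads, x$cdr3_nt)
  x <- x[ord, , drop = FALSE]
  cell <- cell[ord]
  key <- paste(cell, x$locus, sep = "\r")
  first <- !duplicated(key)
  sel <- x[first, , drop = FALSE]
  prod_per_key <- tapply(x$productive, key, sum)
  sel$multi <- unname(prod_per_key[key[first]]) > 1

  a <- sel[sel$locus == "TRA", , drop = FALSE]
  b <- sel[sel$locus == "TRB", , drop = FALSE]
  cells <- unique(data.frame(cell = cell, barcode = x$barcode,
                             sample_id = x$sample_id,
                             stringsAsFactors = FALSE))
  ia <- match(cells$cell, paste(a$sample_id, a$barcode, sep = "\r"))
  ib <- match(cells$cell, paste(b$sample_id, b$barcode, sep = "\r"))
  out <- data.frame(
    barcode = cells$barcode, sample_id = cells$sample_id,
    cdr3a_nt = a$cdr3_nt[ia], cdr3a_aa = a$cdr3_aa[ia],
    va = a$v_gene[ia], ja = a$j_gene[ia],
    cdr3b_nt = b$cdr3_nt[ib], cdr3b_aa = b$cdr3_aa[ib],
    vb = b$v_gene[ib], db = b$d_gene[ib], jb = b$j_gene[ib],
    paired = !is.na(ia) & !is.na(ib),
    multi_alpha = !is.na(ia) & a$multi[ia],
    multi_beta = !is.na(ib) & b$multi[ib],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$sample_id, out$barcode), , drop = FALSE]
}

#' Paired-chain recovery rate
#'
#' @param profiles cell profiles ([consolidate_cell_chains()])
#' @return list with `paired`, `total`, and `percent` (round-half-up to one
#'   decimal)
#' @export
pairing_rate <- function(profiles) {
  if (nrow(profiles) == 0) stop("no cell profiles supplied")
  p <- sum(profiles$paired)
  list(paired = p, total = nrow(profiles), percent = pct1(p, nrow(profiles)))
}

CLONE_DEFINITIONS <- c("paired_nt", "alpha_nt", "beta_nt", "paired_aa")

clone_key <- function(profiles, definition) {
  switch(definition,
    paired_nt = paste(profiles$cdr3a_nt, profiles$cdr3b_nt, sep = "+"),
    paired_aa = paste(profiles$cdr3a_aa, profiles$cdr3b_aa, sep = "+"),
    alpha_nt  = profiles$cdr3a_nt,
    beta_nt   = profiles$cdr3b_nt,
    stop("unknown clone definition: ", definition)
  )
}

clone_eligible <- function(profiles, definition) {
  switch(definition,
    paired_nt = , paired_aa = profiles$paired,
    alpha_nt = !is.na(profiles$cdr3a_nt),
    beta_nt  = !is.na(profiles$cdr3b_nt),
    stop("unknown clone definition: ", definition)
  )
}

# majority vote with deterministic tie-break (lexicographic)
majority_gene <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

#' Partition cells into clones
#'
#' A clone is an equivalence class of eligible cells under exact string
#' equality of the CDR3 sequence(s) named by the definition. The default,
#' `paired_nt` (identical alpha and beta CDR3 nucleotide sequences), is the
#' strictest; `alpha_nt` / `beta_nt` reproduce single-chain (bulk-style)
#' clonotyping and `paired_aa` collapses synonymous variants.
#'
#' @param profiles cell profiles ([consolidate_cell_chains()])
#' @param definition one of `"paired_nt"`, `"alpha_nt"`, `"beta_nt"`,
#'   `"paired_aa"`
#' @return object of class `clone_set`: list with `definition`, `clones`
#'   (one row per clone: `clone_id`, `key`, CDR3s, majority gene calls,
#'   `size`), `members` (`clone_id`, `barcode`, `sample_id`) and
#'   `sample_counts` (long table of per-sample member counts)
#' @export
call_clones <- function(profiles, definition = "paired_nt") {
  definition <- match.arg(definition, CLONE_DEFINITIONS)
  elig <- profiles[clone_eligible(profiles, definition), , drop = FALSE]
  key <- clone_key(elig, definition)
  grp <- split(seq_len(nrow(elig)), key)
  keys <- names(grp)
  clone_id <- paste0(definition, "_", fnv1a_hex(keys))
  # guard against (astronomically unlikely) hash collisions
  if (anyDuplicated(clone_id))
    clone_id <- make.unique(clone_id, sep = "_")
  take <- function(col) vapply(grp, function(i) majority_gene(elig[[col]][i]),
                               character(1), USE.NAMES = FALSE)
  clones <- data.frame(
    clone_id = clone_id, definition = definition, key = keys,
    cdr3a_nt = take("cdr3a_nt"), cdr3b_nt = take("cdr3b_nt"),
    cdr3a_aa = take("cdr3a_aa"), cdr3b_aa = take("cdr3b_aa"),
    va = take("va"), ja = take("ja"),
    vb = take("vb"), db = take("db"), jb = take("jb"),
    size = vapply(grp, length, integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  members <- data.frame(
    clone_id = rep(clone_id, clones$size),
    barcode = elig$barcode[unlist(grp, use.names = FALSE)],
    sample_id = elig$sample_id[unlist(grp, use.names = FALSE)],
    stringsAsFactors = FALSE
  )
  sc <- as.data.frame(table(clone_id = members$clone_id,
                            sample_id = members$sample_id),
                      stringsAsFactors = FALSE)
  names(sc)[3] <- "n"
  sc <- sc[sc$n > 0, , drop = FALSE]
  rownames(sc) <- NULL
  structure(list(definition = definition, clones = clones,
                 members = members, sample_counts = sc),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat("clone_set (", x$definition, "): ", nrow(x$clones), " clones, ",
      nrow(x$members), " cells; ", sum(x$clones$size >= 2),
      " non-singlet clones\n", sep = "")
  invisible(x)
}

#' Restrict a clone set to a subset of member cells
#'
#' Recomputes clone sizes and per-sample counts after keeping only members
#' belonging to the given samples and/or barcodes. Clones left with no
#' members are dropped; clone identifiers are preserved (they depend only
#' on the defining key).
#'
#' @param x `clone_set`
#' @param samples optional character vector of sample ids to keep
#' @param cells optional data.frame (`barcode`, `sample_id`) of cells to keep
#' @return `clone_set`
#' @export
subset_clone_set <- function(x, samples = NULL, cells = NULL) {
  m <- x$members
  keep <- rep(TRUE, nrow(m))
  if (!is.null(samples)) keep <- keep & m$sample_id %in% samples
  if (!is.null(cells))
    keep <- keep & paste(m$sample_id, m$barcode) %in%
      paste(cells$sample_id, cells$barcode)
  m <- m[keep, , drop = FALSE]
  sz <- table(m$clone_id)
  cl <- x$clones[x$clones$clone_id %in% names(sz), , drop = FALSE]
  cl$size <- as.integer(sz[cl$clone_id])
  sc <- as.data.frame(table(clone_id = m$clone_id, sample_id = m$sample_id),
                      stringsAsFactors = FALSE)
  names(sc)[3] <- "n"
  sc <- sc[sc$n > 0, , drop = FALSE]
  rownames(cl) <- rownames(sc) <- NULL
  structure(list(definition = x$definition, clones = cl, members = m,
                 sample_counts = sc), class = "clone_set")
}
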