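# Clonal overlap, expansion and V-J gene-usage statistics over clone sets.

restrict_keys <- function(x, min_clone_size) {
  x$clones$key[x$clones$size >= min_clone_size]
}

#' Clonal overlap between two clone sets
#'
#' Both sets are first restricted to clones with at least `min_clone_size`
#' member cells (singlet clones cannot overlap informatively and are
#' excluded by default); shared clones are those whose defining keys occur
#' in both restricted sets, and the percentage is taken over the union of
#' the restricted sets.
#'
#' @param set_a,set_b `clone_set` objects under the same definition
#' @param min_clone_size minimum clone size retained (default 2)
#' @param labels length-2 character vector naming the sets
#' @return list with `labels`, `n_a`, `n_b` (restricted set sizes),
#'   `shared`, `union`, `percent` (round-half-up, one decimal), and
#'   `shared_keys`
#' @export
clone_overlap <- function(set_a, set_b, min_clone_size = 2,
                          labels = c("A", "B")) {
  if (set_a$definition != set_b$definition)
    stop("clone sets use different definitions: ",
         set_a$definition, " vs ", set_b$definition)
  ka <- restrict_keys(set_a, min_clone_size)
  kb <- restrict_keys(set_b, min_clone_size)
  shared <- intersect(ka, kb)
  uni <- union(ka, kb)
  list(labels = labels, n_a = length(ka), n_b = length(kb),
       shared = length(shared), union = length(uni),
       percent = if (length(uni) == 0) NA_real_
                 else pct1(length(shared), length(uni)),
       shared_keys = shared)
}

#' Membership-pattern (UpSet-style) overlap of k labeled clone sets
#'
#' Every clone in the union of the restricted sets is assigned to exactly
#' one of the 2^k - 1 non-empty membership patterns.
#'
#' @param sets named list of `clone_set` objects (same definition)
#' @param min_clone_size minimum clone size retained
#' @return data.frame with `pattern` (`+`-separated set labels) and `count`;
#'   counts sum to the union size
#' @export
multiset_overlap <- function(sets, min_clone_size = 2) {
  stopifnot(length(sets) >= 2)
  defs <- vapply(sets, function(s) s$definition, character(1))
  if (length(unique(defs)) != 1)
    stop("clone sets use different definitions")
  labs <- names(sets) %||% paste0("S", seq_along(sets))
  keysets <- lapply(sets, restrict_keys, min_clone_size = min_clone_size)
  uni <- unique(unlist(keysets, use.names = FALSE))
  memb <- vapply(keysets, function(k) uni %in% k, logical(length(uni)))
  if (length(uni) == 1) memb <- matrix(memb, nrow = 1)
  pattern <- apply(memb, 1, function(r) paste(labs[r], collapse = "+"))
  out <- as.data.frame(table(pattern = pattern), stringsAsFactors = FALSE)
  names(out)[2] <- "count"
  out[order(-out$count), , drop = FALSE]
}

#' Clone-size class frequencies (1 / 2 / >2 cells)
#'
#' Summarises expansion as the frequency of singlet, doublet and larger
#' clones. With a per-cell grouping (e.g. phenotypic cluster) a clone is
#' counted in every group where it has at least one member cell, but is
#' classified by its total size.
#'
#' @param clone_set `clone_set`
#' @param cell_groups optional data.frame (`barcode`, `sample_id`, `group`)
#'   assigning member cells to groups
#' @return data.frame with `group`, `size_class` (`"1"`, `"2"`, `">2"`),
#'   `count`, `frequency`; frequencies sum to 1 within each group
#' @export
clone_size_classes <- function(clone_set, cell_groups = NULL) {
  cl <- clone_set$clones
  size_class <- cut(cl$size, c(0, 1, 2, Inf), labels = c("1", "2", ">2"))
  if (is.null(cell_groups)) {
    tab <- table(size_class)
    out <- data.frame(group = "all", size_class = names(tab),
                      count = as.integer(tab), stringsAsFactors = FALSE)
  } else {
    m <- clone_set$members
    g <- cell_groups$group[match(paste(m$sample_id, m$barcode),
                                 paste(cell_groups$sample_id,
                                       cell_groups$barcode))]
    pres <- unique(data.frame(clone_id = m$clone_id, group = g,
                              stringsAsFactors = FALSE))
    pres <- pres[!is.na(pres$group), , drop = FALSE]
    pres$size_class <- size_class[match(pres$clone_id, cl$clone_id)]
    tab <- table(pres$group, pres$size_class)
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out) <- c("group", "size_class", "count")
  }
  tot <- tapply(out$count, out$group, sum)
  out$frequency <- as.numeric(ifelse(tot[out$group] > 0,
                                     out$count / as.vector(tot[out$group]),
                                     0))
  rownames(out) <- NULL
  out
}

#' Mean clone size among expanded clones
#'
#' @param clone_set `clone_set`
#' @param min_clone_size minimum size for a clone to qualify (default 2,
#'   i.e. non-singlet clones)
#' @return arithmetic mean of qualifying clone sizes
#' @export
mean_clone_size <- function(clone_set, min_clone_size = 2) {
  sz <- clone_set$clones$size[clone_set$clones$size >= min_clone_size]
  if (length(sz) == 0)
    stop("no clones with size >= ", min_clone_size)
  mean(sz)
}

#' Joint V-J gene-usage matrix with marginals
#'
#' Computes the joint V x J usage frequency matrix of one chain locus at
#' either the cell or clone level, plus V and J marginal frequencies.
#' Display conventions for chord diagrams (hide genes used by < 2% of
#' observations; label frequencies >= 10%) are attached as annotation
#' attributes only and never alter the stored frequencies.
#'
#' @param x cell profiles data.frame or a `clone_set`
#' @param locus `"TRA"` or `"TRB"`
#' @param level `"cell"` or `"clone"`
#' @return list with `joint` (V x J matrix summing to 1), `v_marginal`,
#'   `j_marginal`, `n` (observations); attribute `display` carries the
#'   chord-diagram annotation thresholds and the gene/label sets they
#'   select
#' @export
vj_usage <- function(x, locus = c("TRA", "TRB"),
                     level = c("cell", "clone")) {
  locus <- match.arg(locus)
  level <- match.arg(level)
  df <- if (inherits(x, "clone_set")) x$clones else x
  if (inherits(x, "clone_set") && level == "cell")
    df <- df[rep(seq_len(nrow(df)), df$size), , drop = FALSE]
  v <- if (locus == "TRA") df$va else df$vb
  j <- if (locus == "TRA") df$ja else df$jb
  ok <- !is.na(v) & !is.na(j)
  v <- v[ok]; j <- j[ok]
  if (length(v) == 0) stop("no ", locus, " gene calls available")
  joint <- table(v, j) / length(v)
  joint <- as.matrix(unclass(joint))
  vm <- rowSums(joint); jm <- colSums(joint)
  display <- list(
    hide_gene_threshold = 0.02, hide_label_threshold = 0.10,
    shown_v = names(vm)[vm >= 0.02], shown_j = names(jm)[jm >= 0.02],
    labeled_v = names(vm)[vm >= 0.10], labeled_j = names(jm)[jm >= 0.10]
  )
  out <- list(locus = locus, level = level, joint = joint,
              v_marginal = vm, j_marginal = jm, n = length(v))
  attr(out, "display") <- display
  out
}
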