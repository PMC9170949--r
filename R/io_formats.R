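# Readers and writers for the external formats consumed and produced by the
# pipeline: 10x-dialect contig annotation CSVs, cell metadata TSVs,
# MatrixMarket expression triplets, germline FASTA with CDR3 boundary
# annotations, and plain-text gene lists.

CONTIG_COLUMNS <- c("barcode", "chain", "v_gene", "j_gene",
                    "cdr3", "cdr3_nt", "productive", "umis")

#' Read a 10x-style contig annotation table
#'
#' Accepts the `filtered_contig_annotations.csv` dialect: one row per
#' assembled chain per cell barcode. Rows whose chain is not TRA/TRB, or
#' whose CDR3 is blank/None, are dropped and tallied in the skip report.
#' Extra columns are ignored.
#'
#' @param path CSV file with a header row
#' @param sample_id sample label attached to every record
#' @return data.frame of contig records (columns `barcode`, `sample_id`,
#'   `locus`, `v_gene`, `d_gene`, `j_gene`, `cdr3_aa`, `cdr3_nt`,
#'   `productive`, `umis`, `reads`) with a `skip_report` attribute (named
#'   integer vector of dropped-row counts).
#' @export
read_contig_table <- function(path, sample_id) {
  if (!file.exists(path)) stop("contig table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(CONTIG_COLUMNS, names(df))
  if (length(missing) > 0)
    stop("contig table ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  skip <- integer(0)

  blank <- is.na(df$cdr3_nt) | df$cdr3_nt %in% c("", "None", "NA") |
           is.na(df$cdr3)    | df$cdr3    %in% c("", "None", "NA")
  if (any(blank)) skip["blank_cdr3"] <- sum(blank)
  keep_locus <- df$chain %in% c("TRA", "TRB")
  if (any(!keep_locus & !blank)) {
    other <- table(df$chain[!keep_locus & !blank])
    skip[names(other)] <- as.integer(other)
  }
  kept <- df[keep_locus & !blank, , drop = FALSE]

  prod_raw <- tolower(trimws(as.character(kept$productive)))
  prod <- rep(NA, nrow(kept))
  prod[prod_raw %in% c("true", "t", "yes", "1")] <- TRUE
  prod[prod_raw %in% c("false", "f", "no", "0", "none")] <- FALSE
  if (anyNA(prod)) {
    bad <- which(keep_locus & !blank)[which(is.na(prod))[1]]
    stop("unparseable 'productive' value '",
         kept$productive[which(is.na(prod))[1]],
         "' in ", path, " at data line ", bad)
  }

  d <- if ("d_gene" %in% names(kept)) as.character(kept$d_gene) else
    rep(NA_character_, nrow(kept))
  d[d %in% c("", "None", "NA")] <- NA_character_
  d[kept$chain == "TRA"] <- NA_character_

  out <- data.frame(
    barcode    = as.character(kept$barcode),
    sample_id  = rep(sample_id, nrow(kept)),
    locus      = as.character(kept$chain),
    v_gene     = as.character(kept$v_gene),
    d_gene     = d,
    j_gene     = as.character(kept$j_gene),
    cdr3_aa    = as.character(kept$cdr3),
    cdr3_nt    = as.character(kept$cdr3_nt),
    productive = prod,
    umis       = as.integer(kept$umis),
    reads      = if ("reads" %in% names(kept)) as.integer(kept$reads)
                 else rep(NA_integer_, nrow(kept)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "skip_report") <- skip
  out
}

#' Write contig records back to the 10x CSV dialect
#'
#' @param contigs contig record data.frame as returned by
#'   [read_contig_table()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_contig_table <- function(contigs, path) {
  out <- data.frame(
    barcode    = contigs$barcode,
    chain      = contigs$locus,
    v_gene     = contigs$v_gene,
    d_gene     = ifelse(is.na(contigs$d_gene), "None", contigs$d_gene),
    j_gene     = contigs$j_gene,
    cdr3       = contigs$cdr3_aa,
    cdr3_nt    = contigs$cdr3_nt,
    productive = ifelse(contigs$productive, "True", "False"),
    umis       = contigs$umis,
    reads      = contigs$reads,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sparse expression matrix from a MatrixMarket triplet directory
#'
#' Expects `matrix.mtx` plus one-column `features.tsv` and `barcodes.tsv`
#' lists. The on-disk orientation is genes x cells (10x convention); the
#' returned matrix is normalised to cells x genes.
#'
#' @param dir directory holding the triplet
#' @return `dgCMatrix`, cells as rows (barcodes), genes as columns
#' @export
read_expression_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  for (p in paths) if (!file.exists(p)) stop("expected file not found: ", p)
  m <- Matrix::readMM(paths[1])
  genes <- readLines(paths[2])
  cells <- readLines(paths[3])
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("matrix dimensions ", nrow(m), " x ", ncol(m),
         " do not match feature/barcode list lengths ",
         length(genes), " x ", length(cells))
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in features.tsv")
  if (anyDuplicated(cells)) stop("duplicate barcodes in barcodes.tsv")
  m <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(m) <- list(cells, genes)
  m
}

#' Write a cells x genes sparse matrix as a MatrixMarket triplet directory
#'
#' @param expr cells x genes sparse matrix with dimnames
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_expression_mtx <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(expr), file.path(dir, "matrix.mtx"))
  writeLines(colnames(expr), file.path(dir, "features.tsv"))
  writeLines(rownames(expr), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read / write the cell metadata table
#'
#' Tab-separated with columns `barcode`, `sample_id`, `tissue`, `tetramer`,
#' `cluster`, `experiment`. `(barcode, sample_id)` must be unique.
#'
#' @param path TSV path
#' @return data.frame of per-cell metadata
#' @export
read_cell_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "sample_id", "tissue", "tetramer", "experiment")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("cell metadata is missing column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df[c("barcode", "sample_id")]))
    stop("duplicate (barcode, sample_id) pairs in cell metadata")
  if (!"cluster" %in% names(df)) df$cluster <- NA_character_
  df
}

#' @rdname read_cell_metadata
#' @param metadata data.frame of per-cell metadata
#' @export
write_cell_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write germline V/D/J reference sequences
#'
#' FASTA with headers of the form `>GENE|cdr3_boundary=<int>`. For V genes
#' the boundary is the 1-based start of the conserved Cys codon (the CDR3
#' contribution is the suffix from there); for J genes it is the 1-based end
#' of the conserved Phe/Trp codon (the CDR3 contribution is the prefix up to
#' there); D genes carry boundary 0 (the whole sequence may appear in the
#' junction).
#'
#' @param path FASTA path
#' @return data.frame with columns `gene`, `seq`, `cdr3_boundary`
#' @export
read_germline_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  m <- regmatches(hdr, regexec("^([^|]+)\\|cdr3_boundary=(\\d+)$", hdr))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad))
    stop("malformed germline FASTA header(s): ",
         paste(hdr[bad], collapse = "; "))
  data.frame(
    gene = vapply(m, `[`, character(1), 2),
    seq = as.character(ss),
    cdr3_boundary = as.integer(vapply(m, `[`, character(1), 3)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @rdname read_germline_fasta
#' @param germline data.frame with columns `gene`, `seq`, `cdr3_boundary`
#' @export
write_germline_fasta <- function(germline, path) {
  lines <- as.vector(rbind(
    sprintf(">%s|cdr3_boundary=%d", germline$gene, germline$cdr3_boundary),
    germline$seq
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-list file
#'
#' Plain text, one gene identifier per line; `#` starts a comment; blank
#' lines ignored.
#'
#' @param path text file path
#' @return character vector of gene identifiers
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Quality-filter cells of an expression matrix
#'
#' Retains cells whose mitochondrial count fraction is strictly below
#' `max_mito_frac` and whose detected-gene count lies in
#' `[min_genes, max_genes]` (inclusive), the conventional filters for
#' removing apoptotic cells, empty droplets and doublets.
#'
#' @param expr cells x genes matrix (raw counts)
#' @param mito_gene_prefix prefix identifying mitochondrial genes
#'   (default `"mt-"`, murine nomenclature)
#' @param max_mito_frac exclusive upper bound on mitochondrial fraction
#' @param min_genes,max_genes inclusive bounds on detected genes per cell
#' @return list with `expr` (filtered matrix) and `report` (named counts of
#'   cells removed per criterion; a cell failing several criteria counts in
#'   each)
#' @export
filter_cells <- function(expr, mito_gene_prefix = "mt-",
                         max_mito_frac = 0.05,
                         min_genes = 200, max_genes = 3500) {
  stopifnot(max_mito_frac > 0, min_genes > 0, min_genes <= max_genes)
  mito <- startsWith(colnames(expr), mito_gene_prefix)
  totals <- Matrix::rowSums(expr)
  if (!any(mito)) {
    warning("no genes match mitochondrial prefix '", mito_gene_prefix,
            "'; mitochondrial fraction treated as 0")
    mito_frac <- rep(0, nrow(expr))
  } else {
    mito_frac <- Matrix::rowSums(expr[, mito, drop = FALSE]) / pmax(totals, 1)
  }
  n_detected <- Matrix::rowSums(expr > 0)
  fail_mito <- !(mito_frac < max_mito_frac)
  fail_low  <- n_detected < min_genes
  fail_high <- n_detected > max_genes
  keep <- !(fail_mito | fail_low | fail_high)
  list(
    expr = expr[keep, , drop = FALSE],
    report = c(mito = sum(fail_mito), low_genes = sum(fail_low),
               high_genes = sum(fail_high), removed = sum(!keep),
               retained = sum(keep))
  )
}
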