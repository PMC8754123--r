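#' Read an ordered gene annotation table
#'
#' Reads a tab-separated per-genome gene table (one row per CDS) and assigns
#' contig-local ordinal positions. Ordinals are recomputed from the sorted
#' start coordinates within each contig, 0-based, so the input row order is
#' irrelevant. Clusters are later measured in ordinal (ORF-count) units, and
#' never across contigs.
#'
#' @param path Path to a TSV with header columns
#'   `genome_id contig_id gene_uid start end strand`.
#' @return A data.frame of gene records with an added integer `ordinal`
#'   column, sorted by (genome_id, contig_id, start).
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("genome_id", "contig_id", "gene_uid", "start", "end", "strand")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("gene table is missing columns: ", paste(missing, collapse = ", "))
  }
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) | v != floor(v)
    if (any(bad)) {
      stop("non-integer '", col, "' coordinate in rows: ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    df[[col]] <- as.integer(v)
  }
  if (any(df$start > df$end)) stop("gene with start > end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  dup <- unlist(lapply(split(df$gene_uid, df$genome_id),
                       function(u) u[duplicated(u)]), use.names = FALSE)
  if (length(dup) > 0L) {
    stop("duplicate gene_uid within a genome: ", dup[[1L]])
  }
  assign_ordinals(df)
}

#' Recompute contig-local ordinals from start coordinates
#'
#' @param genes Gene table with `genome_id`, `contig_id`, `start` columns.
#' @return The table sorted by (genome, contig, start) with a 0-based
#'   `ordinal` column, a bijection onto 0..n-1 per contig.
#' @export
assign_ordinals <- function(genes) {
  genes <- genes[order(genes$genome_id, genes$contig_id, genes$start), ,
                 drop = FALSE]
  key <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  genes$ordinal <- stats::ave(seq_along(key), key, FUN = seq_along) - 1L
  rownames(genes) <- NULL
  genes
}

#' Read a domain-hit evidence table
#'
#' @param path TSV with columns
#'   `gene_uid source accession evalue identity_pct coverage_pct`
#'   (empty identity/coverage fields read as NA).
#' @return data.frame of domain hits.
#' @export
read_evidence_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("gene_uid", "source", "accession", "evalue")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("evidence table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(df$identity_pct)) df$identity_pct <- NA_real_
  if (is.null(df$coverage_pct)) df$coverage_pct <- NA_real_
  df$evalue <- as.numeric(df$evalue)
  df$identity_pct <- as.numeric(df$identity_pct)
  df$coverage_pct <- as.numeric(df$coverage_pct)
  if (any(df$evalue < 0, na.rm = TRUE)) stop("negative e-value")
  for (col in c("identity_pct", "coverage_pct")) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) stop(col, " outside [0, 100]")
  }
  df
}

#' Read genome metadata
#'
#' @param path TSV with `genome_id species genus family order class
#'   is_type_strain habitat`; habitat one of animal / non_animal / unknown.
#' @return data.frame with logical `is_type_strain`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$is_type_strain <- as.logical(df$is_type_strain)
  if (!all(df$habitat %in% c("animal", "non_animal", "unknown"))) {
    stop("habitat must be animal, non_animal or unknown")
  }
  df
}

#' Read genome QC metrics
#'
#' @param path TSV with `genome_id completeness_pct contamination_pct
#'   marker_fraction`.
#' @return data.frame of QC metrics.
#' @export
read_qc_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  num <- c("completeness_pct", "contamination_pct", "marker_fraction")
  for (col in intersect(num, names(df))) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Read a square ANI matrix
#'
#' @param path TSV: first column genome ids, remaining columns the symmetric
#'   ANI percentages with matching column names.
#' @param tol Symmetry tolerance.
#' @return Numeric matrix with genome ids as dimnames.
#' @export
read_ani_matrix <- function(path, tol = 1e-6) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  validate_ani_matrix(m, tol = tol)
  m
}

validate_ani_matrix <- function(m, tol = 1e-6) {
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("ANI matrix must be square with matching row/column ids")
  }
  if (max(abs(m - t(m))) > tol) stop("ANI matrix asymmetric beyond tolerance")
  if (any(abs(diag(m) - 100) > tol)) stop("ANI matrix diagonal must be 100")
  invisible(m)
}

#' Read a species tree in Newick format
#'
#' Thin wrapper over [ape::read.tree()] that enforces unique leaf labels.
#'
#' @param path Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unparseable Newick in '", path,
                                          "': ", conditionMessage(e)))
  if (is.null(tr)) stop("unparseable Newick in '", path, "'")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: ",
         tr$tip.label[duplicated(tr$tip.label)][[1L]])
  }
  tr
}

#' Write / read a per-genome call table (TSV round trip)
#'
#' @param calls A SacCall data.frame as produced by [call_genomes()].
#' @param path Output TSV path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(df$sac_positive)) df$sac_positive <- as.logical(df$sac_positive)
  df
}

#' Write a run manifest alongside outputs
#'
#' Records input paths, parameter values and the seed so that any output
#' directory is reproducible from its manifest alone.
#'
#' @param dir Output directory.
#' @param params Named list of parameters (seed included).
#' @param inputs Named character vector of input paths, if any.
#' @export
write_manifest <- function(dir, params, inputs = character()) {
  lines <- c(
    paste0("tool\tnanclust ", as.character(utils::packageVersion("nanclust"))),
    if (length(inputs)) paste0("input:", names(inputs), "\t", inputs),
    paste0("param:", names(params), "\t",
           vapply(params, function(p) paste(format(p), collapse = ","), ""))
  )
  writeLines(lines, file.path(dir, "MANIFEST.tsv"))
  invisible(file.path(dir, "MANIFEST.tsv"))
}
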