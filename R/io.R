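# Disk convention: expression is features x samples, first column the
# feature id. Every file written by the package starts with a single
# "# schema:" comment line; readers skip "#" comments.

detect_sep <- function(path) {
  for (line in readLines(path, n = 10L)) {
    if (!startsWith(line, "#")) {
      return(if (grepl("\t", line)) "\t" else ",")
    }
  }
  "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects features x samples with feature ids in the first column;
#' the delimiter (tab or comma) is auto-detected and `#` comment lines
#' are skipped.
#'
#' @param path File path.
#' @param layer Optional layer tag (`"mRNA"`/`"miRNA"`) attached to the
#'   result.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_expression <- function(path, layer = NULL) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    stop("non-numeric expression values in ", path, call. = FALSE)
  }
  rownames(m) <- ids
  if (!is.null(layer)) attr(m, "layer") <- layer
  m
}

write_table_with_schema <- function(df, path, schema, sep = "\t") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# schema: ", schema), con)
  utils::write.table(df, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param x Numeric features x samples matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(x, path) {
  assert_expression_matrix(x)
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_with_schema(
    df, path, "feature_id followed by one numeric column per sample")
  invisible(path)
}

#' Read a sample trait table from CSV
#'
#' Sample ids in the first column become rownames; remaining columns are
#' traits (numeric or binary).
#'
#' @param path File path.
#' @return Data frame of traits with sample rownames.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  rownames(df) <- as.character(df[[1L]])
  df[, -1L, drop = FALSE]
}

#' Write a sample trait table as CSV
#'
#' @param traits Data frame with sample rownames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  df <- data.frame(sample_id = rownames(traits), traits,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table_with_schema(
    df, path, "sample_id followed by one numeric/binary column per trait",
    sep = ",")
  invisible(path)
}

#' Read a scored interaction table from TSV
#'
#' @param path File path to a table with columns `mirna`, `gene`, and
#'   one or more `score_*` columns.
#' @return Data frame.
#' @export
read_interactions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(df))) {
    stop("interaction table in ", path,
         " needs `mirna` and `gene` columns", call. = FALSE)
  }
  df
}

#' Write a scored interaction table as TSV
#'
#' @param interactions Data frame with `mirna`, `gene`, `score_*`
#'   columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  write_table_with_schema(
    interactions, path,
    "mirna, gene, one score column per source database")
  invisible(path)
}

#' Write a module partition as two-column TSV
#'
#' @param partition Named character vector of module labels.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(feature_id = names(partition),
                   module_label = unname(partition),
                   stringsAsFactors = FALSE)
  write_table_with_schema(df, path, "feature_id, module_label")
  invisible(path)
}

#' Write module eigengenes as CSV
#'
#' @param eigengenes A `module_eigengenes` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_eigengenes <- function(eigengenes, path) {
  stopifnot(inherits(eigengenes, "module_eigengenes"))
  me <- eigengenes$eigengenes
  df <- data.frame(sample_id = rownames(me), me, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_with_schema(
    df, path, "sample_id followed by one eigengene column per module",
    sep = ",")
  invisible(path)
}
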