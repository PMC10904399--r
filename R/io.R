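#' Read / write GMT gene-set files
#'
#' Tab-separated, one gene set per line: id, free-text description, then the
#' member genes. Gene ids are case-sensitive; duplicate members within a set
#' are kept as written on output and de-duplicated on ingestion into
#' hyperedges.
#'
#' @param path file path.
#' @return named list of character vectors with attribute
#'   `"descriptions"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional named character vector (defaults to the ids).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a two-column term hierarchy table
#'
#' Tab-delimited `child_id<TAB>parent_id`, one relation per line, with a
#' header row.
#'
#' @param path file path.
#' @return data.frame with columns `child`, `parent`.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(df)))
    stop("hierarchy table must have columns 'child' and 'parent'")
  df[, c("child", "parent")]
}

#' @rdname read_hierarchy
#' @param hierarchy data.frame with columns `child`, `parent`.
#' @export
write_hierarchy <- function(hierarchy, path) {
  utils::write.table(hierarchy[, c("child", "parent")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build an ontology-mode hyperedge set from GMT + hierarchy inputs
#'
#' @param sets named list of member vectors (e.g. from [read_gmt()]).
#' @param hierarchy optional data.frame (`child`, `parent`); relations whose
#'   terms are absent from `sets` are dropped.
#' @return an unweighted `hyperedge_set`.
#' @export
edges_from_sets <- function(sets, hierarchy = NULL) {
  children <- NULL
  if (!is.null(hierarchy) && nrow(hierarchy)) {
    h <- hierarchy[hierarchy$child %in% names(sets) & hierarchy$parent %in% names(sets), ]
    if (nrow(h)) children <- split(h$child, h$parent)
  }
  hyperedge_set(sets, children = children)
}

#' Read / write expression matrices (GCT-like or plain tab-delimited)
#'
#' Accepts the GCT dialect (`#1.2` version line, dimensions line, `Name` and
#' `Description` columns) or a plain matrix with gene ids in the first
#' column.
#'
#' @param path file path.
#' @return numeric matrix, rows named by gene.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.")) {
    df <- utils::read.delim(path, skip = 2L, stringsAsFactors = FALSE, check.names = FALSE)
    genes <- df[[1L]]
    X <- as.matrix(df[, -(1:2), drop = FALSE])
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    genes <- df[[1L]]
    X <- as.matrix(df[, -1L, drop = FALSE])
  }
  mode(X) <- "numeric"
  rownames(X) <- genes
  X
}

#' @rdname read_expression_matrix
#' @param mat numeric matrix with gene rownames.
#' @param gct write the GCT dialect (default plain TSV).
#' @export
write_expression_matrix <- function(mat, path, gct = FALSE) {
  if (gct) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
    df <- data.frame(Name = rownames(mat), Description = rownames(mat), mat,
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write long-format signature tables
#'
#' Tab-delimited columns: `perturbagen_id`, `type`, `cell_line`, `tas`,
#' `gene`; one row per member gene.
#'
#' @param path file path.
#' @return list of `gene_signature` objects.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("perturbagen_id", "type", "cell_line", "tas", "gene")
  if (!all(need %in% names(df)))
    stop("signature table needs columns: ", paste(need, collapse = ", "))
  key <- paste(df$perturbagen_id, df$type, df$cell_line, sep = "\r")
  lapply(split(df, key), function(g)
    gene_signature(g$gene, g$perturbagen_id[1L], g$type[1L],
                   g$cell_line[1L], g$tas[1L]))
}

#' @rdname read_signatures
#' @param signatures list of `gene_signature` objects.
#' @export
write_signatures <- function(signatures, path) {
  rows <- do.call(rbind, lapply(signatures, function(s)
    data.frame(perturbagen_id = s$perturbagen_id, type = s$perturbagen_type,
               cell_line = s$cell_line, tas = s$tas, gene = s$genes,
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a stationary profile as a tab-delimited table
#'
#' Columns: source, gene, probability.
#'
#' @param profile a `stationary_profile`.
#' @param path file path.
#' @export
write_stationary_profile <- function(profile, path) {
  stopifnot(inherits(profile, "stationary_profile"))
  df <- data.frame(source = profile$source,
                   gene = names(profile$distribution),
                   probability = as.numeric(profile$distribution),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a prediction table
#'
#' Tab-delimited columns: compound_id, target_gene, cell_line,
#' perturbagen_type, probability.
#'
#' @param predictions data.frame with those columns.
#' @param path file path.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("compound_id", "target_gene", "cell_line", "perturbagen_type", "probability")
  if (!all(need %in% names(predictions)))
    stop("prediction table needs columns: ", paste(need, collapse = ", "))
  utils::write.table(predictions[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers where possible, otherwise strings.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
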