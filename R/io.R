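#' Read a gene-by-sample count matrix
#'
#' TSV layout: a header row of sample identifiers, first column `gene_id`,
#' integer counts.  MTX layout: a MatrixMarket triplet file accompanied by
#' sidecar name files `<path>.rownames` and `<path>.colnames` (one name per
#' line); entries absent from the triplet are zeros.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"mtx"`.
#' @return Integer matrix with gene rownames (uppercased) and sample
#'   colnames, validated by [validate_counts()].
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("count TSV needs gene_id plus >= 2 samples",
                            call. = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (any(is.na(m))) {
      bad <- which(rowSums(is.na(m)) > 0)[1]
      stop(sprintf("non-numeric or ragged entry at data line %d of %s",
                   bad, path), call. = FALSE)
    }
    storage.mode(m) <- "numeric"
    rownames(m) <- genes
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (nrow(m) != length(rn) || ncol(m) != length(cn)) {
      stop("sidecar name files do not match matrix dimensions", call. = FALSE)
    }
    dimnames(m) <- list(rn, cn)
  }
  validate_counts(m)
  rownames(m) <- toupper(rownames(m))
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix
#'
#' @param counts validated count matrix.
#' @param path destination; for MTX, sidecar `.rownames`/`.colnames` files
#'   are written next to it.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  validate_counts(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Read / write a sample design table
#'
#' Columns: sample_id, cell_line, condition (P/T/R), replicate.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("design table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_design
#' @param design data.frame to write.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then tab-separated member symbols.
#' An empty file yields an empty collection.
#'
#' @param path GMT file.
#' @return Named list of character vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("malformed GMT record at line ", bad[1], call. = FALSE)
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(parts, function(p) toupper(p[-(1:2)]))
  desc <- vapply(parts, `[[`, character(1), 2L)
  structure(stats::setNames(sets, nm),
            descriptions = stats::setNames(desc, nm))
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path destination file.
#' @param descriptions optional per-set description strings.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  nm <- names(sets)
  if (length(sets) && (is.null(nm) || anyDuplicated(nm))) {
    stop("sets must have unique names", call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(nm[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an expression (log-CPM) matrix as TSV
#'
#' @param path TSV file with a `gene_id` first column.
#' @return Numeric matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- toupper(as.character(df[[1]]))
  m
}

#' @rdname read_expression
#' @param expr numeric matrix with gene rownames.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
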