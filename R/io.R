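#' Read a dense bipartite matrix file
#'
#' Reads Web-of-Life-style dense matrices from CSV/TSV.  The file may
#' carry an optional header row with column labels and an optional first
#' column with row labels; by default both are auto-detected (a leading
#' row/column whose cells do not all parse as numbers is treated as
#' labels).  Any positive weight is binarized to 1.
#'
#' @param path file to read.
#' @param sep field separator; `NULL` (default) picks `"\t"` for `.tsv`
#'   files or when the first line contains tabs, `","` otherwise.
#' @param header `TRUE`/`FALSE`, or `NA` to auto-detect a label row.
#' @param row_labels `TRUE`/`FALSE`, or `NA` to auto-detect a label column.
#' @return a [bipartite_network()].
#' @export
read_matrix <- function(path, sep = NULL, header = NA, row_labels = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE) || grepl("\t", lines[[1]])) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  cells <- lapply(cells, trimws)
  is_num <- function(v) !anyNA(suppressWarnings(as.numeric(v))) & all(nzchar(v))
  # auto-detect label column first (a header row's leading cell is often empty)
  if (is.na(row_labels)) {
    first_col <- vapply(cells[-1], `[`, "", 1L)
    if (length(first_col) == 0L) first_col <- cells[[1]][1L]
    row_labels <- !is_num(first_col)
  }
  if (is.na(header)) {
    hdr <- cells[[1]]
    if (isTRUE(row_labels)) hdr <- hdr[-1L]
    header <- length(hdr) == 0L || !is_num(hdr)
  }
  col_lab <- NULL
  if (isTRUE(header)) {
    col_lab <- cells[[1]]
    cells <- cells[-1L]
    if (length(cells) == 0L) stop("matrix file has a header but no data rows: ", path)
  }
  row_lab <- NULL
  if (isTRUE(row_labels)) {
    row_lab <- vapply(cells, `[`, "", 1L)
    cells <- lapply(cells, `[`, -1L)
    if (!is.null(col_lab) && length(col_lab) == length(cells[[1]]) + 1L)
      col_lab <- col_lab[-1L]
  }
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("malformed matrix file %s: line %d has %d fields, expected %d",
                 path, which(ncols != ncols[1])[1] + isTRUE(header), ncols[ncols != ncols[1]][1], ncols[1]))
  vals <- suppressWarnings(vapply(cells, as.numeric, numeric(ncols[1])))
  if (ncols[1] == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(colSums(is.na(vals)) > 0L)
  if (length(bad))
    stop(sprintf("malformed matrix file %s: non-numeric cell on data line %d",
                 path, bad[1] + isTRUE(header)))
  if (any(vals < 0)) stop("negative entries are not a valid incidence weight: ", path)
  B <- t(vals)                      # vapply gave one column per input row
  B <- (B > 0) * 1L
  bipartite_network(B, row_labels = row_lab, col_labels = col_lab)
}

#' Write a network as a dense matrix file
#'
#' Inverse of [read_matrix()]: `read_matrix(write_matrix(net, f))`
#' reproduces `net` bit-exactly.  Auto-generated default labels are
#' omitted from the file (the reader regenerates them); any other labels
#' are written as a header row and a label column.
#'
#' @param net a [bipartite_network()].
#' @param path destination file.
#' @param sep field separator (default `","`).
#' @param labels `TRUE`, `FALSE` or `"auto"` (default: write labels only
#'   when they differ from the generated defaults).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(net, path, sep = ",", labels = "auto") {
  net <- as_binet(net)
  B <- net$matrix
  deflt <- identical(net$row_labels, paste0("r", seq_len(nrow(B)))) &&
    identical(net$col_labels, paste0("c", seq_len(ncol(B))))
  if (identical(labels, "auto")) labels <- !deflt
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeline <- function(x) writeLines(paste(x, collapse = sep), con, useBytes = TRUE)
  if (isTRUE(labels)) {
    writeline(c("", enc2utf8(net$col_labels)))
    for (i in seq_len(nrow(B))) writeline(c(enc2utf8(net$row_labels[i]), B[i, ]))
  } else {
    for (i in seq_len(nrow(B))) writeline(B[i, ])
  }
  invisible(path)
}

#' Read a two-column edge list
#'
#' Each record is `row-guild-id<TAB>column-guild-id`.  Duplicate edges
#' collapse to a single link; label order follows first appearance.  An
#' identifier appearing in both columns makes guild membership ambiguous
#' and is an error.
#'
#' @param path file to read.
#' @param sep field separator (default `"\t"`).
#' @return a [bipartite_network()].
#' @export
read_edgelist <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge list: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop(sprintf("malformed edge list %s: line %d has fewer than 2 fields",
                 path, which(nf < 2L)[1]))
  from <- trimws(vapply(parts, `[`, "", 1L))
  to <- trimws(vapply(parts, `[`, "", 2L))
  amb <- intersect(unique(from), unique(to))
  if (length(amb))
    stop("guild inference ambiguity: identifier(s) appear in both columns: ",
         paste(utils::head(amb, 3), collapse = ", "))
  rl <- unique(from); cl <- unique(to)
  B <- matrix(0L, length(rl), length(cl))
  B[cbind(match(from, rl), match(to, cl))] <- 1L
  bipartite_network(B, row_labels = rl, col_labels = cl)
}
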