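#' Construct a binary bipartite network
#'
#' A `bipartite_network` wraps an `n x m` binary biadjacency matrix `B`
#' with `b_ij = 1` iff row-node i (one guild, e.g. plants) interacts with
#' column-node j (the other guild, e.g. pollinators).  Zero-degree rows
#' and columns are legal members of the data model: null-model samples
#' routinely contain them and every metric must tolerate them.
#'
#' @param matrix numeric matrix whose entries are all 0 or 1.
#' @param row_labels,col_labels optional character vectors of unique
#'   identifiers; auto-generated (`"r1"`, `"c1"`, ...) when absent.
#' @return An object of class `bipartite_network` with elements
#'   `matrix`, `row_labels`, `col_labels`.
#' @examples
#' net <- bipartite_network(rbind(c(1, 1), c(1, 0)))
#' network_size(net)   # E = 3
#' @export
bipartite_network <- function(matrix, row_labels = NULL, col_labels = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  if (nrow(matrix) < 1L || ncol(matrix) < 1L)
    stop("biadjacency matrix needs at least one row and one column")
  if (anyNA(matrix))
    stop("biadjacency matrix contains missing values")
  if (!all(matrix %in% c(0, 1)))
    stop("biadjacency matrix entries must all be 0 or 1; use read_matrix() to binarize weights")
  storage.mode(matrix) <- "integer"
  n <- nrow(matrix); m <- ncol(matrix)
  if (is.null(row_labels)) row_labels <- paste0("r", seq_len(n))
  if (is.null(col_labels)) col_labels <- paste0("c", seq_len(m))
  row_labels <- as.character(row_labels); col_labels <- as.character(col_labels)
  if (length(row_labels) != n) stop("row_labels length must equal nrow(matrix)")
  if (length(col_labels) != m) stop("col_labels length must equal ncol(matrix)")
  if (anyDuplicated(row_labels)) stop("row labels must be unique within the guild")
  if (anyDuplicated(col_labels)) stop("column labels must be unique within the guild")
  dimnames(matrix) <- NULL
  structure(list(matrix = matrix, row_labels = row_labels, col_labels = col_labels),
            class = "bipartite_network")
}

#' Test for bipartite_network objects
#' @param x object to test.
#' @export
is_bipartite_network <- function(x) inherits(x, "bipartite_network")

as_binet <- function(x) {
  if (is_bipartite_network(x)) return(x)
  if (is.matrix(x)) return(bipartite_network(x))
  stop("expected a bipartite_network or a binary matrix")
}

#' @export
print.bipartite_network <- function(x, ...) {
  d <- dim(x$matrix)
  cat(sprintf("bipartite_network: %d x %d, E = %d links (fill %.3f)\n",
              d[1], d[2], sum(x$matrix), mean(x$matrix)))
  invisible(x)
}

#' Number of links E of a network
#' @param net a [bipartite_network()].
#' @return integer count of 1-entries.
#' @export
network_size <- function(net) sum(as_binet(net)$matrix)

#' Row and column degree sequences
#'
#' Row sums and column sums of the biadjacency matrix (`d_p` for rows,
#' `d_a` for columns).  Both sequences sum to E.
#'
#' @param net a [bipartite_network()].
#' @return list with integer vectors `rows` and `cols`.
#' @export
degree_sequences <- function(net) {
  net <- as_binet(net)
  list(rows = as.integer(rowSums(net$matrix)),
       cols = as.integer(colSums(net$matrix)))
}

#' Scalar descriptors of a bipartite network
#'
#' Computes the descriptors used in the dependency analyses:
#' \describe{
#'   \item{size_s}{`n + m`, total node count.}
#'   \item{fill_matrix}{`E / (n * m)`, the density of contacts used by
#'     the temperature and NIR indices.}
#'   \item{links_per_node}{`E / (n + m)`, the density-of-links covariate
#'     of the regression analysis.  Both fill conventions are kept,
#'     named distinctly, because they serve different formulas.}
#'   \item{eccentricity}{`|n - m| / (n + m)`: 0 for a square matrix,
#'     approaching 1 when one guild dominates.}
#'   \item{degeneracy_g}{fraction of nodes whose degree value is shared
#'     with at least one other node of the *same* guild.}
#' }
#'
#' @param net a [bipartite_network()].
#' @return one-row data.frame with the five descriptors plus `n`, `m`, `E`.
#' @export
network_descriptors <- function(net) {
  net <- as_binet(net)
  n <- nrow(net$matrix); m <- ncol(net$matrix); E <- sum(net$matrix)
  ds <- degree_sequences(net)
  shared <- function(d) { tab <- table(d); sum(d %in% as.numeric(names(tab)[tab > 1L])) }
  g <- (shared(ds$rows) + shared(ds$cols)) / (n + m)
  data.frame(n = n, m = m, E = E,
             size_s = n + m,
             fill_matrix = E / (n * m),
             links_per_node = E / (n + m),
             eccentricity = abs(n - m) / (n + m),
             degeneracy_g = g)
}

# condition used for metric values that do not exist for an input
# (E = 0, phi = 1 for NIR, E = n*m for NMD); callers that want a flagged
# NA rather than an error catch this class.
nest_undefined <- function(msg) {
  stop(errorCondition(msg, class = c("nest_undefined_error", "error", "condition")))
}
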