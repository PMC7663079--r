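#' Maximally packed configuration
#'
#' Orders rows and columns by non-increasing degree so that the filled
#' region concentrates toward the upper-left corner.  Ties are broken
#' deterministically: among equal-degree rows, the one whose partners
#' sit further left (larger sum of packed-column weights) comes first,
#' then original index; columns likewise with packed-row weights.  The
#' two sorts are iterated until stable (at most `max_pass` passes), so
#' the result is reproducible -- no stochastic packing search is used.
#'
#' @param net a [bipartite_network()].
#' @param max_pass maximum alternating sort passes (default 100).
#' @return object of class `packed_network`: list with `network` (the
#'   reordered [bipartite_network()]), `row_order`, `col_order`
#'   (permutations such that `original$matrix[row_order, col_order]`
#'   is the packed matrix).
#' @export
pack_network <- function(net, max_pass = 100L) {
  net <- as_binet(net)
  B <- net$matrix
  n <- nrow(B); m <- ncol(B)
  rd <- rowSums(B); cd <- colSums(B)
  row_ord <- order(-rd, seq_len(n))
  col_ord <- order(-cd, seq_len(m))
  for (pass in seq_len(max_pass)) {
    w_col <- integer(m); w_col[col_ord] <- m:1          # leftmost packed column weighs most
    new_row <- order(-rd, -(B %*% w_col), seq_len(n))
    w_row <- integer(n); w_row[new_row] <- n:1
    new_col <- order(-cd, -(crossprod(B, w_row)), seq_len(m))
    if (identical(new_row, row_ord) && identical(new_col, col_ord)) break
    row_ord <- new_row; col_ord <- new_col
  }
  packed <- bipartite_network(B[row_ord, col_ord, drop = FALSE],
                              row_labels = net$row_labels[row_ord],
                              col_labels = net$col_labels[col_ord])
  structure(list(network = packed, row_order = row_ord, col_order = col_ord),
            class = "packed_network")
}

#' @export
print.packed_network <- function(x, ...) {
  cat("packed_network:\n"); print(x$network); invisible(x)
}

# unit-square coordinates of cell centres: column j -> (j-0.5)/m,
# row i -> (i-0.5)/n; all strictly inside (0,1)
unit_square_x <- function(j, m) (j - 0.5) / m
unit_square_y <- function(i, n) (i - 0.5) / n

#' Canonical perfectly nested matrix
#'
#' The reference matrix of given shape and fill used by the temperature,
#' NMD, discrepancy and normalized-spectral-radius indices: the `E`
#' cells whose centres have the smallest Manhattan distance
#' `x_j + y_i` to the origin of the unit square are filled, ties broken
#' by smaller row index then smaller column index.  Every row's support
#' is a prefix of (or equal to) the previous row's support, so the
#' matrix is perfectly nested and already maximally packed.
#'
#' @param n,m matrix dimensions.
#' @param E number of links, `0 <= E <= n*m`.
#' @return a [bipartite_network()].
#' @examples
#' canonical_nested(2, 2, 3)$matrix   # rbind(c(1,1), c(1,0))
#' @export
canonical_nested <- function(n, m, E) {
  n <- as.integer(n); m <- as.integer(m); E <- as.integer(E)
  if (n < 1L || m < 1L) stop("n and m must be >= 1")
  if (E < 0L || E > n * m) stop(sprintf("E must lie in [0, %d], got %d", n * m, E))
  B <- matrix(0L, n, m)
  if (E > 0L) {
    i <- rep(seq_len(n), times = m)
    j <- rep(seq_len(m), each = n)
    d <- unit_square_x(j, m) + unit_square_y(i, n)
    ord <- order(d, i, j)
    B[cbind(i[ord[seq_len(E)]], j[ord[seq_len(E)]])] <- 1L
  }
  bipartite_network(B)
}

#' Isocline of perfect nestedness (discrete form)
#'
#' The boundary separating filled from empty cells in the canonical
#' perfectly nested matrix of the same `n`, `m`, `E`: for each row i
#' (packed order) the threshold `c_i` such that cells `(i, j <= c_i)`
#' lie on the filled side.  `c` is non-increasing and sums to `E`.
#'
#' @inheritParams canonical_nested
#' @return object of class `ipn_boundary`: list with `boundary`
#'   (integer vector `c_i`), `n`, `m`, `E`.
#' @export
ipn_boundary <- function(n, m, E) {
  ref <- canonical_nested(n, m, E)
  structure(list(boundary = as.integer(rowSums(ref$matrix)),
                 n = as.integer(n), m = as.integer(m), E = as.integer(E)),
            class = "ipn_boundary")
}

#' Unexpected presences and absences relative to the IPN
#'
#' Compares a packed matrix against the isocline built for the same
#' `n`, `m`, `E`: 1-cells outside the boundary are unexpected presences,
#' 0-cells inside it unexpected absences.  Because both matrices hold
#' `E` links, the two sets always have equal cardinality.
#'
#' @param packed a [pack_network()] result (or a network, packed first).
#' @param ipn an [ipn_boundary()] for the same dimensions and link count.
#' @return data.frame with columns `row`, `col` (packed indices) and
#'   `kind` (`"unexpected_presence"` / `"unexpected_absence"`).
#' @export
unexpectedness_set <- function(packed, ipn) {
  if (!inherits(packed, "packed_network")) packed <- pack_network(packed)
  B <- packed$network$matrix
  n <- nrow(B); m <- ncol(B)
  if (!inherits(ipn, "ipn_boundary")) stop("`ipn` must be an ipn_boundary")
  if (ipn$n != n || ipn$m != m)
    stop(sprintf("dimension mismatch: network is %dx%d, IPN built for %dx%d",
                 n, m, ipn$n, ipn$m))
  if (ipn$E != sum(B))
    stop(sprintf("link-count mismatch: network has E=%d, IPN built for E=%d",
                 sum(B), ipn$E))
  inside <- col(B) <= ipn$boundary[row(B)]
  pres <- which(B == 1L & !inside, arr.ind = TRUE)
  abse <- which(B == 0L & inside, arr.ind = TRUE)
  out <- data.frame(
    row = c(pres[, 1], abse[, 1]),
    col = c(pres[, 2], abse[, 2]),
    kind = rep(c("unexpected_presence", "unexpected_absence"),
               c(nrow(pres), nrow(abse))),
    stringsAsFactors = FALSE)
  out[order(out$row, out$col), , drop = FALSE]
}
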