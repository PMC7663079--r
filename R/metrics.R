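# Eight nestedness indices for binary bipartite networks, plus the
# transformed 0-100 orientations (larger = more nested) used for
# cross-metric comparison.

# run expr under a temporary RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Atmar-Patterson matrix temperature
#'
#' Packs the matrix, builds the discrete isocline of perfect nestedness
#' (IPN) for the same `n`, `m`, `E`, and scores every unexpected
#' presence/absence by `u_ij = (d_ij / D_ij)^2`, where `d_ij` is the
#' distance from the cell centre to the IPN crossing measured along the
#' 45-degree diagonal of the unit square through the cell, and `D_ij`
#' the full length of that diagonal inside the square.  Since the IPN is
#' a non-increasing step curve the diagonal crosses it exactly once.
#' `T_AP = 100 / (U_max * n * m) * sum(u_ij)`; the transformed index
#' `T = 100 - T_AP` is clamped to `[0, 100]`.
#'
#' A perfectly nested matrix of the same fill has an empty
#' unexpectedness set, hence `T_AP = 0` exactly.  The cell-diagonal
#' geometry is this package's documented convention; temperatures are
#' not expected to match legacy BINMATNEST output digit-for-digit.
#'
#' @param net a [bipartite_network()], `E >= 1`.
#' @param u_max normalization constant of the original implementation
#'   (default 0.04145); it only rescales `T_AP`.
#' @return list with `t_ap` (raw, >= 0) and `t` (transformed, 0-100).
#' @export
nest_temperature <- function(net, u_max = 0.04145) {
  net <- as_binet(net)
  E <- sum(net$matrix)
  if (E == 0L) nest_undefined("temperature is undefined for a network without links")
  pk <- pack_network(net)
  B <- pk$network$matrix
  n <- nrow(B); m <- ncol(B)
  ipn <- ipn_boundary(n, m, E)
  cb <- ipn$boundary
  un <- unexpectedness_set(pk, ipn)
  usum <- 0
  for (k in seq_len(nrow(un))) {
    i <- un$row[k]; j <- un$col[k]
    x <- unit_square_x(j, m); y <- unit_square_y(i, n)
    t0 <- -min(x, y); t1 <- min(1 - x, 1 - y)
    r_lo <- max(1L, ceiling((y + t0) * n - 1e-12))
    r_hi <- min(n, ceiling((y + t1) * n + 1e-12))
    tstar <- NA_real_
    for (r in r_lo:r_hi) {
      ta <- max(t0, (r - 1) / n - y)
      tb <- min(t1, r / n - y)
      if (tb < ta - 1e-12) next
      if (x + ta - cb[r] / m >= 0) { tstar <- ta; break }      # crossing at a step
      tc <- cb[r] / m - x                                      # in-band crossing
      if (tc >= ta - 1e-12 && tc <= tb + 1e-12) { tstar <- min(max(tc, ta), tb); break }
    }
    if (is.na(tstar)) tstar <- t1   # boundary beyond the square edge
    d <- abs(tstar) * sqrt(2)
    D <- (t1 - t0) * sqrt(2)
    usum <- usum + (d / D)^2
  }
  t_ap <- 100 / (u_max * n * m) * usum
  list(t_ap = t_ap, t = min(max(100 - t_ap, 0), 100))
}

#' Nestedness index based on Manhattan distance (NMD)
#'
#' Maps cells of the packed matrix to the unit square and sums their
#' Manhattan distances `x_j + y_i` to the nested corner.  `tau = (d -
#' d_nest) / (d_rand - d_nest)` compares the observed sum `d` with the
#' canonical perfectly nested matrix (`d_nest`) and the expectation
#' under uniformly random placement of `E` links (`d_rand = E`, since
#' the mean cell distance is exactly 1); `tau` is clamped to `[0, 1]`.
#' The transformed index is `NMD = 100 * (1 - tau)`.
#'
#' @param net a [bipartite_network()] with `1 <= E < n*m` (at `E = n*m`
#'   the normalizing denominator vanishes).
#' @return list with `tau` and `nmd`.
#' @export
nest_nmd <- function(net) {
  net <- as_binet(net)
  n <- nrow(net$matrix); m <- ncol(net$matrix); E <- sum(net$matrix)
  if (E == 0L) nest_undefined("NMD is undefined for a network without links")
  if (E == n * m)
    nest_undefined("NMD is undefined for a completely filled matrix (d_rand = d_nest)")
  dist_sum <- function(B) {
    idx <- which(B == 1L, arr.ind = TRUE)
    sum(unit_square_x(idx[, 2], ncol(B)) + unit_square_y(idx[, 1], nrow(B)))
  }
  d <- dist_sum(pack_network(net)$network$matrix)
  d_nest <- dist_sum(canonical_nested(n, m, E)$matrix)
  d_rand <- E
  tau <- min(max((d - d_nest) / (d_rand - d_nest), 0), 1)
  list(tau = tau, nmd = 100 * (1 - tau))
}

# shared pairwise-overlap sum for NODF / stable-NODF over one guild;
# rows of B are the guild's nodes, sorted here by decreasing degree
nodf_half <- function(B, stable) {
  d <- rowSums(B)
  ord <- order(-d)
  B <- B[ord, , drop = FALSE]; d <- d[ord]
  n <- nrow(B)
  if (n < 2L) return(0)
  O <- tcrossprod(B)                         # O[i,j] = shared partners
  dj <- matrix(d, n, n, byrow = TRUE)        # degree of the later element
  contrib <- O / ifelse(dj > 0, dj, 1)
  contrib[dj == 0] <- 0
  if (!stable) contrib[dj >= matrix(d, n, n)] <- 0   # decreasing-fill term
  sum(contrib[upper.tri(contrib)])
}

#' NODF: nestedness by overlap and decreasing fill
#'
#' Closed-form pairwise formulation: with the matrix sorted by
#' decreasing degree, each ordered row pair i < j contributes the
#' overlap fraction `sum_a b_ia b_ja / d_j` when `d_j < d_i` and 0 when
#' degrees tie (the Heaviside convention `theta(0) = 1`, which makes
#' NODF penalize degree repetition) or `d_j = 0`; column pairs likewise.
#' The total is normalized by `K = (n(n-1) + m(m-1)) / 200` so the index
#' lives in `[0, 100]`.
#'
#' @param net a [bipartite_network()] with `n >= 2` or `m >= 2`.
#' @return NODF value in `[0, 100]`.
#' @export
nest_nodf <- function(net) {
  net <- as_binet(net)
  n <- nrow(net$matrix); m <- ncol(net$matrix)
  K <- (n * (n - 1) + m * (m - 1)) / 200
  if (K == 0) stop("NODF needs at least two rows or two columns")
  (nodf_half(net$matrix, FALSE) + nodf_half(t(net$matrix), FALSE)) / K
}

#' stable-NODF: overlap without the decreasing-fill suppression
#'
#' Like [nest_nodf()] but pairs with tied degrees keep their overlap
#' contribution (divisor: the degree of the later, i.e. smaller, element
#' of the pair), so degree repetition is not penalized.
#'
#' @inheritParams nest_nodf
#' @return stable-NODF value in `[0, 100]`.
#' @export
nest_stable_nodf <- function(net) {
  net <- as_binet(net)
  n <- nrow(net$matrix); m <- ncol(net$matrix)
  K <- (n * (n - 1) + m * (m - 1)) / 200
  if (K == 0) stop("stable-NODF needs at least two rows or two columns")
  (nodf_half(net$matrix, TRUE) + nodf_half(t(net$matrix), TRUE)) / K
}

#' Brualdi-Sanderson discrepancy
#'
#' Counts, on one deterministic maximally packed configuration, the
#' 1-cells of each row that fall outside its `d_i` leftmost columns --
#' the presences that would have to move to produce a perfectly nested
#' matrix of equal size and fill.  Normalized per Greve & Chown by the
#' number of links: `Delta' = 100 * (1 - Delta / E)`.  Averaging over
#' alternative packings is deliberately not implemented.
#'
#' @param net a [bipartite_network()], `E >= 1`.
#' @return list with `delta` (raw count) and `delta_prime` (0-100).
#' @export
nest_discrepancy <- function(net) {
  net <- as_binet(net)
  E <- sum(net$matrix)
  if (E == 0L) nest_undefined("discrepancy is undefined for a network without links")
  B <- pack_network(net)$network$matrix
  inside <- sum(vapply(seq_len(nrow(B)), function(i) {
    d <- sum(B[i, ])
    if (d == 0L) 0L else sum(B[i, seq_len(d)])
  }, integer(1)))
  delta <- E - inside
  list(delta = delta, delta_prime = 100 * (1 - delta / E))
}

#' Attack tolerance curve (ATC)
#'
#' Removes the nodes of one guild one at a time, in increasing (IDR) or
#' decreasing (DDR) degree order, and records -- before each removal --
#' the fraction of the *initially connected* opposite-guild nodes that
#' still hold at least one link.  Normalizing over initially connected
#' nodes makes `R_IDR = 1` exact for any perfectly nested network, the
#' identity the NIR index is built on; zero-degree nodes (possible in
#' null-model samples) therefore do not dilute the curve.  The area is
#' the left-Riemann sum `(1/N) * sum(surviving)`.
#'
#' @param net a [bipartite_network()].
#' @param removed_guild `"rows"` or `"cols"`: the guild being removed.
#' @param strategy `"IDR"` (increasing degree) or `"DDR"` (decreasing).
#' @param tie_seed seed for permuting nodes of equal degree.
#' @return object of class `atc`: list with `removed_fraction` (grid
#'   `k/N`, `k = 0..N-1`), `surviving_fraction`, `area`.
#' @export
attack_tolerance <- function(net, removed_guild = c("rows", "cols"),
                             strategy = c("IDR", "DDR"), tie_seed = 1L) {
  net <- as_binet(net)
  removed_guild <- match.arg(removed_guild)
  strategy <- match.arg(strategy)
  M <- if (removed_guild == "rows") net$matrix else t(net$matrix)
  N <- nrow(M)
  deg <- rowSums(M)
  tie <- with_seed(tie_seed, sample.int(N))
  ord <- if (strategy == "IDR") order(deg, tie) else order(-deg, tie)
  conn <- which(colSums(M) > 0L)
  surv <- numeric(N)
  if (length(conn) > 0L) {
    cnt <- colSums(M[, conn, drop = FALSE])
    for (k in seq_len(N)) {
      surv[k] <- mean(cnt > 0L)
      cnt <- cnt - M[ord[k], conn]
    }
  }
  structure(list(removed_fraction = (seq_len(N) - 1L) / N,
                 surviving_fraction = surv,
                 area = mean(surv),
                 removed_guild = removed_guild, strategy = strategy),
            class = "atc")
}

#' Nesting index based on network robustness (NIR)
#'
#' For each guild, the areas under the attack tolerance curves of the
#' two extreme strategies are combined as `(R_IDR - R_DDR) / (1 - phi)`
#' with `phi = E / (n*m)`; for a perfectly nested network `R_IDR = 1`
#' and `R_DDR = phi`, so the index is 1.  Because degree ties make the
#' removal order ambiguous, areas are averaged over `n_orderings`
#' seeded tie permutations.  The final NIR is the mean of the two
#' guilds' values.
#'
#' @param net a [bipartite_network()] with `E >= 1` and `phi < 1` (the
#'   index loses all sensitivity at full fill).
#' @param n_orderings tie permutations averaged per guild/strategy
#'   (default 100; collapses to 1 automatically when the removed guild
#'   has no degree ties).
#' @param seed master seed for the tie permutations.
#' @return NIR value (about `[0, 1]`, up to tie-sampling noise).
#' @export
nest_nir <- function(net, n_orderings = 100L, seed = 1L) {
  net <- as_binet(net)
  n <- nrow(net$matrix); m <- ncol(net$matrix); E <- sum(net$matrix)
  if (E == 0L) nest_undefined("NIR is undefined for a network without links")
  phi <- E / (n * m)
  if (phi >= 1) nest_undefined("NIR is undefined at phi = 1 (denominator vanishes)")
  guild_value <- function(guild, base_seed) {
    deg <- if (guild == "rows") rowSums(net$matrix) else colSums(net$matrix)
    reps <- if (anyDuplicated(deg)) n_orderings else 1L
    r_idr <- mean(vapply(seq_len(reps), function(k)
      attack_tolerance(net, guild, "IDR", tie_seed = base_seed + k)$area, numeric(1)))
    r_ddr <- mean(vapply(seq_len(reps), function(k)
      attack_tolerance(net, guild, "DDR", tie_seed = base_seed + 7919L * k)$area, numeric(1)))
    (r_idr - r_ddr) / (1 - phi)
  }
  mean(c(guild_value("rows", seed), guild_value("cols", seed + 104729L)))
}

#' Spectral radius of the biadjacency matrix
#'
#' Largest singular value of `B`, equal to the spectral radius of the
#' symmetric two-guild adjacency matrix.  Invariant under any row or
#' column permutation, so no packing is involved.
#'
#' @param net a [bipartite_network()].
#' @return the spectral radius (0 for an empty matrix).
#' @export
spectral_radius <- function(net) {
  net <- as_binet(net)
  B <- net$matrix
  storage.mode(B) <- "double"
  if (all(B == 0)) return(0)
  norm(B, type = "2")
}

#' Normalized spectral radius
#'
#' `rho_norm = 100 * rho / rho_max`, where `rho_max` is the spectral
#' radius of the canonical perfectly nested matrix of the same `n`, `m`,
#' `E`.  The canonical matrix may very rarely miss the true maximizer by
#' a sliver; values above 100 are then reported unclamped with a warning.
#'
#' @param net a [bipartite_network()], `E >= 1`.
#' @return normalized spectral radius, nominally in `(0, 100]`.
#' @export
nest_rho_norm <- function(net) {
  net <- as_binet(net)
  E <- sum(net$matrix)
  if (E == 0L)
    nest_undefined("normalized spectral radius is undefined for a network without links")
  rho <- spectral_radius(net)
  rho_max <- spectral_radius(canonical_nested(nrow(net$matrix), ncol(net$matrix), E))
  out <- 100 * rho / rho_max
  if (out > 100 + 1e-9)
    warning(sprintf("rho_norm = %.4f exceeds 100: canonical reference is not the exact maximizer here", out))
  out
}

metric_names <- function() {
  c("temperature", "nmd", "nodf", "stable_nodf", "discrepancy",
    "nir", "spectral_radius", "rho_norm")
}

# raw + transformed value of one metric; errors of class
# nest_undefined_error are propagated to the caller
metric_raw_transformed <- function(net, name, nir_orderings = 100L, seed = 1L) {
  switch(name,
    temperature = { v <- nest_temperature(net); c(raw = v$t_ap, transformed = v$t) },
    nmd = { v <- nest_nmd(net); c(raw = v$tau, transformed = v$nmd) },
    nodf = { v <- nest_nodf(net); c(raw = v, transformed = v) },
    stable_nodf = { v <- nest_stable_nodf(net); c(raw = v, transformed = v) },
    discrepancy = { v <- nest_discrepancy(net); c(raw = v$delta, transformed = v$delta_prime) },
    nir = { v <- nest_nir(net, n_orderings = nir_orderings, seed = seed)
            c(raw = v, transformed = 100 * v) },
    spectral_radius = { v <- spectral_radius(net); c(raw = v, transformed = NA_real_) },
    rho_norm = { v <- nest_rho_norm(net); c(raw = v, transformed = v) },
    stop("unknown metric: ", name))
}

# transformed (0-100 oriented) scalar used for ensemble comparisons;
# spectral_radius is kept raw (it has no bounded transform)
metric_value <- function(net, name, nir_orderings = 20L, seed = 1L) {
  v <- metric_raw_transformed(net, name, nir_orderings = nir_orderings, seed = seed)
  if (name == "spectral_radius") unname(v["raw"]) else unname(v["transformed"])
}

#' Compute all nestedness indices of a network
#'
#' Evaluates the eight indices and their transformed 0-100 orientations
#' in one pass.  Metrics that are undefined for the input (empty
#' network; full matrix for NMD and NIR) are flagged, never silently
#' zeroed.
#'
#' @param net a [bipartite_network()].
#' @param metrics character vector of metric names (default: all eight;
#'   see `binest:::metric_names()`).
#' @param nir_orderings,seed options forwarded to [nest_nir()].
#' @return object of class `nestedness_report`: data.frame with columns
#'   `metric`, `raw`, `transformed`, `defined`, `note`.
#' @examples
#' nestedness_report(canonical_nested(6, 8, 20))
#' @export
nestedness_report <- function(net, metrics = metric_names(),
                              nir_orderings = 100L, seed = 1L) {
  net <- as_binet(net)
  bad <- setdiff(metrics, metric_names())
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  rows <- lapply(metrics, function(nm) {
    tryCatch({
      v <- metric_raw_transformed(net, nm, nir_orderings = nir_orderings, seed = seed)
      data.frame(metric = nm, raw = unname(v["raw"]),
                 transformed = unname(v["transformed"]),
                 defined = TRUE, note = "", stringsAsFactors = FALSE)
    }, nest_undefined_error = function(e) {
      data.frame(metric = nm, raw = NA_real_, transformed = NA_real_,
                 defined = FALSE, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("nestedness_report", "data.frame")
  out
}

#' Serialize a nestedness report
#'
#' `write_report_json()` writes the report as flat JSON;
#' `write_report_csv()` writes a single row (columns
#' `<metric>_raw`, `<metric>_transformed`) suitable for batch
#' concatenation across networks.
#'
#' @param report a [nestedness_report()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @param id optional identifier written as the first column.
#' @export
write_report_csv <- function(report, path, id = NULL) {
  vals <- c(rbind(report$raw, report$transformed))
  names(vals) <- c(rbind(paste0(report$metric, "_raw"),
                         paste0(report$metric, "_transformed")))
  row <- as.data.frame(as.list(vals))
  if (!is.null(id)) row <- cbind(data.frame(network = id), row)
  utils::write.csv(row, path, row.names = FALSE)
  invisible(path)
}
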