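# Maximum-entropy / maximum-likelihood null ensemble for binary
# bipartite networks (bipartite configuration model): both degree
# sequences are preserved on average, and the link probabilities
# p_ia = x_i y_a / (1 + x_i y_a) follow from the fitted Lagrange
# multipliers x (rows) and y (columns).

# analytically clamp structurally forced nodes before solving:
# empty nodes (residual degree 0) get p = 0, saturated nodes (degree =
# number of remaining opposite nodes) get p = 1; peeling iterates
# because a clamp can saturate or empty further nodes.
bicm_peel <- function(B) {
  n <- nrow(B); m <- ncol(B)
  P <- matrix(NA_real_, n, m)
  active_r <- rep(TRUE, n); active_c <- rep(TRUE, m)
  dr <- rowSums(B); dc <- colSums(B)
  flag_r <- rep("free", n); flag_c <- rep("free", m)
  repeat {
    changed <- FALSE
    idx <- which(active_r & dr == 0L)
    if (length(idx)) {
      P[idx, active_c] <- 0; active_r[idx] <- FALSE; flag_r[idx] <- "empty"
      changed <- TRUE
    }
    idx <- which(active_r & dr == sum(active_c) & sum(active_c) > 0L)
    if (length(idx)) {
      P[idx, active_c] <- 1
      dc[active_c] <- dc[active_c] - length(idx)
      active_r[idx] <- FALSE; flag_r[idx] <- "saturated"
      changed <- TRUE
    }
    idx <- which(active_c & dc == 0L & active_c)
    if (length(idx)) {
      P[active_r, idx] <- 0; active_c[idx] <- FALSE; flag_c[idx] <- "empty"
      changed <- TRUE
    }
    idx <- which(active_c & dc == sum(active_r) & sum(active_r) > 0L)
    if (length(idx)) {
      P[active_r, idx] <- 1
      dr[active_r] <- dr[active_r] - length(idx)
      active_c[idx] <- FALSE; flag_c[idx] <- "saturated"
      changed <- TRUE
    }
    if (!changed) break
  }
  list(P = P, active_r = active_r, active_c = active_c,
       dr = dr, dc = dc, flag_r = flag_r, flag_c = flag_c)
}

# damped fixed-point solve of the likelihood equations on degree
# classes.  dr, dc: residual degrees of active nodes; with
# reduce = FALSE every node is its own class (used in tests to validate
# the reduction).
bicm_solve <- function(dr, dc, x0, y0, tol, max_iter, damp = 1, reduce = TRUE) {
  cls_r <- if (reduce) match(dr, unique(dr)) else seq_along(dr)
  cls_c <- if (reduce) match(dc, unique(dc)) else seq_along(dc)
  d_r <- dr[!duplicated(cls_r)]; n_r <- as.numeric(tabulate(cls_r))
  d_c <- dc[!duplicated(cls_c)]; n_c <- as.numeric(tabulate(cls_c))
  x <- x0[!duplicated(cls_r)]
  y <- y0[!duplicated(cls_c)]
  it <- 0L
  for (it in seq_len(max_iter)) {
    xy <- outer(x, y)
    Pm <- xy / (1 + xy)
    res <- max(abs(c(Pm %*% n_c - d_r, crossprod(Pm, n_r) - d_c)))
    if (res <= tol) break
    x_new <- d_r / as.vector((1 / (1 + xy)) %*% (n_c * y))
    x <- x * (x_new / x)^damp
    xy <- outer(x, y)
    y_new <- d_c / as.vector(crossprod(1 / (1 + xy), n_r * x))
    y <- y * (y_new / y)^damp
  }
  xy <- outer(x, y)
  Pm <- xy / (1 + xy)
  res <- max(abs(c(Pm %*% n_c - d_r, crossprod(Pm, n_r) - d_c)))
  list(x = x[cls_r], y = y[cls_c],
       residual = res, converged = res <= tol, iterations = it)
}

#' Fit the bipartite configuration model (BiCM)
#'
#' Determines the Lagrange multipliers of the maximum-entropy ensemble
#' whose expected degree sequences equal the observed ones, by damped
#' fixed-point iteration on the degree-class-reduced likelihood
#' equations.  The likelihood is concave in the log-multipliers, but as
#' a safeguard the solve is repeated from `n_starts` seeded random
#' initial conditions and the runs are required to agree on the
#' expected degrees within `10 * tol`.  Structurally saturated
#' (degree = opposite-guild size) and empty (degree = 0) nodes are
#' clamped analytically before optimization.
#'
#' @param net a [bipartite_network()].
#' @param tol maximum absolute difference allowed between expected and
#'   observed degrees (default `1e-8 * max(n, m)`).
#' @param max_iter iteration cap per start (default 5000).
#' @param n_starts number of random initial conditions (default 8).
#' @param seed seed for the random starts.
#' @param reduce collapse equal-degree nodes into shared multipliers
#'   (default `TRUE`; `FALSE` solves the full per-node system, useful
#'   only to validate the reduction).
#' @return object of class `bicm_fit`: list with `probs` (n x m matrix
#'   of `p_ij`), `row_params`, `col_params` (multipliers, `NA` for
#'   clamped nodes), `row_flags`, `col_flags`
#'   (`"free"`/`"empty"`/`"saturated"`), `residual`, `iterations`,
#'   `tol`.
#' @examples
#' fit <- fit_bicm(bipartite_network(rbind(c(1, 0), c(0, 1))))
#' fit$probs          # all 0.5
#' @export
fit_bicm <- function(net, tol = NULL, max_iter = 5000L, n_starts = 8L,
                     seed = 1L, reduce = TRUE) {
  net <- as_binet(net)
  B <- net$matrix
  n <- nrow(B); m <- ncol(B)
  if (is.null(tol)) tol <- 1e-8 * max(n, m)
  peel <- bicm_peel(B)
  x_full <- rep(NA_real_, n); y_full <- rep(NA_real_, m)
  P <- peel$P
  if (any(peel$active_r) && any(peel$active_c)) {
    dr <- peel$dr[peel$active_r]; dc <- peel$dc[peel$active_c]
    na <- sum(peel$active_c); nb <- sum(peel$active_r)
    runs <- with_seed(seed, lapply(seq_len(n_starts), function(s) {
      x0 <- if (s == 1L) dr / sqrt(sum(dr)) else stats::runif(length(dr), 0.01, 2)
      y0 <- if (s == 1L) dc / sqrt(sum(dc)) else stats::runif(length(dc), 0.01, 2)
      bicm_solve(dr, dc, x0, y0, tol, max_iter, reduce = reduce)
    }))
    ok <- vapply(runs, `[[`, logical(1), "converged")
    if (!any(ok)) {
      res <- vapply(runs, `[[`, numeric(1), "residual")
      stop(sprintf(paste0("BiCM solver failed to converge in %d iterations ",
                          "across %d starts (best residual %.3g, tol %.3g)"),
                   max_iter, n_starts, min(res), tol))
    }
    runs <- runs[ok]
    exp_deg <- lapply(runs, function(r) {
      xy <- outer(r$x, r$y); Pm <- xy / (1 + xy)
      c(rowSums(Pm), colSums(Pm))
    })
    if (length(runs) > 1L) {
      spread <- max(vapply(exp_deg[-1], function(e) max(abs(e - exp_deg[[1]])), numeric(1)))
      if (spread > 10 * tol)
        stop(sprintf("BiCM multi-start runs disagree on expected degrees (spread %.3g > %.3g)",
                     spread, 10 * tol))
    }
    best <- runs[[1]]
    x_full[peel$active_r] <- best$x
    y_full[peel$active_c] <- best$y
    xy <- outer(best$x, best$y)
    P[peel$active_r, peel$active_c] <- xy / (1 + xy)
    residual <- best$residual
    iterations <- best$iterations
  } else {
    residual <- 0; iterations <- 0L
  }
  P[is.na(P)] <- 0   # only when one guild fully clamped left orphan cells
  structure(list(probs = P,
                 row_params = x_full, col_params = y_full,
                 row_flags = peel$flag_r, col_flags = peel$flag_c,
                 residual = residual, iterations = iterations, tol = tol,
                 row_labels = net$row_labels, col_labels = net$col_labels),
            class = "bicm_fit")
}

#' @export
print.bicm_fit <- function(x, ...) {
  cat(sprintf("bicm_fit: %d x %d, residual %.3g (tol %.3g), %d iterations\n",
              nrow(x$probs), ncol(x$probs), x$residual, x$tol, x$iterations))
  invisible(x)
}

# rebuild the probability matrix from (possibly perturbed) multipliers,
# keeping clamped cells; used by the likelihood-maximum property tests
bicm_probs_from_params <- function(fit, x = fit$row_params, y = fit$col_params) {
  P <- fit$probs
  fr <- fit$row_flags == "free"; fc <- fit$col_flags == "free"
  if (any(fr) && any(fc)) {
    xy <- outer(x[fr], y[fc])
    P[fr, fc] <- xy / (1 + xy)
  }
  P
}

#' Bernoulli log-likelihood of a network under a fitted ensemble
#'
#' `sum(b log p + (1 - b) log(1 - p))` over all cells, with the
#' `0 * log 0 = 0` convention for clamped cells that match the
#' observation.  The fitted multipliers maximize this value over the
#' free multipliers.
#'
#' @param net a [bipartite_network()].
#' @param fit a [fit_bicm()] result (or a bare probability matrix).
#' @return the log-likelihood (`-Inf` if a clamped probability
#'   contradicts an observed cell).
#' @export
bicm_loglik <- function(net, fit) {
  net <- as_binet(net)
  P <- if (inherits(fit, "bicm_fit")) fit$probs else fit
  if (!all(dim(P) == dim(net$matrix))) stop("probability matrix shape mismatch")
  B <- net$matrix
  term <- function(b, p) ifelse(b == (p == 1) * 1L & (p %in% c(0, 1)), 0,
                                b * log(p) + (1 - b) * log(1 - p))
  sum(term(B, P))
}

# deterministic per-sample substream seed; reproducible subsets for any
# n_samples without consuming one global stream
sample_seed <- function(seed, k) as.integer((as.numeric(seed) * 69069 + k * 1013) %% 2147483629)

#' Sample networks from a fitted BiCM ensemble
#'
#' Draws each cell independently as Bernoulli(`p_ij`).  Sample `k` uses
#' a substream seed derived from (`seed`, `k`), so any subset of the
#' ensemble is reproducible.  Zero-degree nodes arising in a sample are
#' retained: null matrices may vary in their number of connected nodes.
#'
#' @param fit a [fit_bicm()] result or a bare probability matrix.
#' @param n_samples number of networks to draw.
#' @param seed master seed.
#' @param as_network return [bipartite_network()] objects (default) or
#'   bare integer matrices (faster for large ensembles).
#' @return list of sampled networks.
#' @export
sample_bicm <- function(fit, n_samples, seed = 1L, as_network = TRUE) {
  P <- if (inherits(fit, "bicm_fit")) fit$probs else fit
  n <- nrow(P); m <- ncol(P)
  lapply(seq_len(n_samples), function(k) {
    B <- with_seed(sample_seed(seed, k),
                   matrix((stats::runif(n * m) < P) * 1L, n, m))
    if (as_network) bipartite_network(B) else B
  })
}

#' Ensemble statistics and z-scores of nestedness metrics
#'
#' Computes the chosen metrics on `n_samples` networks drawn from the
#' fitted ensemble and summarizes each as mean, standard deviation
#' (denominator `n - 1`) and the z-score of the observed network,
#' `z = (nu - <nu>) / sigma` -- flagged undefined when `sigma = 0`.
#' Samples for which a metric is undefined (e.g. an empty draw) are
#' excluded and counted.  Metric values are compared on the transformed
#' 0-100 orientation (raw scale for the unnormalized spectral radius).
#'
#' @param net the observed [bipartite_network()].
#' @param fit its [fit_bicm()] result (or probability matrix).
#' @param metrics metric names (default: all eight).
#' @param n_samples ensemble size (default 1e4, the reference choice;
#'   smaller values trade precision for speed).
#' @param seed master sampling seed.
#' @param nir_orderings tie permutations for NIR on each sample.
#' @return object of class `ensemble_summary`: data.frame with columns
#'   `metric`, `observed`, `mean`, `sd`, `z`, `n_used`, `n_undefined`;
#'   attributes `seed`, `diagnostics` (mean sample fill, mean count of
#'   zero-degree nodes).
#' @export
ensemble_metrics <- function(net, fit, metrics = metric_names(),
                             n_samples = 10000L, seed = 1L, nir_orderings = 10L) {
  net <- as_binet(net)
  bad <- setdiff(metrics, metric_names())
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  samples <- sample_bicm(fit, n_samples, seed = seed, as_network = FALSE)
  vals <- matrix(NA_real_, n_samples, length(metrics),
                 dimnames = list(NULL, metrics))
  for (k in seq_len(n_samples)) {
    s <- bipartite_network(samples[[k]])
    for (nm in metrics) {
      vals[k, nm] <- tryCatch(
        metric_value(s, nm, nir_orderings = nir_orderings,
                     seed = sample_seed(seed, k) %% 100000L),
        nest_undefined_error = function(e) NA_real_)
    }
  }
  obs <- vapply(metrics, function(nm) tryCatch(
    metric_value(net, nm, nir_orderings = max(nir_orderings, 20L), seed = seed),
    nest_undefined_error = function(e) NA_real_), numeric(1))
  out <- do.call(rbind, lapply(metrics, function(nm) {
    v <- vals[, nm]
    used <- sum(!is.na(v))
    mu <- if (used) mean(v, na.rm = TRUE) else NA_real_
    sg <- if (used > 1L) stats::sd(v, na.rm = TRUE) else NA_real_
    z <- if (!is.na(obs[nm]) && !is.na(sg) && sg > 0) (obs[nm] - mu) / sg else NA_real_
    data.frame(metric = nm, observed = obs[nm], mean = mu, sd = sg, z = z,
               n_used = used, n_undefined = n_samples - used,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "diagnostics") <- list(
    mean_fill = mean(vapply(samples, mean, numeric(1))),
    mean_zero_degree_nodes = mean(vapply(samples, function(B)
      sum(rowSums(B) == 0L) + sum(colSums(B) == 0L), numeric(1))))
  class(out) <- c("ensemble_summary", "data.frame")
  out
}
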