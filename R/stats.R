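# Dependency analyses: Spearman rank correlations between metric values
# and network descriptors, and the multilinear regression of metric
# values (or z-scores) on size, density of links and eccentricity.

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-corrected (average-rank) Spearman coefficient: the Pearson
#' correlation of the rank vectors.  The two-sided p-value uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom; for `n <= 8` an exact permutation p-value can be
#' requested instead (full enumeration of the `n!` orderings).
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @param exact use the exact permutation null (only for `n <= 8`).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_rank <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    nest_undefined("Spearman correlation undefined for a constant sequence")
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8L) stop("exact permutation p-value supported for n <= 8 only")
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p_value <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p_value, n = n)
}

# all permutations of 1..n as a matrix (n! rows); n is capped by callers
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

#' Correlation table between metrics and descriptors
#'
#' Computes [spearman_rank()] for every (metric, descriptor) pair and
#' flags significance at the raw `p < .01` threshold (no
#' multiple-testing correction is applied, matching the reference
#' analysis; interpret the grid accordingly).
#'
#' @param metric_table data.frame of metric values, one row per network.
#' @param descriptor_table data.frame of descriptors, same row order.
#' @return data.frame with columns `metric`, `descriptor`, `rho`,
#'   `p_value`, `significant`.
#' @export
correlation_table <- function(metric_table, descriptor_table) {
  if (nrow(metric_table) != nrow(descriptor_table))
    stop("metric and descriptor tables must describe the same networks")
  out <- expand.grid(metric = names(metric_table),
                     descriptor = names(descriptor_table),
                     stringsAsFactors = FALSE)
  res <- mapply(function(mn, dn) {
    x <- metric_table[[mn]]; y <- descriptor_table[[dn]]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3L) return(c(NA_real_, NA_real_))
    r <- tryCatch(spearman_rank(x[keep], y[keep]),
                  nest_undefined_error = function(e) NULL)
    if (is.null(r)) c(NA_real_, NA_real_) else c(r$rho, r$p_value)
  }, out$metric, out$descriptor)
  out$rho <- res[1, ]
  out$p_value <- res[2, ]
  out$significant <- !is.na(out$p_value) & out$p_value < 0.01
  out
}

#' Multilinear regression of an index on network descriptors
#'
#' Ordinary least squares with intercept:
#' `nu = b0 + b1 * s + b2 * phi + b3 * eps + error`, where `s` is the
#' size `n + m`, `phi` the density of links `E / (n + m)` and `eps` the
#' eccentricity `|n - m| / (n + m)`.  Reports per-coefficient t-ratios
#' and p-values (flagged at `p < .01`) and the adjusted R-squared.
#'
#' @param response numeric vector (metric values or z-scores).
#' @param s,phi,eps numeric descriptor vectors of the same length.
#' @return object of class `nest_regression`: list with `coefficients`
#'   (data.frame: `term`, `estimate`, `std_error`, `t_ratio`,
#'   `p_value`, `significant`), `adjusted_r2`, `n`.
#' @export
fit_multilinear <- function(response, s, phi, eps) {
  df <- data.frame(response = response, s = s, phi = phi, eps = eps)
  if (anyNA(df)) stop("missing values are not allowed; drop incomplete networks first")
  if (nrow(df) < 6L) stop("need at least 6 observations")
  X <- cbind(1, df$s, df$phi, df$eps)
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    dropped <- c("(intercept)", "s", "phi", "eps")[-qrX$pivot[seq_len(qrX$rank)]]
    stop("rank-deficient design: collinear column(s) ", paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(response ~ s + phi + eps, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  coef_df <- data.frame(term = c("(intercept)", "s", "phi", "eps"),
                        estimate = co[, 1], std_error = co[, 2],
                        t_ratio = co[, 3], p_value = co[, 4],
                        significant = co[, 4] < 0.01,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coef_df,
                 adjusted_r2 = sm$adj.r.squared,
                 n = nrow(df)),
            class = "nest_regression")
}

#' @export
print.nest_regression <- function(x, ...) {
  cat(sprintf("nest_regression on %d networks, adjusted R^2 = %.4f\n", x$n, x$adjusted_r2))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Metric-wise regression of z-scores on descriptors
#'
#' Applies [fit_multilinear()] to each metric column of a z-score table,
#' dropping undefined (NA) z-scores pairwise and reporting how many were
#' dropped.  Metrics with fewer than 6 usable networks are flagged
#' rather than fitted.
#'
#' @param zscores data.frame of per-network z-scores, one column per
#'   metric (an optional `network` id column is ignored).
#' @param descriptors data.frame with columns `size_s`,
#'   `links_per_node`, `eccentricity` (as from [network_descriptors()]),
#'   same row order as `zscores`.
#' @return named list, one entry per metric: either a
#'   `nest_regression` (with attribute `n_dropped`) or `NULL` when too
#'   few networks were usable.
#' @export
zscore_regression <- function(zscores, descriptors) {
  if (nrow(zscores) != nrow(descriptors))
    stop("z-score and descriptor tables must describe the same networks")
  need <- c("size_s", "links_per_node", "eccentricity")
  if (!all(need %in% names(descriptors)))
    stop("descriptors must contain: ", paste(need, collapse = ", "))
  cols <- setdiff(names(zscores), "network")
  out <- lapply(cols, function(nm) {
    z <- zscores[[nm]]
    keep <- !is.na(z) & stats::complete.cases(descriptors[need])
    if (sum(keep) < 6L) return(NULL)
    res <- fit_multilinear(z[keep], descriptors$size_s[keep],
                           descriptors$links_per_node[keep],
                           descriptors$eccentricity[keep])
    attr(res, "n_dropped") <- sum(!keep)
    res
  })
  names(out) <- cols
  out
}
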