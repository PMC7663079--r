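# Seeded generators replacing the external network dataset in all
# tests: canonical nested matrices, Bernoulli random matrices, and
# degree-preserving noisy-nested matrices spanning ranges of size,
# fill and eccentricity.

#' Perfectly nested synthetic network
#'
#' Delegates to [canonical_nested()]; provided under the generator
#' naming so fixture code reads uniformly.
#'
#' @inheritParams canonical_nested
#' @return a [bipartite_network()].
#' @export
gen_perfect_nested <- function(n, m, E) canonical_nested(n, m, E)

#' Bernoulli random bipartite network
#'
#' Every cell is an independent Bernoulli(`fill`) draw.
#'
#' @param n,m matrix dimensions.
#' @param fill link probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return a [bipartite_network()].
#' @export
gen_bernoulli <- function(n, m, fill, seed = 1L) {
  if (fill < 0 || fill > 1) stop("fill must lie in [0, 1]")
  B <- with_seed(seed, matrix((stats::runif(n * m) < fill) * 1L, n, m))
  bipartite_network(B)
}

#' Noisy nested network via random link relocation
#'
#' Starts from the canonical perfectly nested matrix and applies
#' `n_swaps` noise moves, each relocating one randomly chosen link to a
#' randomly chosen empty cell.  Size and fill (`n`, `m`, `E`) are
#' preserved exactly while nestedness degrades monotonically in
#' expectation, providing the nestedness gradient the dependency
#' analyses need.
#'
#' Exact degree-preserving noise cannot start from a perfectly nested
#' matrix: such a matrix contains no checkerboard submatrix and its
#' degree-sequence pair is the conjugate-partition extremal case with a
#' unique binary realization, so every degree-preserving move is the
#' identity.  Link relocation instead lets the degree sequences drift
#' away from extremality, as in noisy real webs; use
#' [checkerboard_swaps()] afterwards for randomization at *fixed*
#' degrees.
#'
#' @inheritParams canonical_nested
#' @param n_swaps number of link-relocation moves.
#' @param seed RNG seed.
#' @return a [bipartite_network()].
#' @export
gen_noisy_nested <- function(n, m, E, n_swaps, seed = 1L) {
  net <- canonical_nested(n, m, E)
  B <- net$matrix
  if (n_swaps > 0L && E > 0L && E < n * m) {
    B <- with_seed(seed, {
      for (k in seq_len(n_swaps)) {
        ones <- which(B == 1L); zeros <- which(B == 0L)
        B[ones[sample.int(length(ones), 1L)]] <- 0L
        B[zeros[sample.int(length(zeros), 1L)]] <- 1L
      }
      B
    })
  }
  bipartite_network(B)
}

#' Degree-preserving checkerboard randomization
#'
#' Attempts `n_swaps` random checkerboard swaps (a 2x2 submatrix
#' `[[1,0],[0,1]]` replaced by `[[0,1],[1,0]]` or vice versa), each of
#' which preserves both degree sequences exactly.  Attempts that do not
#' hit a checkerboard are skipped and counted.  Note that a perfectly
#' nested matrix admits no swap at all (its degree sequence has a
#' unique realization); meaningful randomization requires a
#' non-extremal input.
#'
#' @param net a [bipartite_network()].
#' @param n_swaps number of swap attempts.
#' @param seed RNG seed.
#' @return a [bipartite_network()] with attributes `n_swapped`,
#'   `n_failed`.
#' @export
checkerboard_swaps <- function(net, n_swaps, seed = 1L) {
  net <- as_binet(net)
  B <- net$matrix
  n <- nrow(B); m <- ncol(B)
  done <- 0L; failed <- 0L
  if (n >= 2L && m >= 2L && n_swaps > 0L) {
    B <- with_seed(seed, {
      for (k in seq_len(n_swaps)) {
        i <- sample.int(n, 2L); j <- sample.int(m, 2L)
        sub <- B[i, j]
        if (sub[1, 1] == sub[2, 2] && sub[1, 2] == sub[2, 1] && sub[1, 1] != sub[1, 2]) {
          B[i, j] <- 1L - sub
          done <- done + 1L
        } else failed <- failed + 1L
      }
      B
    })
  }
  out <- bipartite_network(B, row_labels = net$row_labels, col_labels = net$col_labels)
  attr(out, "n_swapped") <- done
  attr(out, "n_failed") <- failed
  out
}

#' Battery of synthetic networks spanning the descriptor space
#'
#' Generates a reproducible collection of noisy-nested networks crossing
#' sizes 20-200 nodes, matrix fills 0.05-0.5, eccentricities 0-0.6 and
#' three nestedness (swap) levels -- the spread of size, density and
#' shape the dependency analyses need, without any external download.
#' All networks have at least 20 nodes.
#'
#' @param seed master seed.
#' @param sizes,eccentricities,fills,swap_levels grid values; the
#'   defaults yield 108 networks.  `swap_levels` are multiples of `E`
#'   used as link-relocation moves (0 = perfectly nested, 0.2 =
#'   moderately degraded, 1 = close to random at fixed fill).
#' @return list with `networks` (named list of [bipartite_network()])
#'   and `descriptors` (data.frame: one row per network with the
#'   [network_descriptors()] columns plus `network`, `swap_level`).
#' @export
fixture_battery <- function(seed = 1L,
                            sizes = c(20L, 60L, 120L, 200L),
                            eccentricities = c(0, 0.3, 0.6),
                            fills = c(0.05, 0.25, 0.5),
                            swap_levels = c(0, 0.2, 1)) {
  grid <- expand.grid(s = sizes, ecc = eccentricities, fill = fills,
                      swaps = swap_levels)
  nets <- vector("list", nrow(grid))
  desc <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    s <- grid$s[k]
    n <- max(1L, round(s * (1 + grid$ecc[k]) / 2))
    m <- s - n
    E <- max(1L, min(n * m, round(grid$fill[k] * n * m)))
    net <- gen_noisy_nested(n, m, E, n_swaps = round(grid$swaps[k] * E),
                            seed = seed + 7L * k)
    nets[[k]] <- net
    d <- network_descriptors(net)
    d$network <- sprintf("net_s%d_e%02d_f%02d_w%03d", s,
                         round(100 * grid$ecc[k]), round(100 * grid$fill[k]),
                         round(100 * grid$swaps[k]))
    d$swap_level <- grid$swaps[k]
    desc[[k]] <- d
  }
  descriptors <- do.call(rbind, desc)
  names(nets) <- descriptors$network
  # guard against a degenerate grid in which descriptors confound each other
  for (pair in list(c("size_s", "links_per_node"),
                    c("size_s", "eccentricity"),
                    c("links_per_node", "eccentricity"))) {
    r <- spearman_rank(descriptors[[pair[1]]], descriptors[[pair[2]]])$rho
    if (abs(r) >= 1)
      stop("degenerate battery: ", pair[1], " and ", pair[2], " are perfectly confounded")
  }
  list(networks = nets, descriptors = descriptors)
}

#' Export a battery to a directory
#'
#' Writes each network as a dense CSV matrix plus a `descriptors.csv`
#' table, the on-disk layout the CLI batch verbs consume.
#'
#' @param battery a [fixture_battery()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_battery <- function(battery, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(battery$networks))
    write_matrix(battery$networks[[nm]], file.path(dir, paste0(nm, ".csv")))
  utils::write.csv(battery$descriptors, file.path(dir, "descriptors.csv"),
                   row.names = FALSE)
  invisible(dir)
}
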