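test_that("temperature vanishes exactly on perfectly nested matrices", {
  for (case in list(c(2, 2, 3), c(6, 8, 20), c(10, 10, 55), c(15, 5, 50))) {
    tp <- nest_temperature(canonical_nested(case[1], case[2], case[3]))
    expect_identical(tp$t_ap, 0)
    expect_identical(tp$t, 100)
  }
  expect_identical(nest_temperature(bipartite_network(matrix(1, 3, 4)))$t_ap, 0)
})

test_that("temperature scores misplaced cells by squared diagonal distance", {
  # checkerboard 2x2: two unexpected cells with u = 0.25 and 0.0625
  # (hand geometry: diagonals of length sqrt(2)/2 and sqrt(2), IPN
  # crossings at 0.25*sqrt(2) from each cell)
  tp <- nest_temperature(rbind(c(1, 0), c(0, 1)))
  expect_equal(tp$t_ap, 100 * 0.3125 / (0.04145 * 4), tolerance = 1e-12)
  expect_gt(tp$t_ap, 0)
  expect_error(nest_temperature(matrix(0, 2, 2)), class = "nest_undefined_error")
})

test_that("NMD worked cases match hand-computed unit-square distances", {
  v <- nest_nmd(canonical_nested(2, 2, 3))      # d = d_nest = 2.5, d_rand = 3
  expect_identical(v$tau, 0)
  expect_identical(v$nmd, 100)
  for (case in list(c(7, 7, 28), c(12, 30, 200)))
    expect_identical(nest_nmd(canonical_nested(case[1], case[2], case[3]))$tau, 0)
  # anti-nested checkerboard packs to the identity: d=2, d_nest=1.5, d_rand=2
  v <- nest_nmd(rbind(c(0, 1), c(1, 0)))
  expect_equal(v$tau, 1)
  expect_equal(v$nmd, 0)
  expect_error(nest_nmd(matrix(1, 2, 2)), class = "nest_undefined_error")
  expect_error(nest_nmd(matrix(0, 2, 2)), class = "nest_undefined_error")
})

test_that("the analytic d_rand equals the sampled uniform-null expectation", {
  # d_rand = E: mean unit-square Manhattan distance is 1 per link
  set.seed(7)
  n <- 9; m <- 13; E <- 30
  x <- (rep(1:m, each = n) - 0.5) / m
  y <- (rep(1:n, times = m) - 0.5) / n
  dist <- x + y
  draws <- replicate(4000, sum(dist[sample.int(n * m, E)]))
  expect_equal(mean(draws), E, tolerance = 4 * sd(draws) / sqrt(4000) / E)
})

test_that("NODF and stable-NODF match their worked 2x2 cases", {
  expect_equal(nest_nodf(rbind(c(1, 1), c(1, 0))), 100)
  expect_equal(nest_nodf(rbind(c(1, 1), c(1, 1))), 0)     # theta(0) = 1
  expect_equal(nest_nodf(matrix(0, 3, 3)), 0)
  expect_equal(nest_stable_nodf(rbind(c(1, 1), c(1, 1))), 100)
  expect_equal(nest_stable_nodf(rbind(c(1, 1), c(1, 0))), 100)
  expect_equal(nest_stable_nodf(rbind(c(1, 0), c(0, 1))), 0)
})

test_that("closed-form NODF agrees with the brute-force pairwise oracle", {
  for (s in 1:25) {
    net <- random_net(sample(4:12, 1), sample(4:12, 1), runif(1, 0.1, 0.9), seed = 400 + s)
    expect_equal(nest_nodf(net), oracle_nodf(net$matrix, FALSE), tolerance = 1e-12)
    expect_equal(nest_stable_nodf(net), oracle_nodf(net$matrix, TRUE), tolerance = 1e-12)
  }
})

test_that("discrepancy counts misplaced presences on the packed matrix", {
  expect_identical(nest_discrepancy(canonical_nested(9, 6, 30))$delta, 0L)
  expect_identical(nest_discrepancy(matrix(1, 3, 3))$delta, 0L)
  v <- nest_discrepancy(rbind(c(1, 0), c(0, 1)))
  expect_identical(v$delta, 1L)
  expect_equal(v$delta_prime, 50)
  expect_error(nest_discrepancy(matrix(0, 2, 2)), class = "nest_undefined_error")
})

test_that("attack tolerance curves match the 2x2 hand computation", {
  net <- canonical_nested(2, 2, 3)
  a <- attack_tolerance(net, "cols", "IDR")
  expect_equal(a$surviving_fraction, c(1, 1))
  expect_equal(a$area, 1)
  a <- attack_tolerance(net, "cols", "DDR")
  expect_equal(a$surviving_fraction, c(1, 0.5))
  expect_equal(a$area, 0.75)            # = phi for the nested matrix
  z <- attack_tolerance(bipartite_network(matrix(0, 3, 2)), "rows", "IDR")
  expect_equal(z$surviving_fraction, c(0, 0, 0))
  expect_equal(z$area, 0)
  # curves are non-increasing for any input/strategy
  for (s in 1:8) {
    net <- random_net(6, 9, 0.3, seed = 500 + s)
    for (st in c("IDR", "DDR"))
      expect_true(all(diff(attack_tolerance(net, "rows", st)$surviving_fraction) <= 1e-12))
  }
})

test_that("NIR is exactly 1 for nested matrices and lower for random ones", {
  expect_equal(nest_nir(canonical_nested(2, 2, 3)), 1)
  nested_val <- nest_nir(canonical_nested(50, 50, 500), n_orderings = 10, seed = 1)
  random_val <- nest_nir(gen_bernoulli(50, 50, 0.2, seed = 3), n_orderings = 10, seed = 1)
  expect_gt(nested_val, random_val + 0.2)
  # near-full matrix: finite, no division blow-up
  expect_true(is.finite(nest_nir(canonical_nested(3, 3, 8))))
  expect_error(nest_nir(matrix(1, 2, 2)), class = "nest_undefined_error")
  expect_error(nest_nir(matrix(0, 2, 2)), class = "nest_undefined_error")
})

test_that("spectral radius matches hand-solved eigenproblems and is order-invariant", {
  expect_equal(spectral_radius(rbind(c(1, 1), c(1, 0))), (1 + sqrt(5)) / 2)
  expect_equal(spectral_radius(matrix(1, 2, 2)), 2)
  expect_identical(spectral_radius(matrix(0, 3, 2)), 0)
  set.seed(11)
  for (s in 1:6) {
    net <- random_net(7, 9, 0.4, seed = 600 + s)
    perm <- net$matrix[sample(7), sample(9)]
    expect_equal(spectral_radius(net), spectral_radius(bipartite_network(perm)))
  }
})

test_that("normalized spectral radius is 100 on its own reference", {
  for (case in list(c(4, 4, 9), c(10, 10, 55), c(12, 30, 200)))
    expect_equal(nest_rho_norm(canonical_nested(case[1], case[2], case[3])), 100)
  expect_equal(nest_rho_norm(rbind(c(1, 0), c(0, 1))), 100 / sqrt(2))
  expect_error(nest_rho_norm(matrix(0, 2, 2)), class = "nest_undefined_error")
})

test_that("all bounded indices stay in [0, 100] on random networks", {
  for (s in 1:10) {
    net <- random_net(sample(4:12, 1), sample(4:12, 1), runif(1, 0.1, 0.85), seed = 700 + s)
    rep <- nestedness_report(net, nir_orderings = 10, seed = 1)
    tr <- rep$transformed[rep$defined & rep$metric != "spectral_radius"]
    expect_true(all(tr >= 0 & tr <= 100 + 1e-9))
    nir <- rep$raw[rep$metric == "nir"]
    if (!is.na(nir)) expect_lte(nir, 1 + 1 / min(dim(net$matrix)))
  }
})

test_that("metrics tolerate zero-degree rows and columns", {
  B <- rbind(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 0))
  rep <- nestedness_report(B, nir_orderings = 5, seed = 1)
  expect_true(all(rep$defined))
  expect_true(all(is.finite(rep$raw)))
})

test_that("nestedness degrades monotonically (in trend) with relocation noise", {
  sn <- function(moves) mean(vapply(1:12, function(s)
    nest_stable_nodf(gen_noisy_nested(20, 20, 250, moves, seed = s)), numeric(1)))
  rho <- function(moves) mean(vapply(1:12, function(s)
    spectral_radius(gen_noisy_nested(20, 20, 250, moves, seed = s)), numeric(1)))
  expect_gt(sn(5), sn(60))
  expect_gt(rho(5), rho(60))
})

test_that("the full report flags undefined metrics and round-trips to JSON", {
  net <- canonical_nested(15, 5, 50)
  rep <- nestedness_report(net, nir_orderings = 10, seed = 1)
  hundred <- rep$transformed[rep$metric %in%
    c("temperature", "nmd", "discrepancy", "stable_nodf", "rho_norm")]
  expect_equal(hundred, rep(100, 5))
  expect_equal(rep$raw[rep$metric == "nir"], 1, tolerance = 1 / 5)
  # empty network: NODF variants defined (0), the rest flagged
  empty <- nestedness_report(matrix(0, 3, 4), seed = 1)
  expect_identical(empty$transformed[empty$metric == "nodf"], 0)
  expect_false(any(empty$defined[!empty$metric %in% c("nodf", "stable_nodf", "spectral_radius")]))
  expect_true(all(nzchar(empty$note[!empty$defined])))
  # JSON round trip
  f <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$raw, rep$raw)
  expect_equal(back$metric, rep$metric)
})
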