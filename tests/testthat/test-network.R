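test_that("constructor enforces the binary-matrix invariants", {
  expect_error(bipartite_network(rbind(c(1, 2), c(0, 1))), "0 or 1")
  expect_error(bipartite_network(rbind(c(1, -1), c(0, 1))), "0 or 1")
  expect_error(bipartite_network(matrix(1, 2, 2), row_labels = c("a", "a")), "unique")
  expect_error(bipartite_network(matrix(numeric(0), 0, 0)), "at least one")
  net <- bipartite_network(rbind(c(1, 1), c(1, 0)))
  expect_s3_class(net, "bipartite_network")
  expect_identical(network_size(net), 3L)
})

test_that("degree sequences are the row/column sums and total E", {
  expect_identical(degree_sequences(rbind(c(1, 1), c(1, 0))),
                   list(rows = c(2L, 1L), cols = c(2L, 1L)))
  expect_identical(degree_sequences(matrix(0L, 2, 3)),
                   list(rows = c(0L, 0L), cols = c(0L, 0L, 0L)))
  for (s in 1:20) {
    net <- random_net(sample(2:15, 1), sample(2:15, 1), runif(1, 0.05, 0.9), seed = s)
    ds <- degree_sequences(net)
    expect_identical(sum(ds$rows), network_size(net))
    expect_identical(sum(ds$cols), network_size(net))
  }
})

test_that("descriptors match their definitions, including degeneracy", {
  d <- network_descriptors(canonical_nested(30, 10, 50))
  expect_equal(d$eccentricity, 0.5)
  expect_equal(d$size_s, 40)
  d2 <- network_descriptors(rbind(c(1, 1), c(1, 0)))
  expect_equal(d2$fill_matrix, 0.75)
  expect_equal(d2$links_per_node, 0.75)
  # row degrees (2,2,1), col degrees (3,1,1): 2 + 2 degree-sharing nodes
  B <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 0, 0))
  ds <- degree_sequences(B)
  expect_identical(ds$rows, c(2L, 2L, 1L))
  expect_identical(ds$cols, c(3L, 1L, 1L))
  # brute-force count under the within-guild convention
  count_shared <- function(d) sum(vapply(seq_along(d), function(i)
    sum(d == d[i]) > 1L, logical(1)))
  expect_equal(network_descriptors(B)$degeneracy_g,
               (count_shared(ds$rows) + count_shared(ds$cols)) / 6)
  expect_equal(network_descriptors(B)$degeneracy_g, 4 / 6)
})

test_that("eccentricity, size and degeneracy are transpose-invariant", {
  for (s in 1:10) {
    net <- random_net(sample(2:12, 1), sample(2:12, 1), runif(1, 0.1, 0.8), seed = 100 + s)
    d1 <- network_descriptors(net)
    d2 <- network_descriptors(t(net$matrix))
    expect_equal(d1$eccentricity, d2$eccentricity)
    expect_equal(d1$size_s, d2$size_s)
    expect_equal(d1$degeneracy_g, d2$degeneracy_g)
  }
})

test_that("dense matrix reader parses plain, weighted and labeled files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,1", "1,0"), f)
  net <- read_matrix(f)
  expect_identical(network_size(net), 3L)
  expect_identical(degree_sequences(net), list(rows = c(2L, 1L), cols = c(2L, 1L)))

  writeLines(c("0,3.5", "2,0"), f)
  net <- read_matrix(f)
  expect_identical(net$matrix, rbind(c(0L, 1L), c(1L, 0L)))

  writeLines(c(",bee,fly", "rose,0,3.5", "iris,2,0"), f)
  lab <- read_matrix(f)
  expect_identical(lab$matrix, rbind(c(0L, 1L), c(1L, 0L)))
  expect_identical(lab$row_labels, c("rose", "iris"))
  expect_identical(lab$col_labels, c("bee", "fly"))
})

test_that("dense matrix reader rejects malformed and negative input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,1", "1"), f)
  expect_error(read_matrix(f), "line 2")
  writeLines(c("1,1", "0,x"), f)
  expect_error(read_matrix(f), "line 2")
  writeLines(c("1,x", "1,0"), f)
  expect_error(read_matrix(f, header = FALSE, row_labels = FALSE), "line 1")
  writeLines(c("1,-2", "1,0"), f)
  expect_error(read_matrix(f), "negative")
})

test_that("matrix write/read round-trips bit-exactly, labels included", {
  f <- withr::local_tempfile(fileext = ".csv")
  for (s in 1:12) {
    net <- random_net(sample(1:10, 1), sample(1:10, 1), runif(1, 0.1, 0.9), seed = 200 + s)
    write_matrix(net, f)
    expect_identical(read_matrix(f), net)
  }
  # non-ASCII labels survive
  net <- bipartite_network(rbind(c(1, 0), c(1, 1)),
                           row_labels = c("plaça", "érable"),
                           col_labels = c("abeiña", "b"))
  write_matrix(net, f)
  expect_identical(read_matrix(f), net)
  # 1x1 default-labeled matrix writes a bare "1"
  write_matrix(bipartite_network(matrix(1, 1, 1)), f)
  expect_identical(readLines(f), "1")
})

test_that("edge lists build networks in first-appearance order", {
  f <- withr::local_tempfile(fileext = ".edges")
  writeLines(c("P1\tA1", "P1\tA2", "P2\tA1"), f)
  net <- read_edgelist(f)
  expect_identical(net$matrix, rbind(c(1L, 1L), c(1L, 0L)))
  expect_identical(net$row_labels, c("P1", "P2"))
  # duplicates collapse
  writeLines(c("P1\tA1", "P1\tA2", "P2\tA1", "P1\tA2"), f)
  expect_identical(network_size(read_edgelist(f)), 3L)
  # ambiguity and empty files are errors
  writeLines(c("P1\tA1", "A1\tA2"), f)
  expect_error(read_edgelist(f), "ambiguity")
  writeLines(character(0), f)
  expect_error(read_edgelist(f), "empty")
})
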