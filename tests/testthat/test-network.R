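test_that("edge lists are deduplicated, undirected, and self-loop free", {
  net <- load_edge_list(c("a\tb", "b\ta", "a\tb"))
  expect_equal(nrow(net$edges), 1)
  expect_warning(net2 <- ppi_network(rbind(c("a", "a"), c("a", "b"))),
                 "self-loop")
  expect_equal(nrow(net2$edges), 1)
  tri <- load_edge_list(c("a b", "b c", "a c"))
  expect_equal(length(tri$proteins), 3)
  expect_equal(nrow(tri$edges), 3)
  expect_error(load_edge_list(c("a b", "c")), "line 2")
})

test_that("node lists preserve isolated proteins and writing is bit-stable", {
  net <- load_edge_list(c("b\ta"), node_list = c("z"))
  expect_setequal(net$proteins, c("a", "b", "z"))
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_edge_list(net, p1)
  write_edge_list(load_edge_list(p1, node_list = "z"), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(readLines(p1), "a\tb")   # lexicographic pair order
})

test_that("network statistics report m, pendant proteins and mean degree", {
  path3 <- load_edge_list(c("a b", "b c"))
  s <- network_stats(path3)
  expect_equal(s$m, 2)
  expect_equal(s$degree_one_count, 2)
  expect_equal(s$avg_degree, 4 / 3)
})

test_that("partition degrees split a protein's interactions exactly", {
  tri <- load_edge_list(c("a b", "b c", "a c"))
  whole <- clustering_from_membership(c(1, 1, 1), tri$proteins)
  expect_equal(partition_degrees(tri, "a", whole), c(intra = 2, inter = 0))
  singles <- clustering_from_membership(1:3, tri$proteins)
  expect_equal(partition_degrees(tri, "a", singles), c(intra = 0, inter = 2))
  split <- clustering_from_membership(c(1, 1, 2), tri$proteins)
  expect_equal(partition_degrees(tri, "a", split), c(intra = 1, inter = 1))
})

test_that("intra and inter degrees sum to the degree for any clustering", {
  set.seed(21)
  b <- generate_planted(planted_spec(sizes = c(4, 4, 4), seed = 3))
  net <- b$network
  deg <- igraph::degree(as_igraph(net))
  for (rep in 1:3) {
    memb <- sample(1:4, length(net$proteins), replace = TRUE)
    cl <- clustering_from_membership(memb, net$proteins)
    for (p in net$proteins) {
      pd <- partition_degrees(net, p, cl)
      expect_equal(unname(sum(pd)), unname(deg[p]))
    }
  }
})

test_that("perturbation alters exactly round(p*m) edges in the right direction", {
  set.seed(1)
  b <- generate_planted(planted_spec(sizes = c(6, 6), p_in = 0.8,
                                     p_out = 0.1, seed = 5))
  net <- b$network
  m <- nrow(net$edges)
  key <- function(e) paste(e[, 1], e[, 2])

  zero <- perturb(net, noise_spec("add", "random", 0, seed = 1))
  expect_identical(zero$edges, net$edges)

  for (targ in c("random", "high_degree", "low_degree")) {
    added <- perturb(net, noise_spec("add", targ, 0.3, seed = 2))
    expect_equal(nrow(added$edges), m + round(0.3 * m))
    expect_true(all(key(net$edges) %in% key(added$edges)))   # superset

    deleted <- perturb(net, noise_spec("delete", targ, 0.3, seed = 2))
    expect_equal(nrow(deleted$edges), m - round(0.3 * m))
    expect_true(all(key(deleted$edges) %in% key(net$edges))) # subset
    expect_setequal(deleted$proteins, net$proteins)          # n constant
  }

  half <- perturb(net, noise_spec("delete", "random", 0.5, seed = 7))
  expect_equal(nrow(half$edges), m - round(0.5 * m))
})

test_that("perturbation is deterministic in the seed", {
  net <- load_edge_list(c("a b", "b c", "c d", "d e", "a e", "b d"))
  s <- noise_spec("add", "high_degree", 0.5, seed = 42)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_edge_list(perturb(net, s), p1)
  write_edge_list(perturb(net, s), p2)
  expect_identical(readLines(p1), readLines(p2))
  different <- perturb(net, noise_spec("add", "high_degree", 0.5, seed = 43))
  expect_equal(nrow(different$edges), nrow(net$edges) + 3)
})

test_that("degree-targeted perturbation anchors at extreme-degree proteins", {
  # star plus pendant chain: 'hub' has max degree, 'tail' has degree 1
  net <- load_edge_list(c("hub a", "hub b", "hub c", "hub d", "c tail"))
  grown <- perturb(net, noise_spec("add", "high_degree", 0.2, seed = 1))
  new_edge <- setdiff(paste(grown$edges[, 1], grown$edges[, 2]),
                      paste(net$edges[, 1], net$edges[, 2]))
  expect_true(grepl("hub", new_edge))

  shrunk <- perturb(net, noise_spec("delete", "low_degree", 0.2, seed = 1))
  gone <- setdiff(paste(net$edges[, 1], net$edges[, 2]),
                  paste(shrunk$edges[, 1], shrunk$edges[, 2]))
  # the only degree-1 proteins are a, b, d (pendants of hub) and tail
  expect_true(grepl("a|b|d|tail", gone))

  expect_error(perturb(load_edge_list(c("a b", "b c", "a c")),
                       noise_spec("add", "random", 0.5, seed = 1)),
               "complete")
  expect_error(noise_spec("delete", "random", 1.5))
})

test_that("replicate perturbations derive their seeds from the base seed", {
  net <- load_edge_list(c("a b", "b c", "c d", "d e", "a e", "b d"))
  reps <- perturb_replicates(net, noise_spec("delete", "random", 0.5,
                                             replicates = 3, seed = 10))
  expect_length(reps, 3)
  direct <- perturb(net, noise_spec("delete", "random", 0.5, seed = 11))
  expect_identical(reps[[2]]$edges, direct$edges)
})

test_that("average degree identity 2m/n survives perturbation", {
  set.seed(2)
  b <- generate_planted(planted_spec(sizes = c(5, 5), seed = 8))
  for (mode in c("add", "delete")) {
    out <- perturb(b$network, noise_spec(mode, "random", 0.2, seed = 3))
    s <- network_stats(out)
    expect_identical(s$avg_degree, 2 * s$m / length(out$proteins))
  }
})
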