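test_that("random chromosomes are feasible and forced where degree is 1", {
  path <- load_edge_list(c("a b"))
  set.seed(1)
  ch <- random_chromosome(path)
  expect_equal(as.integer(ch), c(2L, 1L))   # only neighbours available
  expect_equal(decode(ch, path)$K, 1)

  iso <- ppi_network(rbind(c("a", "b")), proteins = "z")
  set.seed(1)
  ch <- random_chromosome(iso)
  expect_equal(as.integer(ch)[3], 3L)       # self-sentinel on the isolate
  cl <- decode(ch, iso)
  expect_equal(cl$K, 2)
  expect_true(any(lengths(cl$complexes) == 1))
})

test_that("any triangle chromosome decodes to a single complex", {
  tri <- load_edge_list(c("a b", "b c", "a c"))
  nbr <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  combos <- expand.grid(nbr[[1]], nbr[[2]], nbr[[3]])
  for (r in seq_len(nrow(combos))) {
    ch <- structure(as.integer(combos[r, ]), class = "chromosome")
    expect_equal(decode(ch, tri)$K, 1)
  }
})

test_that("decoding yields the components of the locus-allele graph", {
  net <- load_edge_list(c("p1 p2", "p2 p3", "p4 p5", "p5 p6"))
  ch <- structure(c(2L, 1L, 2L, 5L, 4L, 5L), class = "chromosome")
  cl <- decode(ch, net)
  expect_equal(cl$K, 2)
  expect_equal(cl$complexes[[1]], 1:3)
  expect_equal(cl$complexes[[2]], 4:6)
  expect_error(decode(structure(c(3L, 1L, 2L, 5L, 4L, 5L),
                                class = "chromosome"), net),
               "infeasible")
})

test_that("decoded clusterings are partitions for random chromosomes", {
  set.seed(33)
  b <- generate_planted(planted_spec(sizes = c(5, 5, 5), seed = 2))
  for (rep in 1:20) {
    ch <- random_chromosome(b$network)
    cl <- decode(ch, b$network)
    members <- sort(unlist(cl$complexes))
    expect_equal(members, seq_along(b$network$proteins))  # disjoint + covering
    expect_equal(max(cl$membership), cl$K)
  }
})

test_that("uniform crossover mixes parent genes and respects pc", {
  net <- two_triangle_network()
  set.seed(4)
  p1 <- random_chromosome(net)
  p2 <- random_chromosome(net)

  same <- uniform_crossover(p1, p1, pc = 1)
  expect_equal(as.integer(same), as.integer(p1))

  off <- uniform_crossover(p1, p2, pc = 0)   # no crossover: copy of parent 1
  expect_equal(as.integer(off), as.integer(p1))

  for (rep in 1:100) {
    child <- uniform_crossover(p1, p2, pc = 1)
    expect_true(all(child == as.integer(p1) | child == as.integer(p2)))
  }
  expect_error(uniform_crossover(p1, structure(1:3, class = "chromosome")),
               "different networks")
})

test_that("FS-PTO leaves chromosomes without weak proteins untouched", {
  net <- two_triangle_network()
  fsm <- block_fsm(c(1, 1, 1, 2, 2, 2))
  ch <- structure(c(2L, 3L, 1L, 5L, 6L, 4L), class = "chromosome")
  set.seed(5)
  out <- fs_pto(ch, net, fsm, pm = 1)
  expect_equal(as.integer(out), as.integer(ch))
  expect_equal(nrow(attr(out, "moves")), 0)
})

test_that("FS-PTO translocates a weak protein to its best-matching complex", {
  # p1 currently with p2 (intra 0.4) but closer to {p3, p4} (inter 0.7)
  net <- ppi_network(rbind(c("p1", "p2"), c("p3", "p4"), c("p1", "p3")))
  fsm <- matrix(c(1, 0.4, 0.3, 0.4,
                  0.4, 1, 0.1, 0.1,
                  0.3, 0.1, 1, 0.9,
                  0.4, 0.1, 0.9, 1), 4, 4,
                dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  ch <- structure(c(2L, 1L, 4L, 3L), class = "chromosome")
  set.seed(6)
  out <- fs_pto(ch, net, fsm, pm = 1)
  moves <- attr(out, "moves")
  expect_equal(moves$protein[1], 1)
  expect_equal(moves$f_intra[1], 0.4)
  expect_equal(moves$f_inter[1], 0.7)
  expect_equal(as.integer(out)[1], 3L)        # re-pointed into the target
  cl <- decode(out, net)
  expect_equal(cl$membership[1], cl$membership[3])

  set.seed(6)
  frozen <- fs_pto(ch, net, fsm, pm = 0)      # gate closed: no moves
  expect_equal(nrow(attr(frozen, "moves")), 0)
})

test_that("FS-PTO restores a planted two-block partition in one pass", {
  net <- ppi_network(rbind(
    c("p1", "p2"), c("p1", "p3"), c("p2", "p3"),
    c("p4", "p5"), c("p4", "p6"), c("p5", "p6"), c("p3", "p4")))
  fsm <- block_fsm(c(1, 1, 1, 2, 2, 2))
  # p4 mis-assigned into the first block via the bridge allele
  ch <- structure(c(2L, 3L, 1L, 3L, 6L, 5L), class = "chromosome")
  expect_equal(decode(ch, net)$K, 2)
  expect_equal(decode(ch, net)$membership[4], 1L)
  set.seed(7)
  out <- fs_pto(ch, net, fsm, pm = 1)
  cl <- decode(out, net)
  expect_equal(cl$membership, c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("FS-PTO moves are gated by the per-protein random draw", {
  net <- ppi_network(rbind(c("p1", "p2"), c("p3", "p4"), c("p1", "p3")))
  fsm <- matrix(c(1, 0.1, 0.9, 0.9,
                  0.1, 1, 0.1, 0.1,
                  0.9, 0.1, 1, 0.9,
                  0.9, 0.1, 0.9, 1), 4, 4,
                dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  ch <- structure(c(2L, 1L, 4L, 3L), class = "chromosome")
  moved <- 0L
  for (seed in 1:200) {
    set.seed(seed)
    out <- fs_pto(ch, net, fsm, pm = 0.2)
    moved <- moved + (nrow(attr(out, "moves")) > 0)
  }
  expect_gt(moved, 20)    # pm = 0.2 admits some moves
  expect_lt(moved, 190)   # ... but far from every pass
})

test_that("accepted FS-PTO moves always improve the protein's fit", {
  set.seed(44)
  b <- generate_planted(planted_spec(sizes = c(6, 6, 6), seed = 4))
  fsm <- build_fs_matrix(b$network$proteins, b$annotations, b$ontology)
  nbrs <- lapply(seq_along(b$network$proteins), function(i)
    which(as.matrix(b$network)[i, ] == 1))
  for (rep in 1:10) {
    ch <- random_chromosome(b$network)
    out <- fs_pto(ch, b$network, fsm, pm = 1)
    moves <- attr(out, "moves")
    if (nrow(moves)) expect_true(all(moves$f_inter > moves$f_intra))
    # feasibility closed under the operator
    for (i in seq_along(out))
      expect_true(out[i] == i || out[i] %in% nbrs[[i]])
  }
})
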