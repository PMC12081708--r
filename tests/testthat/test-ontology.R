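test_that("OBO parsing maps stanzas, relations and alt_ids correctly", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "",
    "[Term]", "id: GO:0000002", "alt_id: GO:0000099",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003",
    "relationship: part_of GO:0000002", "",
    "[Term]", "id: GO:0000004",
    "relationship: positively_regulates GO:0000099", "",
    "[Term]", "id: GO:0000005", "is_a: GO:0000001", "is_obsolete: true", "")
  g <- load_ontology(obo)
  expect_setequal(g$terms,
                  c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"))
  expect_equal(g$roots, "GO:0000001")
  rel <- g$relations
  expect_equal(rel$relation[rel$child == "GO:0000003"], "part_of")
  # regulates variant collapsed, alt_id remapped to the canonical term
  r4 <- rel[rel$child == "GO:0000004", ]
  expect_equal(r4$relation, "regulates")
  expect_equal(r4$parent, "GO:0000002")
})

test_that("minimal two-term ontology loads with one is_a edge", {
  g <- load_ontology(c("[Term]", "id: B", "is_a: A", "", "[Term]", "id: A"))
  expect_length(g$terms, 2)
  expect_equal(nrow(g$relations), 1)
  expect_equal(g$relations$relation, "is_a")
  expect_equal(g$roots, "A")
})

test_that("unsupported relationship kinds are dropped with a message", {
  obo <- c("[Term]", "id: A", "",
           "[Term]", "id: B", "is_a: A",
           "relationship: has_part A", "")
  expect_message(g <- load_ontology(obo), "ignored 1")
  expect_equal(nrow(g$relations), 1)
})

test_that("malformed stanzas and cyclic relations are rejected", {
  expect_error(load_ontology(c("[Term]", "id: A", "nonsense line", "")),
               "malformed OBO line 3")
  expect_error(load_ontology(c("[Term]", "id: A", "is_a: B", "",
                               "[Term]", "id: B", "is_a: A", "")),
               "cycle")
  expect_error(ontology_graph(data.frame(child = "A", parent = "B",
                                         relation = "develops_from")),
               "unsupported relation")
})

test_that("TSV ontologies load through the simplified reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("B\tis_a\tA", "C\tpart_of\tB"), path)
  g <- load_ontology_tsv(path)
  expect_setequal(g$terms, c("A", "B", "C"))
  expect_equal(g$roots, "A")
})

test_that("ancestor DAG extraction gives the reachable closure", {
  g <- ontology_graph(data.frame(
    child = c("A", "P", "A", "P2", "X"),
    parent = c("P", "R", "P2", "R", "R"),
    relation = "is_a"))
  root_dag <- ancestor_dag(g, "R")
  expect_equal(root_dag$members, "R")
  expect_equal(nrow(root_dag$edges), 0)

  chain <- ancestor_dag(g, "A")
  expect_setequal(chain$members, c("A", "P", "P2", "R"))
  expect_equal(nrow(chain$edges), 4)   # diamond: 2 up, 2 to root
  expect_false("X" %in% chain$members) # unrelated branch excluded

  expect_error(ancestor_dag(g, "nope"), "unknown term")
})

test_that("semantic contribution follows the max-product rule with root at 0", {
  chain <- ontology_graph(data.frame(child = c("A", "P"), parent = c("P", "R"),
                                     relation = "is_a"))
  s <- semantic_contribution(ancestor_dag(chain, "A"))
  expect_equal(s[c("A", "P", "R")], c(A = 1, P = 0.8, R = 0))
  expect_equal(semantic_value(ancestor_dag(chain, "A")), 1.8)

  # focus-is-root: the focus clause wins over the root clause
  expect_equal(unname(semantic_contribution(ancestor_dag(chain, "R"))), 1)
  expect_equal(semantic_value(ancestor_dag(chain, "R")), 1)

  diamond <- ontology_graph(data.frame(
    child = c("A", "A", "P1", "P2"), parent = c("P1", "P2", "R", "R"),
    relation = c("is_a", "part_of", "is_a", "is_a")))
  s <- semantic_contribution(ancestor_dag(diamond, "A"))
  expect_equal(s[c("A", "P1", "P2", "R")], c(A = 1, P1 = 0.8, P2 = 0.6, R = 0))
  expect_equal(semantic_value(ancestor_dag(diamond, "A")), 2.4)
})

test_that("semantic contribution matches exhaustive path enumeration", {
  for (seed in 1:6) {
    g <- random_ontology(sample(5:12, 1), seed = seed)
    focus <- sample(g$terms[-1], 1)   # T01 is the root
    dag <- ancestor_dag(g, focus)
    got <- semantic_contribution(dag)
    want <- oracle_contribution(g, focus)
    expect_setequal(names(got), names(want))
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("term similarity reproduces hand-computed toys", {
  sib <- ontology_graph(data.frame(
    child = c("A", "B", "P"), parent = c("P", "P", "R"), relation = "is_a"))
  dA <- ancestor_dag(sib, "A")
  dB <- ancestor_dag(sib, "B")
  expect_equal(term_similarity(dA, dA), 1)
  expect_equal(term_similarity(dA, dB), 4 / 9)
  expect_equal(term_similarity(dB, dA), 4 / 9)

  # disjoint ancestor sets (different aspects) score 0
  two <- ontology_graph(data.frame(
    child = c("A", "B"), parent = c("RA", "RB"), relation = "is_a"))
  expect_equal(term_similarity(ancestor_dag(two, "A"),
                               ancestor_dag(two, "B")), 0)
})

test_that("similarity is symmetric, bounded, and 1 on the diagonal", {
  for (seed in 7:9) {
    g <- random_ontology(10, seed = seed)
    ss <- ss_source(g)
    for (a in g$terms) expect_equal(ss(a, a), 1)
    pairs <- utils::combn(g$terms, 2)
    for (c in seq_len(ncol(pairs))) {
      v1 <- ss(pairs[1, c], pairs[2, c])
      v2 <- ss(pairs[2, c], pairs[1, c])
      expect_identical(v1, v2)
      expect_gte(v1, 0)
      expect_lte(v1, 1)
    }
  }
})

test_that("a shared ancestor with positive contribution raises similarity", {
  shallow <- ontology_graph(data.frame(
    child = c("A", "B"), parent = c("R", "R"), relation = "is_a"))
  deep <- ontology_graph(data.frame(
    child = c("A", "B", "P"), parent = c("P", "P", "R"), relation = "is_a"))
  before <- term_similarity(ancestor_dag(shallow, "A"),
                            ancestor_dag(shallow, "B"))
  after <- term_similarity(ancestor_dag(deep, "A"),
                           ancestor_dag(deep, "B"))
  expect_gte(after, before)
})

test_that("similarity tables round numbers to six decimals on disk", {
  g <- random_ontology(6, seed = 3)
  tab <- term_similarity_table(g)
  expect_equal(nrow(tab), choose(6, 2) + 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ss_table(tab, path)
  back <- utils::read.delim(path)
  expect_equal(back$SS, round(tab$SS, 6), tolerance = 1e-9)
})
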