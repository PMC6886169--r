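make_links <- function(a, b, s) gene_link_set(a, b, s, "gene")

test_that("gene-to-set relevance hits its membership, max and empty branches", {
  net <- make_links(c("g1", "g1"), c("g2", "g3"), c(0.8, 0.6))
  expect_equal(gene_set_relevance("g2", c("g2", "g3"), net), 1)
  expect_equal(gene_set_relevance("g9", c("g2", "g3"), net), 0)
  expect_equal(gene_set_relevance("g1", c("g2", "g3"), net), 0.8)
  expect_equal(gene_set_relevance("g1", c("g2", "g3"), net,
                                  relevance = "mean"), 0.7)
})

test_that("disease functional similarity matches hand and oracle values", {
  net <- make_links("g1", "g2", 0.5)
  expect_equal(fnsim(c("g1"), c("g2"), net), 0.5)
  expect_equal(fnsim(c("g1", "g2"), c("g1", "g2"), net), 1)
  empty <- make_links(character(0), character(0), numeric(0))
  expect_equal(fnsim("g1", "g9", empty), 0)
  expect_warning(v <- fnsim(character(0), "g1", net), "empty")
  expect_equal(v, 0)
})

test_that("fnsim is symmetric, bounded, and agrees with the brute-force oracle", {
  set.seed(71)
  genes <- sprintf("g%02d", 1:12)
  for (rep in 1:200) {
    ne <- sample(0:10, 1)
    a <- sample(genes, ne, replace = TRUE)
    b <- sample(genes, ne, replace = TRUE)
    keep <- a != b
    edf <- data.frame(a = pmin(a[keep], b[keep]), b = pmax(a[keep], b[keep]),
                      score = round(stats::runif(sum(keep)), 3))
    edf <- edf[!duplicated(edf[, 1:2]), , drop = FALSE]
    net <- link_df_to_set(edf)
    Ga <- sample(genes, sample(1:5, 1))
    Gb <- sample(genes, sample(1:5, 1))
    v1 <- fnsim(Ga, Gb, net)
    expect_equal(v1, fnsim(Gb, Ga, net), tolerance = 1e-15)
    expect_true(v1 >= 0 && v1 <= 1)
    expect_equal(v1, oracle_fnsim(Ga, Gb, edf), tolerance = 1e-12)
    expect_equal(fnsim(Ga, Ga, net), 1)
  }
})

diamond_onto <- function() {
  # d1, d2 share two ancestors: B (small gene set, high IC) and A (root)
  onto <- disease_ontology(c("A", "B", "C", "d1", "d2", "d3"),
                           children = c("B", "C", "d1", "d2", "d1", "d3"),
                           parents = c("A", "A", "B", "B", "C", "C"))
  dg <- association_table(c("d1", "d1", "d2", "d2", "d3", "d3", "d3"),
                          c("g1", "g2", "g2", "g3", "g4", "g5", "g6"),
                          left_ns = "disease", right_ns = "gene")
  propagate_annotations(onto, dg)
}

test_that("MICA picks the highest-IC common ancestor deterministically", {
  onto <- diamond_onto()
  expect_equal(mica("d1", "d1", onto), "d1")
  # d1 and d2: ancestors {B, A, (C for d1)}; B has 3 propagated genes,
  # A has 6 -> B wins on IC (brute-force check below)
  ic <- term_ic(onto)
  common <- intersect(term_ancestors(onto, "d1"), term_ancestors(onto, "d2"))
  brute <- common[order(-ic[common], common)][1]
  expect_equal(mica("d1", "d2", onto), brute)
  expect_equal(mica("d1", "d2", onto), "B")
  # siblings under a sole root
  expect_equal(mica("B", "C", onto), "A")
  # IC is antitone in propagated size; IC(root) = 0
  sizes <- lengths(onto$propagated)
  fin <- is.finite(ic)
  expect_true(all(diff(ic[fin][order(sizes[fin])]) <= 1e-12))
  expect_equal(unname(ic["A"]), 0)
  # disjoint forest -> no MICA
  forest <- disease_ontology(c("X", "Y"))
  dgf <- association_table(c("X", "Y"), c("g1", "g2"),
                           left_ns = "disease", right_ns = "gene")
  forest <- propagate_annotations(forest, dgf)
  expect_true(is.na(mica("X", "Y", forest)))
})

test_that("semantic correction multiplies by the MICA gene-set ratio", {
  onto <- diamond_onto()
  gs <- disease_gene_sets(association_table(
    c("d1", "d1", "d2", "d2"), c("g1", "g2", "g2", "g3"),
    left_ns = "disease", right_ns = "gene"))
  net <- make_links("g1", "g3", 0.5)
  base <- fnsim(gs[["d1"]], gs[["d2"]], net)
  # |G_MICA(B)| = 3 propagated genes
  expect_equal(fnsemsim("d1", "d2", gs, net, onto), base * (2 * 2) / 9)
  # self-similarity where Ga = G_MICA: ratio collapses to 1
  onto_self <- disease_ontology("solo")
  dg_self <- association_table(c("solo", "solo"), c("g1", "g2"),
                               left_ns = "disease", right_ns = "gene")
  onto_self <- propagate_annotations(onto_self, dg_self)
  gs_self <- disease_gene_sets(dg_self)
  expect_equal(fnsemsim("solo", "solo", gs_self, net, onto_self),
               fnsim(gs_self[["solo"]], gs_self[["solo"]], net))
  # fnsim = 0 forces 0 regardless of sizes
  gs0 <- list(d1 = "g1", d2 = "g3")
  empty <- make_links(character(0), character(0), numeric(0))
  expect_equal(fnsemsim("d1", "d2", gs0, empty, onto), 0)
})

test_that("min-max normalization maps endpoints and preserves order", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m[upper.tri(m)] <- c(0.2, 0.5, 0.8)
  m <- m + t(m)
  nm <- minmax_normalize(m)
  expect_equal(sort(nm[upper.tri(nm)]), c(0, 0.5, 1))
  expect_equal(diag(nm), c(a = 1, b = 1, c = 1))
  expect_equal(nm, t(nm), ignore_attr = TRUE)

  m2 <- matrix(0, 4, 4)
  m2[upper.tri(m2)] <- c(1, 3, 5, 9, 2, 7)
  m2 <- m2 + t(m2)
  dimnames(m2) <- list(letters[1:4], letters[1:4])
  nm2 <- minmax_normalize(m2)
  expect_equal(sort(unique(nm2[upper.tri(nm2)])),
               (sort(unique(m2[upper.tri(m2)])) - 1) / 8)
  expect_equal(order(nm2[upper.tri(nm2)]), order(m2[upper.tri(m2)]))

  const <- matrix(0.4, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(nc <- minmax_normalize(const), "equal")
  expect_equal(nc["a", "b"], 0)
  expect_equal(diag(nc), c(a = 1, b = 1))
})

test_that("diseases without gene annotations are similar only to themselves", {
  onto <- diamond_onto()
  dg <- association_table(c("d1", "d1", "d2", "d2"),
                          c("g1", "g2", "g2", "g3"),
                          left_ns = "disease", right_ns = "gene")
  net <- make_links("g1", "g3", 0.5)
  m <- disease_similarity(c("d1", "d2", "d3"), dg, net, onto)
  expect_equal(m["d3", "d1"], 0)
  expect_equal(m["d3", "d2"], 0)
  expect_equal(m["d3", "d3"], 1)
  expect_true(all(m >= 0 & m <= 1))
})
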