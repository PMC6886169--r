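test_that("cosine similarity matches hand values and degenerate branches", {
  expect_equal(cosine_cr(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_equal(cosine_cr(c(0.3, 0.7), c(0.3, 0.7)), 1)
  expect_equal(cosine_cr(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_cr(c(0, 0), c(1, 1)), 0)
  expect_error(cosine_cr(c(1, 0), c(1, 0, 0)), "different spaces")
})

test_that("cosine similarity is scale-invariant in either argument", {
  set.seed(9)
  for (i in 1:50) {
    v1 <- stats::runif(6); v2 <- stats::runif(6)
    s <- stats::runif(1, 0.1, 10)
    expect_equal(cosine_cr(v1, v2), cosine_cr(s * v1, v2), tolerance = 1e-12)
    expect_equal(cosine_cr(v1, v2), cosine_cr(v1, s * v2), tolerance = 1e-12)
  }
})

test_that("mRNA relevance counts links into the set", {
  links <- gene_link_set(c("k", "k"), c("m1", "m2"), c(1, 1), "mrna")
  M <- c("m1", "m2", "m3", "m4")
  expect_equal(mrna_relevance("m1", M, links), 1)
  expect_equal(mrna_relevance("k", M, links), 0.5)
  empty <- gene_link_set(character(0), character(0), numeric(0), "mrna")
  expect_equal(mrna_relevance("k", M, empty), 0)
})

test_that("mRNA-based similarity matches the hand-evaluated example", {
  # M1 = {a}, M2 = {b, c}, single link (a, b):
  # R(b, M1) = 1, R(c, M1) = 0, R(a, M2) = 1/2 -> (1 + 0 + 0.5) / 3 = 0.5
  links <- gene_link_set("a", "b", 1, "mrna")
  expect_equal(mrna_mr("a", c("b", "c"), links), 0.5)
  expect_equal(mrna_mr(c("x", "y"), c("x", "y"), links), 1)
  empty <- gene_link_set(character(0), character(0), numeric(0), "mrna")
  expect_equal(mrna_mr("a", "b", empty), 0)
  expect_warning(v <- mrna_mr(character(0), character(0), links), "empty")
  expect_equal(v, 0)
})

test_that("mRNA similarity is symmetric and agrees with the oracle", {
  set.seed(31)
  mrnas <- sprintf("M%02d", 1:10)
  for (i in 1:100) {
    M1 <- sample(mrnas, sample(0:5, 1))
    M2 <- sample(mrnas, sample(1:5, 1))
    ne <- sample(1:12, 1)
    a <- sample(mrnas, ne, replace = TRUE)
    b <- sample(mrnas, ne, replace = TRUE)
    keep <- a != b
    edf <- data.frame(a = pmin(a[keep], b[keep]), b = pmax(a[keep], b[keep]),
                      score = rep(1, sum(keep)))
    edf <- edf[!duplicated(edf[, 1:2]), , drop = FALSE]
    links <- link_df_to_set(edf, "mrna")
    v <- mrna_mr(M1, M2, links)
    expect_equal(v, mrna_mr(M2, M1, links), tolerance = 1e-15)
    expect_equal(v, oracle_mr(M1, M2, edf), tolerance = 1e-12)
    expect_true(v >= 0 && v <= 1)
    if (length(M1)) expect_equal(mrna_mr(M1, M1, links), 1)
  }
})

test_that("expression similarity is Spearman rho mapped into [0,1]", {
  expect_equal(expression_er(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(expression_er(c(1, 2, 3), c(10, 200, 3000)), 1)
  expect_equal(expression_er(c(1, 2, 3), c(3, 2, 1)), 0)  # clamped
  expect_equal(expression_er(c(1, 2, 3), c(3, 2, 1), transform = "abs"), 1)
  expect_warning(v <- expression_er(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_equal(v, 0)
  expect_error(expression_er(c(1, 2), c(2, 1)), "3 shared samples")
})

test_that("noisy-OR weight combination has its absorbing/identity structure", {
  expect_equal(combine_weight(0, 0), 0)
  expect_equal(combine_weight(1, 0.3), 1)
  expect_equal(combine_weight(0.5, 0.5), 0.75)
  expect_equal(combine_weight(0.5, 0.5, 0.5), 0.875)
  expect_error(combine_weight(1.2, 0), "\\[0,1\\]")
  set.seed(4)
  for (i in 1:100) {
    cr <- stats::runif(1); mr <- stats::runif(1); er <- stats::runif(1)
    w <- combine_weight(cr, mr, er)
    expect_equal(w, combine_weight(mr, cr, er), tolerance = 1e-15)
    expect_gte(w, max(cr, mr, er))
    expect_lte(w, 1)
    expect_gte(combine_weight(min(cr + 0.1, 1), mr, er), w)
  }
})

test_that("all-pair scores match the double-loop oracle on random instances", {
  set.seed(12)
  for (i in 1:30) {
    inst <- random_instance(n_lnc = sample(3:8, 1))
    lnc_mrna <- association_table(
      rep(names(inst$msets), lengths(inst$msets)),
      unlist(inst$msets, use.names = FALSE),
      left_ns = "lncrna", right_ns = "mrna")
    links <- link_df_to_set(inst$edges, "mrna")
    got <- suppressWarnings(lnc_pair_scores(inst$V, lnc_mrna, links))
    want <- suppressWarnings(oracle_pair_scores(inst$V, inst$msets,
                                                inst$edges))
    expect_equal(nrow(got), nrow(want))
    key <- function(d) paste(d$a, d$b)
    got <- got[order(key(got)), ]; want <- want[order(key(want)), ]
    expect_equal(got$cr, want$cr, tolerance = 1e-12)
    expect_equal(got$mr, want$mr, tolerance = 1e-12)
    expect_equal(got$weight, want$weight, tolerance = 1e-12)
    expect_true(all(got$weight >= pmax(got$cr, got$mr) - 1e-12))
  }
})

test_that("identical vectors give weight 1 and zero-evidence pairs are absent", {
  V <- rbind(l1 = c(1, 0.4, 0), l2 = c(1, 0.4, 0), l3 = c(0, 0, 0),
             l4 = c(0, 0, 0))
  lnc_mrna <- association_table(character(0), character(0),
                                left_ns = "lncrna", right_ns = "mrna")
  links <- gene_link_set(character(0), character(0), numeric(0), "mrna")
  ps <- suppressWarnings(lnc_pair_scores(V, lnc_mrna, links))
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$a, "l1"); expect_equal(ps$b, "l2")
  expect_equal(ps$weight, 1)
  expect_setequal(attr(ps, "lncrnas"), rownames(V))
})
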