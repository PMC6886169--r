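test_that("fixture generation is deterministic and byte-identical per seed", {
  b1 <- suppressMessages(generate_fixture(fixture_config(seed = 7)))
  b2 <- suppressMessages(generate_fixture(fixture_config(seed = 7)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(b1, d1); write_fixture(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  b3 <- suppressMessages(generate_fixture(fixture_config(seed = 8)))
  expect_false(identical(b1$lnc_dis_old$left, b3$lnc_dis_old$left))
})

test_that("generated tables satisfy the core container invariants", {
  b <- suppressMessages(generate_fixture(fixture_config(seed = 3)))
  # association tables: de-duplicated, non-empty ids
  for (tab in list(b$lnc_dis_old, b$lnc_dis_new, b$lnc_prot, b$lnc_mrna,
                   b$disease_gene)) {
    expect_s3_class(tab, "assoc_table")
    expect_false(any(duplicated(paste(tab$left, tab$right))))
    expect_true(all(nzchar(tab$left) & nzchar(tab$right)))
  }
  # old snapshot is a subset of the new one; every disease keeps a seed
  old_keys <- paste(b$lnc_dis_old$left, b$lnc_dis_old$right)
  new_keys <- paste(b$lnc_dis_new$left, b$lnc_dis_new$right)
  expect_true(all(old_keys %in% new_keys))
  expect_true(all(unique(b$lnc_dis_new$right) %in% unique(b$lnc_dis_old$right)))
  # link sets: [0,1], no self links, one orientation
  for (ls in list(b$gene_links, b$prot_links, b$mrna_links)) {
    expect_true(all(ls$score >= 0 & ls$score <= 1))
    expect_true(all(ls$a < ls$b))
  }
  # ontology: DAG with a single root, annotations propagated
  expect_equal(ontology_roots(b$onto), "DOID:0000001")
  expect_true(all(lengths(b$onto$propagated) >= lengths(b$onto$annotations)))
  expect_true(all(unique(b$disease_gene$left) %in% b$onto$terms))
  # expression: non-negative, no missing rows
  expect_true(all(b$expression >= 0))
  expect_equal(sort(rownames(b$expression)), sort(names(b$modules)))
})

test_that("infeasible configurations are rejected", {
  expect_error(fixture_config(n_lncrnas = 3, n_modules = 4), "n_modules")
  expect_error(fixture_config(signal = 0.2, noise = 0.5), "noise")
  expect_error(fixture_config(holdout_fraction = 1.2), "holdout_fraction")
  expect_error(fixture_config(n_samples = 2), "samples")
})

test_that("stronger planted signal weakly increases end-to-end recovery", {
  aucs <- vapply(c(0.2, 0.5, 0.8), function(s) {
    b <- suppressMessages(generate_fixture(
      fixture_config(seed = 19, signal = s, noise = 0.05)))
    attr(suppressMessages(run_benchmark(b))$report, "macro_auc")
  }, 0)
  expect_true(all(diff(aucs) >= -0.02))
  expect_gt(aucs[3], aucs[1])
})

test_that("the worked example has the cholangiocarcinoma-like shape", {
  wb <- worked_example()
  d <- wb$focal_disease
  old_l <- wb$lnc_dis_old$left[wb$lnc_dis_old$right == d]
  new_l <- wb$lnc_dis_new$left[wb$lnc_dis_new$right == d]
  expect_equal(length(old_l), 1L)           # one seed lncRNA
  expect_equal(length(setdiff(new_l, old_l)), 5L)  # five held-out positives
  # bundle passes the same validation the generated fixtures do
  expect_false(any(duplicated(paste(wb$lnc_dis_new$left,
                                    wb$lnc_dis_new$right))))
  expect_true(all(wb$gene_links$score >= 0 & wb$gene_links$score <= 1))
  expect_equal(ontology_roots(wb$onto), "DOID:0000001")
})

test_that("fixture files round-trip into an equivalent bundle", {
  b <- suppressMessages(generate_fixture(fixture_config(seed = 5)))
  d <- withr::local_tempdir()
  write_fixture(b, d)
  old <- suppressMessages(read_association_table(
    file.path(d, "lnc_disease_old.tsv")))
  expect_setequal(paste(old$left, old$right),
                  paste(b$lnc_dis_old$left, b$lnc_dis_old$right))
  onto <- read_ontology(file.path(d, "ontology_edges.tsv"))
  expect_setequal(onto$terms, b$onto$terms)
  gl <- read_gene_links(file.path(d, "gene_links.tsv"))
  expect_equal(sort(gl$score), sort(b$gene_links$score), tolerance = 1e-12)
  # the STRING-scale copy ingests back to [0,1]
  gs <- read_gene_links(file.path(d, "protein_links_string_scale.tsv"),
                        "protein")
  expect_true(all(gs$score >= 0 & gs$score <= 1))
  expect_equal(sort(gs$score), sort(round(b$prot_links$score * 1000) / 1000),
               tolerance = 1e-12)
  expr <- read_expression_matrix(file.path(d, "expression.tsv"))
  expect_equal(expr[rownames(b$expression), ], b$expression,
               tolerance = 1e-12)
})
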