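#' Configuration for the planted-module synthetic benchmark
#'
#' The generator plants `n_modules` functional modules: lncRNAs, diseases,
#' genes, proteins and mRNAs are each partitioned across modules, and a
#' lncRNA acquires associations with entities of its own module with
#' probability `signal` and with entities of other modules with probability
#' `noise`. A `holdout_fraction` share of each disease's true lncRNA
#' associations appears only in the "new" snapshot, giving the
#' version-difference evaluation a known ground truth. Setting
#' `noise = signal` ablates the planted structure (null model).
#'
#' @param seed master RNG seed; each artifact (ontology, association
#'   tables, expression) derives its own stream from it.
#' @param n_diseases,n_genes,n_lncrnas,n_proteins,n_mrnas entity counts.
#' @param n_modules number of planted modules (<= each entity count).
#' @param signal within-module association probability in (0,1\].
#' @param noise cross-module association probability, `<= signal`.
#' @param holdout_fraction share of each disease's lncRNA associations
#'   reserved for the "new" snapshot, in (0,1); at least one association
#'   per disease always stays in the "old" snapshot.
#' @param n_samples number of expression samples (>= 3).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_diseases = 24L, n_genes = 80L,
                           n_lncrnas = 40L, n_modules = 4L,
                           n_proteins = 20L, n_mrnas = 40L,
                           signal = 0.8, noise = 0.05,
                           holdout_fraction = 0.25, n_samples = 8L) {
  cfg <- list(seed = as.integer(seed), n_diseases = as.integer(n_diseases),
              n_genes = as.integer(n_genes), n_lncrnas = as.integer(n_lncrnas),
              n_modules = as.integer(n_modules),
              n_proteins = as.integer(n_proteins),
              n_mrnas = as.integer(n_mrnas), signal = signal, noise = noise,
              holdout_fraction = holdout_fraction,
              n_samples = as.integer(n_samples))
  if (!(cfg$signal > 0 && cfg$signal <= 1)) stop("signal must lie in (0,1]")
  if (!(cfg$noise >= 0 && cfg$noise <= cfg$signal)) {
    stop("noise must lie in [0, signal]")
  }
  if (!(cfg$holdout_fraction > 0 && cfg$holdout_fraction < 1)) {
    stop("holdout_fraction must lie in (0,1)")
  }
  counts <- c(cfg$n_diseases, cfg$n_genes, cfg$n_lncrnas, cfg$n_proteins,
              cfg$n_mrnas)
  if (any(counts < cfg$n_modules)) {
    stop("every entity count must be >= n_modules")
  }
  if (cfg$n_modules < 1L) stop("need at least one module")
  if (cfg$n_samples < 3L) stop("need at least 3 expression samples")
  structure(cfg, class = "fixture_config")
}

# independent sub-seed per artifact, kept under 2^31
sub_seed <- function(seed, k) {
  (as.numeric(seed) * 1000003 + k * 7919) %% 2147483629
}

module_of <- function(n, n_modules) ((seq_len(n) - 1L) %% n_modules) + 1L

# Bernoulli association table between module-labelled left and right sets
planted_pairs <- function(left_ids, left_mod, right_ids, right_mod,
                          signal, noise) {
  same <- outer(left_mod, right_mod, "==")
  prob <- ifelse(same, signal, noise)
  hit <- matrix(stats::runif(length(prob)) < prob, nrow = nrow(prob))
  idx <- which(hit, arr.ind = TRUE)
  list(left = left_ids[idx[, 1]], right = right_ids[idx[, 2]])
}

# weighted within/cross-module links, scores uniform(0.3, 1)
planted_links <- function(ids, mod, p_within, p_cross, namespace) {
  n <- length(ids)
  a <- character(0); b <- character(0)
  if (n >= 2) {
    cmb <- utils::combn(n, 2)
    same <- mod[cmb[1, ]] == mod[cmb[2, ]]
    keep <- stats::runif(ncol(cmb)) < ifelse(same, p_within, p_cross)
    a <- ids[cmb[1, keep]]; b <- ids[cmb[2, keep]]
  }
  gene_link_set(a, b, stats::runif(length(a), 0.3, 1.0), namespace)
}

#' Generate a complete synthetic input bundle
#'
#' Produces internally consistent synthetic versions of every pipeline
#' input: a random disease DAG whose branches mirror the planted modules,
#' disease-gene annotations, gene/protein/mRNA link sets, old and new
#' lncRNA-disease snapshots, lncRNA-protein and lncRNA-mRNA tables, and a
#' module-correlated expression matrix. Deterministic given
#' `cfg$seed`; each artifact uses its own derived RNG stream so changing
#' one count does not reshuffle unrelated tables.
#'
#' @param cfg a [fixture_config()].
#' @return A list of class `fixture_bundle` with elements `onto` (annotated
#'   and propagated), `disease_gene`, `gene_links`, `lnc_dis_old`,
#'   `lnc_dis_new`, `lnc_prot`, `prot_links`, `lnc_mrna`, `mrna_links`,
#'   `expression`, `modules` (named module index per lncRNA) and `config`.
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  dis <- sprintf("DOID:%07d", 100L + seq_len(cfg$n_diseases))
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  lncs <- sprintf("URS%07X", 0x10000L + seq_len(cfg$n_lncrnas))
  prots <- sprintf("PROT%03d", seq_len(cfg$n_proteins))
  mrnas <- sprintf("MRNA%04d", seq_len(cfg$n_mrnas))
  dis_mod <- module_of(cfg$n_diseases, cfg$n_modules)
  gene_mod <- module_of(cfg$n_genes, cfg$n_modules)
  lnc_mod <- module_of(cfg$n_lncrnas, cfg$n_modules)
  prot_mod <- module_of(cfg$n_proteins, cfg$n_modules)
  mrna_mod <- module_of(cfg$n_mrnas, cfg$n_modules)

  # -- ontology: one root, one branch term per module, diseases under their
  #    branch; occasional second parent makes diamonds
  set.seed(sub_seed(cfg$seed, 1))
  root <- "DOID:0000001"
  branches <- sprintf("DOID:%07d", 1L + seq_len(cfg$n_modules))
  children <- c(branches, dis)
  parents <- c(rep(root, cfg$n_modules), branches[dis_mod])
  extra <- stats::runif(cfg$n_diseases) < 0.15
  if (any(extra)) {
    other <- vapply(dis_mod[extra], function(m) {
      sample(setdiff(seq_len(cfg$n_modules), m), 1L)
    }, 0L)
    children <- c(children, dis[extra])
    parents <- c(parents, branches[other])
  }
  onto <- disease_ontology(c(root, branches, dis), children, parents)

  # -- disease-gene annotations
  set.seed(sub_seed(cfg$seed, 2))
  dg <- planted_pairs(dis, dis_mod, genes, gene_mod, cfg$signal, cfg$noise)
  # every disease needs at least one gene for the similarity stage
  bare <- setdiff(dis, unique(dg$left))
  if (length(bare)) {
    pick <- vapply(match(bare, dis), function(i) {
      pool <- genes[gene_mod == dis_mod[i]]
      pool[sample.int(length(pool), 1L)]
    }, "")
    dg$left <- c(dg$left, bare); dg$right <- c(dg$right, pick)
  }
  disease_gene <- association_table(dg$left, dg$right,
                                    left_ns = "disease", right_ns = "gene")
  onto <- propagate_annotations(onto, disease_gene)

  # -- link sets
  set.seed(sub_seed(cfg$seed, 3))
  gene_links <- planted_links(genes, gene_mod, 0.30, 0.02, "gene")
  set.seed(sub_seed(cfg$seed, 4))
  prot_links <- planted_links(prots, prot_mod, 0.30, 0.02, "protein")
  set.seed(sub_seed(cfg$seed, 5))
  mrna_links <- planted_links(mrnas, mrna_mod, 0.30, 0.02, "mrna")

  # -- lncRNA association tables
  set.seed(sub_seed(cfg$seed, 6))
  ld <- planted_pairs(lncs, lnc_mod, dis, dis_mod, cfg$signal, cfg$noise)
  # each disease needs >= 2 lncRNAs so one can be held out and one seeded
  tab <- table(factor(ld$right, levels = dis))
  for (d in dis[tab < 2L]) {
    pool <- setdiff(lncs[lnc_mod == dis_mod[match(d, dis)]],
                    ld$left[ld$right == d])
    need <- 2L - sum(ld$right == d)
    add <- pool[sample.int(length(pool), min(need, length(pool)))]
    ld$left <- c(ld$left, add); ld$right <- c(ld$right, rep(d, length(add)))
  }
  lnc_dis_all <- association_table(ld$left, ld$right,
                                   left_ns = "lncrna", right_ns = "disease")
  set.seed(sub_seed(cfg$seed, 7))
  lp <- planted_pairs(lncs, lnc_mod, prots, prot_mod, cfg$signal, cfg$noise)
  lnc_prot <- association_table(lp$left, lp$right,
                                left_ns = "lncrna", right_ns = "protein")
  set.seed(sub_seed(cfg$seed, 8))
  lm <- planted_pairs(lncs, lnc_mod, mrnas, mrna_mod, cfg$signal, cfg$noise)
  lnc_mrna <- association_table(lm$left, lm$right,
                                left_ns = "lncrna", right_ns = "mrna")

  # -- snapshot split: per disease, hold out a share of its lncRNAs for the
  #    "new" snapshot, always keeping at least one seed in the "old" one
  set.seed(sub_seed(cfg$seed, 9))
  old_keep <- rep(TRUE, nrow(lnc_dis_all))
  for (d in unique(lnc_dis_all$right)) {
    rows <- which(lnc_dis_all$right == d)
    n_hold <- min(length(rows) - 1L,
                  floor(cfg$holdout_fraction * length(rows)))
    if (n_hold >= 1L) {
      old_keep[sample(rows, n_hold)] <- FALSE
    }
  }
  lnc_dis_old <- association_table(lnc_dis_all$left[old_keep],
                                   lnc_dis_all$right[old_keep],
                                   left_ns = "lncrna", right_ns = "disease")
  lnc_dis_new <- lnc_dis_all

  # -- expression: shared module base profile plus per-lncRNA noise
  set.seed(sub_seed(cfg$seed, 10))
  base <- matrix(stats::runif(cfg$n_modules * cfg$n_samples, 1, 10),
                 cfg$n_modules, cfg$n_samples)
  expr <- base[lnc_mod, , drop = FALSE] +
    matrix(stats::rnorm(cfg$n_lncrnas * cfg$n_samples, sd = 1),
           cfg$n_lncrnas, cfg$n_samples)
  expr <- pmax(expr, 0)
  rownames(expr) <- lncs
  colnames(expr) <- sprintf("tissue%02d", seq_len(cfg$n_samples))

  structure(list(onto = onto, disease_gene = disease_gene,
                 gene_links = gene_links, lnc_dis_old = lnc_dis_old,
                 lnc_dis_new = lnc_dis_new, lnc_prot = lnc_prot,
                 prot_links = prot_links, lnc_mrna = lnc_mrna,
                 mrna_links = mrna_links, expression = expr,
                 modules = stats::setNames(lnc_mod, lncs), config = cfg),
            class = "fixture_bundle")
}

#' Write a fixture bundle to a directory of TSV files
#'
#' Emits every table in the package's TSV dialects, deterministically
#' ordered, plus a STRING-style integer-scaled copy of the protein links
#' (scores x 1000) to exercise the ingest rescale, and a `manifest.yaml`
#' echoing the configuration. Same seed, same bytes.
#'
#' @param bundle a [generate_fixture()] result.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_association_table(bundle$lnc_dis_old, fp("lnc_disease_old.tsv"))
  write_association_table(bundle$lnc_dis_new, fp("lnc_disease_new.tsv"))
  write_association_table(bundle$lnc_prot, fp("lnc_protein.tsv"))
  write_association_table(bundle$lnc_mrna, fp("lnc_mrna.tsv"))
  write_association_table(bundle$disease_gene, fp("disease_gene.tsv"))
  write_gene_links(bundle$gene_links, fp("gene_links.tsv"))
  write_gene_links(bundle$prot_links, fp("protein_links.tsv"))
  string_style <- bundle$prot_links
  writeLines(paste(string_style$a, string_style$b,
                   round(string_style$score * 1000), sep = "\t"),
             fp("protein_links_string_scale.tsv"), useBytes = TRUE)
  write_gene_links(bundle$mrna_links, fp("mrna_links.tsv"))
  onto_edges <- do.call(rbind, lapply(names(bundle$onto$parents), function(t) {
    ps <- bundle$onto$parents[[t]]
    if (length(ps)) data.frame(child = t, parent = ps) else NULL
  }))
  onto_edges <- onto_edges[order(onto_edges$child, onto_edges$parent), ]
  writeLines(paste(onto_edges$child, onto_edges$parent, sep = "\t"),
             fp("ontology_edges.tsv"), useBytes = TRUE)
  write_expression_matrix(bundle$expression, fp("expression.tsv"))
  cfg <- bundle$config
  writeLines(c("# synthetic fixture manifest",
               paste0(names(unclass(cfg)), ": ",
                      vapply(unclass(cfg), format, ""))),
             fp("manifest.yaml"), useBytes = TRUE)
  invisible(dir)
}

#' Hand-checkable worked example bundle
#'
#' A deterministic miniature data set built without any random draws: one
#' focal disease with a single seed lncRNA and exactly five lncRNAs whose
#' association with the focal disease appears only in the newer snapshot,
#' plus two unrelated lncRNAs. Every intermediate quantity (disease
#' similarities, association vectors, pair weights, walk probabilities) is
#' small enough to verify by hand.
#'
#' @return A `fixture_bundle` (without expression-driven randomness; the
#'   expression matrix is a small fixed table). The focal disease id is in
#'   the `focal_disease` element.
#' @export
worked_example <- function() {
  root <- "DOID:0000001"
  brA <- "DOID:0000002"; brB <- "DOID:0000003"
  d1 <- "DOID:0000010"; d2 <- "DOID:0000011"; d3 <- "DOID:0000020"
  onto <- disease_ontology(c(root, brA, brB, d1, d2, d3),
                           children = c(brA, brB, d1, d2, d3),
                           parents = c(root, root, brA, brA, brB))
  disease_gene <- association_table(
    left = c(d1, d1, d2, d2, d3, d3),
    right = c("g1", "g2", "g2", "g3", "g5", "g6"),
    left_ns = "disease", right_ns = "gene")
  onto <- propagate_annotations(onto, disease_gene)
  gene_links <- gene_link_set(c("g1", "g1"), c("g3", "g5"), c(0.6, 0.2),
                              "gene")
  seedl <- "URS0000000A"
  helds <- sprintf("URS0000000%s", c("B", "C", "D", "E", "F"))
  others <- c("URS0000000G", "URS0000000H")
  lnc_dis_old <- association_table(
    left = c(seedl, helds, others),
    right = c(d1, rep(d2, 5), rep(d3, 2)))
  lnc_dis_new <- association_table(
    left = c(lnc_dis_old$left, helds),
    right = c(lnc_dis_old$right, rep(d1, 5)))
  lnc_prot <- association_table(
    left = c(seedl, helds, others),
    right = c(rep("PROT1", 6), rep("PROT2", 2)),
    left_ns = "lncrna", right_ns = "protein")
  prot_links <- gene_link_set("PROT1", "PROT2", 0.1, "protein")
  lnc_mrna <- association_table(
    left = c(seedl, seedl, helds[1], helds[1], helds[2:5], others),
    right = c("m1", "m2", "m1", "m2", rep("m2", 4), rep("m3", 2)),
    left_ns = "lncrna", right_ns = "mrna")
  mrna_links <- gene_link_set("m1", "m2", 1, "mrna")
  expr <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(1, 3, 2, 4), c(4, 3, 2, 1),
                c(1, 2, 4, 3), c(2, 2.5, 3, 5), c(5, 1, 2, 2), c(4, 4.5, 1, 0))
  rownames(expr) <- c(seedl, helds, others)
  colnames(expr) <- sprintf("tissue%02d", 1:4)
  structure(list(onto = onto, disease_gene = disease_gene,
                 gene_links = gene_links, lnc_dis_old = lnc_dis_old,
                 lnc_dis_new = lnc_dis_new, lnc_prot = lnc_prot,
                 prot_links = prot_links, lnc_mrna = lnc_mrna,
                 mrna_links = mrna_links, expression = expr,
                 modules = NULL, focal_disease = d1,
                 config = NULL),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(paste0("Synthetic bundle: %d lncRNA-disease pairs (old), ",
                     "%d (new), %d ontology terms\n"),
              nrow(x$lnc_dis_old), nrow(x$lnc_dis_new),
              length(x$onto$terms)))
  invisible(x)
}
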