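# Independent brute-force oracles. Everything here works directly on plain
# data frames / vectors with naive double loops, deliberately sharing no
# code with the package implementations.

# max (or mean) link score between gene g and set G, scanning the edge list
oracle_relevance <- function(g, G, edges, relevance = "max") {
  if (g %in% G) return(1)
  hits <- numeric(0)
  for (k in seq_len(nrow(edges))) {
    if ((edges$a[k] == g && edges$b[k] %in% G) ||
        (edges$b[k] == g && edges$a[k] %in% G)) {
      hits <- c(hits, edges$score[k])
    }
  }
  if (!length(hits)) return(0)
  if (relevance == "max") max(hits) else mean(hits)
}

oracle_fnsim <- function(Ga, Gb, edges, relevance = "max") {
  Ga <- unique(Ga); Gb <- unique(Gb)
  if (!length(Ga) || !length(Gb)) return(0)
  s <- 0
  for (g in Ga) s <- s + oracle_relevance(g, Gb, edges, relevance)
  for (g in Gb) s <- s + oracle_relevance(g, Ga, edges, relevance)
  s / (length(Ga) + length(Gb))
}

oracle_cosine <- function(v1, v2) {
  num <- 0; s1 <- 0; s2 <- 0
  for (i in seq_along(v1)) {
    num <- num + v1[i] * v2[i]
    s1 <- s1 + v1[i]^2
    s2 <- s2 + v2[i]^2
  }
  if (s1 == 0 || s2 == 0) return(0)
  unname(num / (sqrt(s1) * sqrt(s2)))
}

oracle_mrna_rel <- function(k, M, edges) {
  if (k %in% M) return(1)
  cnt <- 0
  for (r in seq_len(nrow(edges))) {
    if ((edges$a[r] == k && edges$b[r] %in% M) ||
        (edges$b[r] == k && edges$a[r] %in% M)) {
      cnt <- cnt + 1
    }
  }
  cnt / length(M)
}

oracle_mr <- function(M1, M2, edges) {
  M1 <- unique(M1); M2 <- unique(M2)
  if (!length(M1) && !length(M2)) return(0)
  s <- 0
  for (m in M2) if (length(M1)) s <- s + oracle_mrna_rel(m, M1, edges)
  for (m in M1) if (length(M2)) s <- s + oracle_mrna_rel(m, M2, edges)
  s / (length(M1) + length(M2))
}

# all-pair noisy-OR weights from a vector matrix and per-lncRNA mRNA sets
oracle_pair_scores <- function(V, msets, mrna_edges) {
  lncs <- sort(unique(c(rownames(V), names(msets))))
  out <- data.frame(a = character(0), b = character(0), cr = numeric(0),
                    mr = numeric(0), weight = numeric(0))
  for (i in seq_along(lncs)) {
    for (j in seq_along(lncs)) {
      if (j <= i) next
      la <- lncs[i]; lb <- lncs[j]
      cr <- if (la %in% rownames(V) && lb %in% rownames(V)) {
        min(1, oracle_cosine(V[la, ], V[lb, ]))
      } else 0
      Ma <- msets[[la]]; Mb <- msets[[lb]]
      mr <- if (length(Ma) || length(Mb)) oracle_mr(Ma, Mb, mrna_edges) else 0
      w <- 1 - (1 - cr) * (1 - mr)
      if (w > 0) {
        out <- rbind(out, data.frame(a = la, b = lb, cr = cr, mr = mr,
                                     weight = w))
      }
    }
  }
  out
}

# dense RWR oracle: solve (I - (1-r) W) p = r p0 directly
oracle_rwr <- function(net, seeds, r) {
  ids <- net$nodes
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(net$edges))) {
    A[net$edges$a[k], net$edges$b[k]] <- net$edges$weight[k]
    A[net$edges$b[k], net$edges$a[k]] <- net$edges$weight[k]
  }
  p0 <- stats::setNames(rep(0, n), ids)
  p0[seeds] <- 1 / length(seeds)
  cs <- colSums(A)
  W <- sweep(A, 2, ifelse(cs > 0, cs, 1), "/")
  W[, cs == 0] <- p0
  drop(solve(diag(n) - (1 - r) * W, r * p0))
}

# AUC as the trapezoidal area under the empirical ROC curve
oracle_auc_trapezoid <- function(scores, positives, negatives) {
  s <- scores[c(positives, negatives)]
  y <- c(rep(1, length(positives)), rep(0, length(negatives)))
  cuts <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0); fpr <- c(0)
  for (t in cuts) {
    tpr <- c(tpr, sum(s >= t & y == 1) / sum(y == 1))
    fpr <- c(fpr, sum(s >= t & y == 0) / sum(y == 0))
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# random lncRNA-space instance for oracle-equivalence checks
random_instance <- function(n_lnc = 8, n_dim = 6, n_mrna = 10) {
  lncs <- sprintf("L%02d", seq_len(n_lnc))
  V <- matrix(round(stats::runif(n_lnc * n_dim), 3), n_lnc, n_dim,
              dimnames = list(lncs, sprintf("dim%02d", seq_len(n_dim))))
  V[stats::runif(length(V)) < 0.5] <- 0
  mrnas <- sprintf("M%02d", seq_len(n_mrna))
  msets <- lapply(stats::setNames(lncs, lncs), function(l) {
    sort(sample(mrnas, stats::rbinom(1, n_mrna, 0.3)))
  })
  msets <- msets[lengths(msets) > 0]
  n_edge <- stats::rbinom(1, n_mrna * 2, 0.4)
  edges <- if (n_edge > 0) {
    a <- sample(mrnas, n_edge, replace = TRUE)
    b <- sample(mrnas, n_edge, replace = TRUE)
    keep <- a != b
    data.frame(a = pmin(a[keep], b[keep]), b = pmax(a[keep], b[keep]),
               score = rep(1, sum(keep)))
  } else {
    data.frame(a = character(0), b = character(0), score = numeric(0))
  }
  edges <- edges[!duplicated(edges[, c("a", "b")]), , drop = FALSE]
  list(lncs = lncs, V = V, msets = msets, edges = edges)
}

# random weighted undirected network for RWR checks
random_network <- function(n_nodes, n_edges) {
  ids <- sprintf("N%03d", seq_len(n_nodes))
  a <- sample(ids, n_edges, replace = TRUE)
  b <- sample(ids, n_edges, replace = TRUE)
  keep <- a != b
  pr <- data.frame(a = a[keep], b = b[keep],
                   weight = stats::runif(sum(keep), 0.05, 1))
  suppressWarnings(assemble_network(pr, nodes = ids))
}

link_df_to_set <- function(edges, namespace = "gene") {
  gene_link_set(edges$a, edges$b, edges$score, namespace)
}
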