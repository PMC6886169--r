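#' Cosine similarity between two lncRNA association vectors
#'
#' \deqn{CR(l_1,l_2) = \sum_i AS_{1,i} AS_{2,i} /
#'       (\lVert v_1 \rVert \, \lVert v_2 \rVert).}
#' Because association scores are non-negative the value lies in \[0,1\].
#' Returns 0 when either vector is all zero.
#'
#' @param v1,v2 numeric vectors over the same [dimension_space()].
#' @return A number in \[0,1\].
#' @export
cosine_cr <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors live in different spaces")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(0)
  min(1, sum(v1 * v2) / (n1 * n2))
}

#' Relevance of an mRNA to an mRNA set
#'
#' 1 when the mRNA belongs to the set; otherwise the number of interaction
#' links between it and members of the set, divided by the set size. Each
#' link is counted once regardless of stored orientation; self-pairs are
#' never counted.
#'
#' @param k an mRNA id.
#' @param M character vector, a non-empty mRNA set.
#' @param linkset a [gene_link_set()] of mRNA-mRNA interactions.
#' @return A number in \[0,1\].
#' @export
mrna_relevance <- function(k, M, linkset) {
  M <- unique(M)
  if (k %in% M) return(1)
  nb <- link_neighbors(linkset, k)
  n_links <- sum(names(nb) %in% M)
  n_links / length(M)
}

#' mRNA-based similarity between two lncRNAs
#'
#' For lncRNAs with mRNA partner sets `M1` and `M2`, sums the relevance of
#' each member of `M2` to `M1` and of each member of `M1` to `M2`, divided
#' by `|M1| + |M2|`. Equals 1 when the sets coincide (non-empty), 0 when
#' both are empty (with a warning) or when there is no overlap and no link.
#'
#' @param M1,M2 character vectors of mRNA ids.
#' @inheritParams mrna_relevance
#' @return A number in \[0,1\].
#' @export
mrna_mr <- function(M1, M2, linkset) {
  M1 <- unique(M1); M2 <- unique(M2)
  if (!length(M1) && !length(M2)) {
    warning("both mRNA sets empty; similarity 0")
    return(0)
  }
  s1 <- if (length(M1)) {
    sum(vapply(M2, mrna_relevance, 0, M = M1, linkset = linkset))
  } else 0
  s2 <- if (length(M2)) {
    sum(vapply(M1, mrna_relevance, 0, M = M2, linkset = linkset))
  } else 0
  (s1 + s2) / (length(M1) + length(M2))
}

#' Expression similarity between two lncRNAs
#'
#' Spearman's rank correlation between two expression profiles, mapped into
#' \[0,1\] either by clamping negative correlations to 0 (default) or by
#' taking the absolute value. A constant profile has undefined rank
#' correlation and returns 0 with a warning.
#'
#' @param x1,x2 numeric expression profiles over the same >= 3 samples.
#' @param transform `"clamp"` (negative rho to 0) or `"abs"`.
#' @return A number in \[0,1\].
#' @export
expression_er <- function(x1, x2, transform = c("clamp", "abs")) {
  transform <- match.arg(transform)
  if (length(x1) != length(x2)) stop("profiles differ in length")
  if (length(x1) < 3L) stop("need at least 3 shared samples")
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
    warning("constant expression profile; similarity 0")
    return(0)
  }
  rho <- stats::cor(x1, x2, method = "spearman")
  if (transform == "clamp") max(0, rho) else abs(rho)
}

#' Combine similarity channels into a network edge weight
#'
#' Noisy-OR combination of the independent evidence channels:
#' `1 - (1-cr)(1-mr)` without expression, with an extra `(1-er)` factor
#' when expression similarity is supplied. Symmetric, monotone in each
#' argument, and at least as large as any single channel.
#'
#' @param cr cosine similarity in \[0,1\].
#' @param mr mRNA-based similarity in \[0,1\].
#' @param er optional expression similarity in \[0,1\].
#' @return A number in \[0,1\].
#' @export
combine_weight <- function(cr, mr, er = NULL) {
  vals <- c(cr, mr, er)
  if (any(vals < 0 | vals > 1)) stop("similarity channels must lie in [0,1]")
  w <- 1 - (1 - cr) * (1 - mr)
  if (!is.null(er)) w <- 1 - (1 - w) * (1 - er)
  w
}

#' All-pair lncRNA similarity scores
#'
#' Enumerates unordered pairs among all lncRNAs having at least one
#' association of any kind (disease, protein or mRNA; matching a network
#' restricted to annotated lncRNAs), computes the cosine, mRNA and optional
#' expression channels, combines them by noisy-OR, and keeps only pairs
#' with positive weight.
#'
#' @param vectors matrix from [build_lnc_vectors()].
#' @param lnc_mrna an [association_table()] (lncRNA left, mRNA right).
#' @param mrna_links a [gene_link_set()] of mRNA-mRNA interactions.
#' @param expression optional expression matrix (lncRNA rows); enables the
#'   expression channel for pairs where both profiles are present.
#' @param er_transform passed to [expression_er()].
#' @return A data frame of class `lnc_pairs` with columns `a`, `b`, `cr`,
#'   `mr`, (optionally `er`,) `weight`, plus attribute `lncrnas` listing
#'   every enumerated lncRNA (including isolated ones).
#' @export
lnc_pair_scores <- function(vectors, lnc_mrna, mrna_links,
                            expression = NULL,
                            er_transform = c("clamp", "abs")) {
  er_transform <- match.arg(er_transform)
  stopifnot(inherits(lnc_mrna, "assoc_table"))
  Msets <- lapply(split(lnc_mrna$right, lnc_mrna$left),
                  function(m) sort(unique(m)))
  # enumerate lncRNAs with at least one association of any kind: vector rows
  # (disease/protein-associated by construction) plus mRNA-associated ones
  lncs <- sort(unique(c(rownames(vectors), names(Msets))))
  with_er <- !is.null(expression)
  n <- length(lncs)
  out_a <- character(0); out_b <- character(0)
  out_cr <- numeric(0); out_mr <- numeric(0); out_er <- numeric(0)
  out_w <- numeric(0)
  for (i in seq_len(max(0, n - 1L))) {
    for (j in seq((i + 1L), n)) {
      la <- lncs[i]; lb <- lncs[j]
      va <- if (la %in% rownames(vectors)) vectors[la, ] else NULL
      vb <- if (lb %in% rownames(vectors)) vectors[lb, ] else NULL
      cr <- if (!is.null(va) && !is.null(vb)) cosine_cr(va, vb) else 0
      Ma <- Msets[[la]]; Mb <- Msets[[lb]]
      mr <- if (length(Ma) || length(Mb)) {
        mrna_mr(Ma, Mb, mrna_links)
      } else 0
      er <- NA_real_
      if (with_er && la %in% rownames(expression) &&
          lb %in% rownames(expression) &&
          stats::sd(expression[la, ]) > 0 && stats::sd(expression[lb, ]) > 0) {
        er <- expression_er(expression[la, ], expression[lb, ],
                            transform = er_transform)
      }
      w <- if (with_er && !is.na(er)) {
        combine_weight(cr, mr, er)
      } else {
        combine_weight(cr, mr)
      }
      if (w > 0) {
        out_a <- c(out_a, la); out_b <- c(out_b, lb)
        out_cr <- c(out_cr, cr); out_mr <- c(out_mr, mr)
        out_er <- c(out_er, er); out_w <- c(out_w, w)
      }
    }
  }
  df <- data.frame(a = out_a, b = out_b, cr = out_cr, mr = out_mr,
                   stringsAsFactors = FALSE)
  if (with_er) df$er <- out_er
  df$weight <- out_w
  structure(df, lncrnas = lncs, class = c("lnc_pairs", "data.frame"))
}

#' @export
print.lnc_pairs <- function(x, ...) {
  cat(sprintf("lncRNA pair scores: %d positive-weight pairs over %d lncRNAs\n",
              nrow(x), length(attr(x, "lncrnas"))))
  NextMethod()
}
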