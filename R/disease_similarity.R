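#' Relevance of a gene to a gene set
#'
#' The building block of disease functional similarity. A gene inside the
#' set has relevance 1; a gene outside the set is scored by its strongest
#' (default) or mean functional link into the set, 0 when no link exists.
#' Values always lie in \[0,1\].
#'
#' @param g a gene id.
#' @param G character vector, a non-empty gene set.
#' @param net a [gene_link_set()] with scores in \[0,1\].
#' @param relevance `"max"` (default) or `"mean"` aggregation over the
#'   gene's links into `G`.
#' @return A number in \[0,1\].
#' @export
gene_set_relevance <- function(g, G, net, relevance = c("max", "mean")) {
  relevance <- match.arg(relevance)
  if (g %in% G) return(1)
  nb <- link_neighbors(net, g)
  hits <- nb[names(nb) %in% G]
  if (!length(hits)) return(0)
  if (relevance == "max") max(hits) else mean(hits)
}

#' Disease functional similarity from gene sets
#'
#' Best-match style similarity between the gene sets of two diseases:
#' the relevances of every gene of one set to the other set, summed both
#' ways and divided by the total number of genes,
#' \deqn{(\sum_i R_{G_b}(g_{ai}) + \sum_j R_{G_a}(g_{bj})) /
#'       (|G_a|+|G_b|).}
#' Symmetric, in \[0,1\], and exactly 1 when the two sets coincide.
#'
#' @param Ga,Gb character vectors of gene ids (disease gene sets).
#' @inheritParams gene_set_relevance
#' @return A number in \[0,1\]; 0 with a warning if either set is empty.
#' @export
fnsim <- function(Ga, Gb, net, relevance = c("max", "mean")) {
  relevance <- match.arg(relevance)
  Ga <- unique(Ga); Gb <- unique(Gb)
  if (!length(Ga) || !length(Gb)) {
    warning("empty gene set; functional similarity is 0")
    return(0)
  }
  ra <- vapply(Ga, gene_set_relevance, 0, G = Gb, net = net,
               relevance = relevance)
  rb <- vapply(Gb, gene_set_relevance, 0, G = Ga, net = net,
               relevance = relevance)
  (sum(ra) + sum(rb)) / (length(Ga) + length(Gb))
}

#' Information content of ontology terms
#'
#' IC(t) = -log(|propagated(t)| / N), with N the number of distinct genes
#' annotated anywhere in the ontology (the propagated set of the root in a
#' single-root DAG). Terms with no propagated annotations get `-Inf` and
#' can never be a most informative common ancestor.
#'
#' @param onto a [disease_ontology()] after [propagate_annotations()].
#' @return Named numeric vector of IC values over all terms.
#' @export
term_ic <- function(onto) {
  stopifnot(inherits(onto, "disease_ontology"))
  sizes <- lengths(onto$propagated)
  total <- length(unique(unlist(onto$propagated, use.names = FALSE)))
  ic <- rep(-Inf, length(sizes))
  names(ic) <- names(sizes)
  if (total > 0) {
    pos <- sizes > 0
    ic[pos] <- -log(sizes[pos] / total)
  }
  ic
}

#' Most informative common ancestor of two disease terms
#'
#' Among the common ancestors of the two terms (each term being its own
#' ancestor), returns the one with maximum information content. Ties are
#' broken deterministically by the lexicographically smallest term id.
#'
#' @param da,db disease term ids present in the ontology.
#' @inheritParams term_ic
#' @param ic optional precomputed [term_ic()] vector.
#' @return The MICA term id, or `NA_character_` when the terms share no
#'   ancestor or every common ancestor has IC `-Inf`.
#' @export
mica <- function(da, db, onto, ic = NULL) {
  common <- intersect(term_ancestors(onto, da), term_ancestors(onto, db))
  if (!length(common)) return(NA_character_)
  if (is.null(ic)) ic <- term_ic(onto)
  vals <- ic[common]
  if (all(!is.finite(vals))) return(NA_character_)
  best <- vals == max(vals)
  sort(common[best])[1]
}

#' Semantically corrected disease functional similarity
#'
#' Multiplies the gene-set functional similarity by a semantic correction
#' derived from the ontology: the product of the two diseases' gene-set
#' sizes over the squared size of the MICA's propagated gene set,
#' \deqn{FNSemSim(d_a,d_b) = FNSim(G_a,G_b) \cdot
#'       |G_a||G_b| / |G_{MICA}|^2.}
#' Raw values can exceed 1; the pairwise matrix is min-max normalized
#' afterwards (see [disease_similarity()]).
#'
#' @param da,db disease term ids.
#' @param gene_sets named list of per-disease gene sets (see
#'   [disease_gene_sets()]).
#' @inheritParams gene_set_relevance
#' @param onto a propagated [disease_ontology()].
#' @param ic optional precomputed [term_ic()] vector.
#' @return A non-negative raw similarity; 0 (with a warning where relevant)
#'   when a gene set is empty, the MICA is unresolvable, or the MICA has no
#'   annotations.
#' @export
fnsemsim <- function(da, db, gene_sets, net, onto, ic = NULL,
                     relevance = c("max", "mean")) {
  relevance <- match.arg(relevance)
  Ga <- gene_sets[[da]]; Gb <- gene_sets[[db]]
  if (is.null(Ga) || is.null(Gb) || !length(Ga) || !length(Gb)) return(0)
  m <- mica(da, db, onto, ic = ic)
  if (is.na(m)) return(0)
  g_mica <- onto$propagated[[m]]
  if (!length(g_mica)) {
    warning("MICA of ", da, " and ", db, " has no annotations; similarity 0")
    return(0)
  }
  base <- fnsim(Ga, Gb, net, relevance = relevance)
  base * (length(Ga) * length(Gb)) / length(g_mica)^2
}

#' Min-max normalize a similarity matrix
#'
#' Off-diagonal values are mapped by `(x - min)/(max - min)` over the pool
#' of all off-diagonal entries; the diagonal is excluded from the pool and
#' pinned to 1 (self-similarity). Symmetry is preserved and the relative
#' ordering of off-diagonal values is unchanged. If all off-diagonal values
#' are equal they all map to 0 with a warning.
#'
#' @param m a symmetric numeric matrix with dimnames.
#' @return The normalized matrix, with attribute `stage = "normalized"`.
#' @export
minmax_normalize <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (nrow(m) >= 2) {
    off <- m[upper.tri(m) | lower.tri(m)]
    lo <- min(off); hi <- max(off)
    if (hi == lo) {
      warning("all off-diagonal similarities equal; normalized to 0")
      m[upper.tri(m) | lower.tri(m)] <- 0
    } else {
      idx <- upper.tri(m) | lower.tri(m)
      m[idx] <- (m[idx] - lo) / (hi - lo)
    }
  }
  diag(m) <- 1
  attr(m, "stage") <- "normalized"
  m
}

#' Pairwise disease functional similarity matrix
#'
#' Computes the raw semantically corrected similarity for every unordered
#' disease pair and (by default) min-max normalizes the result. Diseases
#' without gene annotations get similarity 0 to everything but themselves.
#'
#' @param diseases character vector of disease term ids (the matrix index).
#' @inheritParams fnsemsim
#' @param disease_gene an [association_table()] of direct disease-gene
#'   annotations, used when `gene_sets` is not supplied.
#' @param gene_sets optional named list of per-disease gene sets; overrides
#'   `disease_gene`.
#' @param use_propagated_gene_sets if `TRUE`, use DAG-propagated gene sets
#'   in the functional-similarity term instead of direct annotations.
#' @param normalize min-max normalize the matrix (default `TRUE`).
#' @return A symmetric numeric matrix over `diseases` with a `stage`
#'   attribute (`"raw"` or `"normalized"`).
#' @export
disease_similarity <- function(diseases, disease_gene = NULL, net, onto,
                               gene_sets = NULL,
                               use_propagated_gene_sets = FALSE,
                               relevance = c("max", "mean"),
                               normalize = TRUE) {
  relevance <- match.arg(relevance)
  diseases <- unique(diseases)
  if (is.null(gene_sets)) {
    if (use_propagated_gene_sets) {
      gene_sets <- onto$propagated
    } else {
      if (is.null(disease_gene)) stop("need disease_gene or gene_sets")
      gene_sets <- disease_gene_sets(disease_gene)
    }
  }
  ic <- term_ic(onto)
  n <- length(diseases)
  m <- matrix(0, n, n, dimnames = list(diseases, diseases))
  in_onto <- diseases %in% onto$terms
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i == j) {
        m[i, j] <- if (!is.null(gene_sets[[diseases[i]]]) &&
                       length(gene_sets[[diseases[i]]]) && in_onto[i]) {
          fnsemsim(diseases[i], diseases[i], gene_sets, net, onto, ic = ic,
                   relevance = relevance)
        } else 0
      } else {
        v <- if (in_onto[i] && in_onto[j]) {
          fnsemsim(diseases[i], diseases[j], gene_sets, net, onto, ic = ic,
                   relevance = relevance)
        } else 0
        m[i, j] <- m[j, i] <- v
      }
    }
  }
  attr(m, "stage") <- "raw"
  if (normalize) m <- minmax_normalize(m)
  m
}

#' Write a disease similarity matrix as a 3-column TSV
#'
#' One row per unordered pair with similarity > 0:
#' `disease_a<TAB>disease_b<TAB>similarity`.
#'
#' @param m a similarity matrix from [disease_similarity()].
#' @param path output path.
#' @export
write_similarity_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  ids <- rownames(m)
  rows <- character(0)
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in seq((i + 1L), ncol(m))) {
      if (m[i, j] > 0) {
        rows <- c(rows, paste(ids[i], ids[j], format_score(m[i, j]),
                              sep = "\t"))
      }
    }
  }
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}
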