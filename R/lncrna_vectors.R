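#' Dimension space for lncRNA association vectors
#'
#' The vector space every lncRNA is embedded in: first all lncRNA-related
#' diseases (any disease associated with at least one lncRNA), then all
#' lncRNA-related proteins, in a fixed sorted order shared by every vector.
#' Entities appearing only in similarity or link tables but never
#' associated with a lncRNA are not dimensions.
#'
#' @param lnc_disease an [association_table()] (lncRNA left, disease right).
#' @param lnc_protein an [association_table()] (lncRNA left, protein right).
#' @return A list of class `dimension_space` with elements `diseases`,
#'   `proteins` and `dimensions` (diseases then proteins).
#' @export
dimension_space <- function(lnc_disease, lnc_protein) {
  stopifnot(inherits(lnc_disease, "assoc_table"),
            inherits(lnc_protein, "assoc_table"))
  D <- sort(unique(lnc_disease$right))
  P <- sort(unique(lnc_protein$right))
  if (length(intersect(D, P))) {
    stop("disease and protein dimensions overlap: ",
         paste(utils::head(intersect(D, P), 3), collapse = ", "))
  }
  structure(list(diseases = D, proteins = P, dimensions = c(D, P)),
            class = "dimension_space")
}

#' @export
print.dimension_space <- function(x, ...) {
  cat(sprintf("Dimension space: %d diseases + %d proteins = %d dimensions\n",
              length(x$diseases), length(x$proteins), length(x$dimensions)))
  invisible(x)
}

#' Imputed association score between a disease and a lncRNA
#'
#' The collaborative-filtering MAX rule: 1 when the disease is directly
#' associated with the lncRNA; otherwise the maximum normalized functional
#' similarity between the disease and any disease directly associated with
#' the lncRNA; 0 when the lncRNA has no disease associations.
#'
#' @param d a disease id (a dimension).
#' @param DRl character vector of diseases directly related to the lncRNA.
#' @param dsim a normalized disease similarity matrix
#'   (see [disease_similarity()]).
#' @return A number in \[0,1\].
#' @export
association_score_disease <- function(d, DRl, dsim) {
  if (d %in% DRl) return(1)
  if (!length(DRl)) return(0)
  known <- intersect(DRl, rownames(dsim))
  if (!length(known) || !d %in% colnames(dsim)) return(0)
  max(dsim[known, d])
}

#' Imputed association score between a protein and a lncRNA
#'
#' MAX rule over protein-protein relevance scores: 1 when the protein is
#' directly associated with the lncRNA; otherwise the maximum link score
#' between the protein and any protein directly associated with the lncRNA;
#' 0 when there is no evidence.
#'
#' @param p a protein id (a dimension).
#' @param PRl character vector of proteins directly related to the lncRNA.
#' @param pnet a [gene_link_set()] of protein-protein scores in \[0,1\].
#' @return A number in \[0,1\].
#' @export
association_score_protein <- function(p, PRl, pnet) {
  if (p %in% PRl) return(1)
  if (!length(PRl)) return(0)
  nb <- link_neighbors(pnet, p)
  hits <- nb[names(nb) %in% PRl]
  if (!length(hits)) return(0)
  max(hits)
}

#' Build per-lncRNA association-score vectors
#'
#' One dense vector per lncRNA over the `|D| + |P|` dimension space: the
#' disease block holds the imputed disease association scores, the protein
#' block the imputed protein scores. Entries are exactly 1 at directly
#' associated dimensions; a lncRNA with no associations gets an all-zero
#' vector and is flagged with a message.
#'
#' @param lncrnas character vector of lncRNA ids to build vectors for;
#'   defaults to the union of lncRNAs in the two association tables.
#' @inheritParams dimension_space
#' @param dsim normalized disease similarity matrix.
#' @param pnet protein [gene_link_set()].
#' @param space optional precomputed [dimension_space()].
#' @return Numeric matrix (lncRNAs in rows, dimensions in columns) with
#'   attributes `space` and `n_disease`.
#' @export
build_lnc_vectors <- function(lnc_disease, lnc_protein, dsim, pnet,
                              lncrnas = NULL, space = NULL) {
  if (is.null(space)) space <- dimension_space(lnc_disease, lnc_protein)
  if (is.null(lncrnas)) {
    lncrnas <- sort(unique(c(lnc_disease$left, lnc_protein$left)))
  }
  DR <- split(lnc_disease$right, lnc_disease$left)
  PR <- split(lnc_protein$right, lnc_protein$left)
  D <- space$diseases; P <- space$proteins
  V <- matrix(0, length(lncrnas), length(D) + length(P),
              dimnames = list(lncrnas, space$dimensions))
  for (l in lncrnas) {
    drl <- unique(DR[[l]]); prl <- unique(PR[[l]])
    if (length(D)) {
      if (length(drl)) {
        known <- intersect(drl, rownames(dsim))
        if (length(known)) {
          hit <- intersect(colnames(dsim), D)
          if (length(hit)) {
            sub <- dsim[known, hit, drop = FALSE]
            V[l, hit] <- apply(sub, 2, max)
          }
        }
        V[l, intersect(drl, D)] <- 1
      }
    }
    if (length(P)) {
      if (length(prl)) {
        sc <- vapply(P, association_score_protein, 0, PRl = prl, pnet = pnet)
        V[l, P] <- sc
      }
    }
    if (!length(drl) && !length(prl)) {
      message("lncRNA with no associations (all-zero vector): ", l)
    }
  }
  attr(V, "space") <- space
  attr(V, "n_disease") <- length(D)
  V
}

#' Write nonzero vector entries as TSV
#'
#' Columns: `lncrna_id<TAB>dimension_id<TAB>score`, one row per nonzero
#' entry, in deterministic order.
#'
#' @param V matrix from [build_lnc_vectors()].
#' @param path output path.
#' @export
write_lnc_vectors <- function(V, path) {
  rows <- character(0)
  for (l in sort(rownames(V))) {
    nz <- which(V[l, ] > 0)
    if (length(nz)) {
      rows <- c(rows, paste(l, colnames(V)[nz], format_score(V[l, nz]),
                            sep = "\t"))
    }
  }
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}
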