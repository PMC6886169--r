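#' Assemble the weighted lncRNA functional network
#'
#' Keeps edges with weight strictly greater than `max(0, min_weight)`;
#' duplicate pair rows collapse to a single undirected edge (maximum
#' weight); lncRNAs left without any edge are retained as isolated nodes.
#'
#' @param pair_scores an `lnc_pairs` data frame from [lnc_pair_scores()],
#'   or any data frame with columns `a`, `b`, `weight`.
#' @param min_weight edge-weight threshold; 0 keeps every positive-weight
#'   pair. A threshold such as 0.4 is typically used only for export and
#'   display, not for the random walk.
#' @param nodes optional character vector of node ids to retain (defaults
#'   to the `lncrnas` attribute of `pair_scores`, else the ids seen in it).
#' @return An object of class `lnc_network`: list with `nodes` (sorted ids)
#'   and `edges` (data frame `a`, `b`, `weight`).
#' @export
assemble_network <- function(pair_scores, min_weight = 0, nodes = NULL) {
  stopifnot(all(c("a", "b", "weight") %in% names(pair_scores)))
  if (is.null(nodes)) nodes <- attr(pair_scores, "lncrnas")
  if (is.null(nodes)) nodes <- unique(c(pair_scores$a, pair_scores$b))
  lo <- pmin(pair_scores$a, pair_scores$b)
  hi <- pmax(pair_scores$a, pair_scores$b)
  ed <- data.frame(a = lo, b = hi, weight = pair_scores$weight,
                   stringsAsFactors = FALSE)
  ed <- ed[ed$a != ed$b & ed$weight > max(0, min_weight), , drop = FALSE]
  if (nrow(ed)) {
    key <- paste(ed$a, ed$b, sep = "\r")
    ed <- ed[order(key, -ed$weight), , drop = FALSE]
    ed <- ed[!duplicated(paste(ed$a, ed$b, sep = "\r")), , drop = FALSE]
    ed <- ed[order(ed$a, ed$b), , drop = FALSE]
    rownames(ed) <- NULL
  }
  if (!nrow(ed)) {
    warning("network has no edges; random walk will return the seed distribution")
  }
  nodes <- sort(unique(c(nodes, ed$a, ed$b)))
  structure(list(nodes = nodes, edges = ed), class = "lnc_network")
}

#' @export
print.lnc_network <- function(x, ...) {
  cat(sprintf("lncRNA functional network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Random walk with restart on the lncRNA network
#'
#' Iterates \eqn{p \leftarrow (1-r) W p + r p_0} to its fixed point, where
#' `W` is the column-normalized weighted adjacency matrix and `p0` is
#' uniform over the seed nodes. Columns of isolated (degree-0) nodes are
#' replaced by the restart vector so probability mass is conserved.
#' Iteration stops when the L1 change drops below `tol` or after
#' `max_iter` sweeps; the stationary vector is the proximity of every node
#' to the seed set.
#'
#' @param net an [assemble_network()] result.
#' @param seeds non-empty character vector of seed node ids, all present in
#'   the network.
#' @param restart restart probability `r` in (0,1); 0.7 by default.
#' @param tol L1 convergence threshold (> 0).
#' @param max_iter iteration cap (>= 1).
#' @return Named numeric probability vector over `net$nodes`
#'   (non-negative, sums to 1).
#' @export
rwr <- function(net, seeds, restart = 0.7, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(net, "lnc_network"))
  if (!(restart > 0 && restart < 1)) stop("restart must lie in (0,1)")
  if (!(tol > 0)) stop("tol must be > 0")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  seeds <- unique(seeds)
  if (!length(seeds)) stop("no known lncRNAs for disease: empty seed set")
  miss <- setdiff(seeds, net$nodes)
  if (length(miss)) stop("seed(s) not in network: ", paste(miss, collapse = ", "))
  n <- length(net$nodes)
  p0 <- stats::setNames(rep(0, n), net$nodes)
  p0[seeds] <- 1 / length(seeds)
  W <- rwr_transition(net)
  dangling <- attr(W, "dangling")
  p <- p0
  for (it in seq_len(max_iter)) {
    mass_d <- if (length(dangling)) sum(p[dangling]) else 0
    p_new <- as.numeric((1 - restart) * (W %*% p)) +
      (1 - restart) * mass_d * p0 + restart * p0
    names(p_new) <- net$nodes
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  p / sum(p)
}

# column-normalized sparse transition matrix; attr "dangling" marks
# zero-degree columns (handled by redirecting their mass to the restart
# vector)
rwr_transition <- function(net) {
  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  if (nrow(net$edges)) {
    i <- c(idx[net$edges$a], idx[net$edges$b])
    j <- c(idx[net$edges$b], idx[net$edges$a])
    x <- rep(net$edges$weight, 2L)
    A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  } else {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }
  colsum <- Matrix::colSums(A)
  dangling <- net$nodes[colsum == 0]
  scale <- ifelse(colsum > 0, 1 / colsum, 0)
  W <- A %*% Matrix::Diagonal(n, scale)
  attr(W, "dangling") <- dangling
  W
}

#' Rank candidate lncRNAs for a disease
#'
#' Seeds the random walk on the disease's known lncRNAs and ranks every
#' other network node by stationary probability (descending), breaking
#' ties by lexicographic lncRNA id. Percentiles are reported over the
#' candidate (non-seed) set.
#'
#' @inheritParams rwr
#' @param disease the query disease id.
#' @param known an [association_table()] of known lncRNA-disease pairs
#'   (lncRNA left, disease right); its lncRNAs for `disease` become seeds.
#' @return A data frame of class `ranked_list` with columns `rank`,
#'   `lncrna`, `probability`, `percentile`, `is_seed` (seeds listed after
#'   candidates with `rank NA`), and attribute `disease`.
#' @export
rank_candidates <- function(net, disease, known, restart = 0.7,
                            tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(known, "assoc_table"))
  seeds <- unique(known$left[known$right == disease])
  seeds <- intersect(seeds, net$nodes)
  if (!length(seeds)) {
    stop("no known lncRNAs in the network for disease ", disease)
  }
  p <- rwr(net, seeds, restart = restart, tol = tol, max_iter = max_iter)
  cand <- setdiff(net$nodes, seeds)
  ord <- cand[order(-p[cand], cand)]
  res <- data.frame(
    rank = c(seq_along(ord), rep(NA_integer_, length(seeds))),
    lncrna = c(ord, sort(seeds)),
    probability = c(p[ord], p[sort(seeds)]),
    percentile = c(seq_along(ord) / length(ord), rep(NA_real_, length(seeds))),
    is_seed = c(rep(FALSE, length(ord)), rep(TRUE, length(seeds))),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, disease = disease, class = c("ranked_list", "data.frame"))
}

#' Export the network as an edge-list TSV
#'
#' Writes `lncrna_a<TAB>lncrna_b<TAB>weight` for every edge at or above the
#' display threshold (0.4 by default, the conventional cut for
#' visualization; the random walk itself uses the unthresholded network).
#'
#' @param net an [assemble_network()] result.
#' @param path output path.
#' @param min_weight display threshold; edges with weight > `min_weight`
#'   are written.
#' @export
export_network <- function(net, path, min_weight = 0.4) {
  ed <- net$edges[net$edges$weight > min_weight, , drop = FALSE]
  ed <- ed[order(ed$a, ed$b), , drop = FALSE]
  writeLines(paste(ed$a, ed$b, format_score(ed$weight), sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}
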