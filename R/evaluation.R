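#' Build per-disease test sets from two association-table snapshots
#'
#' The version-difference protocol: for every disease, positives are the
#' lncRNAs associated with it only in the newer snapshot and present as
#' network nodes; negatives are the network lncRNAs associated with it in
#' neither snapshot. Diseases with no positives or no negatives are dropped
#' with a logged reason. Pairs present in the old snapshot but absent from
#' the new one are ignored (removals are not positives).
#'
#' @param old,new [association_table()]s of lncRNA-disease pairs (lncRNA
#'   left, disease right), older and newer snapshots.
#' @param net_nodes character vector of network lncRNA ids.
#' @return A list of class `version_diff` mapping disease id to a list with
#'   `positives`, `negatives` and `seeds` (old-snapshot lncRNAs of the
#'   disease that are network nodes).
#' @export
version_diff <- function(old, new, net_nodes) {
  stopifnot(inherits(old, "assoc_table"), inherits(new, "assoc_table"))
  old_by_d <- lapply(split(old$left, old$right), unique)
  new_by_d <- lapply(split(new$left, new$right), unique)
  out <- list()
  for (d in sort(unique(c(names(old_by_d), names(new_by_d))))) {
    old_l <- old_by_d[[d]]; if (is.null(old_l)) old_l <- character(0)
    new_l <- new_by_d[[d]]; if (is.null(new_l)) new_l <- character(0)
    pos <- sort(intersect(setdiff(new_l, old_l), net_nodes))
    neg <- sort(setdiff(net_nodes, union(old_l, new_l)))
    if (!length(pos) || !length(neg)) {
      message("dropping disease ", d, ": ",
              if (!length(pos)) "no new positives in network"
              else "no negatives in network")
      next
    }
    out[[d]] <- list(positives = pos, negatives = neg,
                     seeds = sort(intersect(old_l, net_nodes)))
  }
  structure(out, class = "version_diff")
}

#' @export
print.version_diff <- function(x, ...) {
  cat(sprintf("Version-difference test set: %d evaluable diseases, %d positives\n",
              length(x), sum(vapply(x, function(d) length(d$positives), 0L))))
  invisible(x)
}

#' Mann-Whitney ROC AUC
#'
#' The probability that a random positive outscores a random negative,
#' with half-credit for ties, computed over all positive x negative pairs.
#' Equals the area under the empirical ROC curve.
#'
#' @param scores named numeric vector of scores (names are lncRNA ids).
#' @param positives,negatives disjoint non-empty character vectors of ids
#'   present in `scores`.
#' @return A number in \[0,1\].
#' @export
roc_auc <- function(scores, positives, negatives) {
  positives <- unique(positives); negatives <- unique(negatives)
  if (!length(positives) || !length(negatives)) {
    stop("both positives and negatives must be non-empty")
  }
  if (length(intersect(positives, negatives))) {
    stop("positives and negatives overlap")
  }
  miss <- setdiff(c(positives, negatives), names(scores))
  if (length(miss)) stop("unscored ids: ", paste(utils::head(miss, 5), collapse = ", "))
  sp <- scores[positives]; sn <- scores[negatives]
  r <- rank(c(sp, sn))  # average ranks handle ties with half-credit
  n_pos <- length(sp); n_neg <- length(sn)
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Two-snapshot network evaluation
#'
#' Runs the version-difference protocol end to end: per disease, seeds a
#' random walk on the old-snapshot lncRNAs and scores the newly added
#' (new-snapshot-only) lncRNAs against the never-associated network
#' lncRNAs. In `per_disease` mode one AUC is computed per disease over all
#' its positives; in `per_lncrna` mode each held-out lncRNA gets its own
#' AUC against the negatives and the per-disease value is their mean.
#' The headline number is the unweighted (macro) mean over evaluated
#' diseases.
#'
#' @param net an [assemble_network()] result.
#' @param old,new snapshot [association_table()]s (lncRNA left, disease
#'   right).
#' @param mode `"per_disease"` or `"per_lncrna"`.
#' @inheritParams rwr
#' @return A data frame of class `evaluation_report` with columns
#'   `disease`, `n_pos`, `n_neg`, `auc`, and attribute `macro_auc`.
#'   Diseases whose seeds are absent from the network are skipped with a
#'   message.
#' @export
evaluate_network <- function(net, old, new,
                             mode = c("per_disease", "per_lncrna"),
                             restart = 0.7, tol = 1e-10, max_iter = 1000L) {
  mode <- match.arg(mode)
  ts <- version_diff(old, new, net$nodes)
  diseases <- character(0); n_pos <- integer(0); n_neg <- integer(0)
  aucs <- numeric(0)
  for (d in names(ts)) {
    seeds <- ts[[d]]$seeds
    if (!length(seeds)) {
      message("skipping disease ", d, ": no old-snapshot seeds in network")
      next
    }
    p <- rwr(net, seeds, restart = restart, tol = tol, max_iter = max_iter)
    pos <- ts[[d]]$positives; neg <- ts[[d]]$negatives
    a <- if (mode == "per_disease") {
      roc_auc(p, pos, neg)
    } else {
      mean(vapply(pos, function(l) roc_auc(p, l, neg), 0))
    }
    diseases <- c(diseases, d)
    n_pos <- c(n_pos, length(pos)); n_neg <- c(n_neg, length(neg))
    aucs <- c(aucs, a)
  }
  rep <- data.frame(disease = diseases, n_pos = n_pos, n_neg = n_neg,
                    auc = aucs, stringsAsFactors = FALSE)
  structure(rep, macro_auc = if (nrow(rep)) mean(rep$auc) else NA_real_,
            mode = mode, class = c("evaluation_report", "data.frame"))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s): %d diseases, macro-average AUC %.4f\n",
              attr(x, "mode"), nrow(x), attr(x, "macro_auc")))
  NextMethod()
}

#' Write an evaluation report as TSV
#'
#' Columns `disease_id`, `n_pos`, `n_neg`, `auc`, with a final `AVERAGE`
#' row carrying the macro-average AUC.
#'
#' @param report an [evaluate_network()] result.
#' @param path output path.
#' @export
write_evaluation_report <- function(report, path) {
  rows <- c(paste("disease_id", "n_pos", "n_neg", "auc", sep = "\t"),
            paste(report$disease, report$n_pos, report$n_neg,
                  format_score(report$auc), sep = "\t"),
            paste("AVERAGE", sum(report$n_pos), sum(report$n_neg),
                  format_score(attr(report, "macro_auc")), sep = "\t"))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}
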