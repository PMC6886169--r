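#' Construct an association table
#'
#' A bipartite set of (left, right) identifier pairs with an optional
#' non-negative score per pair. This is the backbone container for all
#' lncRNA-disease, lncRNA-protein, lncRNA-mRNA and disease-gene inputs.
#' Pairs are de-duplicated; identifiers are whitespace-trimmed and compared
#' by exact string equality.
#'
#' @param left,right character vectors of identifiers (recycled to common
#'   length).
#' @param score optional numeric vector of finite, non-negative scores.
#' @param left_ns,right_ns namespace labels, each one of
#'   `"lncrna"`, `"disease"`, `"gene"`, `"protein"`, `"mrna"`.
#' @return A data frame of class `assoc_table` with columns `left`, `right`
#'   and (if given) `score`, plus `left_ns`/`right_ns` attributes.
#' @export
association_table <- function(left, right, score = NULL,
                              left_ns = "lncrna", right_ns = "disease") {
  check_namespace(left_ns)
  check_namespace(right_ns)
  left <- trimws(as.character(left))
  right <- trimws(as.character(right))
  if (length(left) != length(right)) {
    stop("'left' and 'right' must have the same length")
  }
  if (any(!nzchar(left)) || any(!nzchar(right))) {
    stop("empty identifiers are not allowed")
  }
  if (!is.null(score)) {
    score <- as.numeric(score)
    if (length(score) != length(left)) stop("'score' length mismatch")
    if (any(!is.finite(score)) || any(score < 0)) {
      stop("scores must be finite and >= 0")
    }
    tab <- data.frame(left = left, right = right, score = score,
                      stringsAsFactors = FALSE)
    tab <- tab[!duplicated(tab[, c("left", "right")]), , drop = FALSE]
  } else {
    tab <- data.frame(left = left, right = right, stringsAsFactors = FALSE)
    tab <- tab[!duplicated(tab), , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(tab, left_ns = left_ns, right_ns = right_ns,
            class = c("assoc_table", "data.frame"))
}

check_namespace <- function(ns) {
  ok <- c("lncrna", "disease", "gene", "protein", "mrna")
  if (!is.character(ns) || length(ns) != 1L || !ns %in% ok) {
    stop("namespace must be one of: ", paste(ok, collapse = ", "))
  }
  invisible(ns)
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("Association table: %s -> %s, %d pairs%s\n",
              attr(x, "left_ns"), attr(x, "right_ns"), nrow(x),
              if ("score" %in% names(x)) " (scored)" else ""))
  NextMethod()
}

# split non-comment, non-blank lines of a TSV into fields, tracking line numbers
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE), lineno = keep)
}

#' Read an association table from a TSV file
#'
#' Expects 2 or 3 tab-separated columns: `left_id<TAB>right_id[<TAB>score]`.
#' Lines starting with `#` and blank lines are ignored. Duplicate pairs are
#' dropped. Rows with a wrong column count or an unparsable score raise an
#' error naming the offending line.
#'
#' @param path path to a UTF-8 TSV file.
#' @inheritParams association_table
#' @return An [association_table()].
#' @export
read_association_table <- function(path, left_ns = "lncrna",
                                   right_ns = "disease") {
  parsed <- read_tsv_lines(path)
  if (length(parsed$fields) == 0L) {
    warning("empty association file: ", path)
    return(association_table(character(), character(),
                             left_ns = left_ns, right_ns = right_ns))
  }
  nf <- lengths(parsed$fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop(sprintf("%s: expected 2 or 3 tab-separated columns at line %d (got %d)",
                 path, parsed$lineno[bad[1]], nf[bad[1]]))
  }
  left <- vapply(parsed$fields, `[`, "", 1L)
  right <- vapply(parsed$fields, `[`, "", 2L)
  score <- NULL
  if (any(nf == 3L)) {
    raw <- vapply(parsed$fields, function(f) if (length(f) >= 3L) f[3] else NA_character_, "")
    score <- suppressWarnings(as.numeric(raw))
    badsc <- which(!is.na(raw) & is.na(score))
    if (length(badsc)) {
      stop(sprintf("%s: unparsable score '%s' at line %d",
                   path, raw[badsc[1]], parsed$lineno[badsc[1]]))
    }
    score[is.na(score)] <- 0
  }
  message(sprintf("read %d rows from %s", length(left), path))
  association_table(left, right, score, left_ns = left_ns, right_ns = right_ns)
}

#' Write an association table as TSV
#'
#' Rows are written in a deterministic (sorted) order so identical tables
#' produce byte-identical files.
#'
#' @param tab an [association_table()].
#' @param path output path.
#' @export
write_association_table <- function(tab, path) {
  stopifnot(inherits(tab, "assoc_table"))
  ord <- order(tab$left, tab$right)
  tab <- tab[ord, , drop = FALSE]
  cols <- if ("score" %in% names(tab)) {
    paste(tab$left, tab$right, format_score(tab$score), sep = "\t")
  } else {
    paste(tab$left, tab$right, sep = "\t")
  }
  writeLines(cols, path, useBytes = TRUE)
  invisible(path)
}

format_score <- function(x) sprintf("%.15g", x)

#' Construct a gene/protein/mRNA link set
#'
#' An undirected weighted link set over one namespace. Links are stored in a
#' single orientation (lexicographically smaller id first); self-links are
#' dropped; duplicate links keep their maximum score. Scores must lie in
#' \[0,1\].
#'
#' @param a,b character vectors of endpoint identifiers.
#' @param score numeric scores in \[0,1\].
#' @param namespace one of `"gene"`, `"protein"`, `"mrna"`.
#' @return An object of class `gene_links`: a data frame with columns
#'   `a`, `b`, `score` and an adjacency-list attribute used for fast
#'   relevance lookups.
#' @export
gene_link_set <- function(a, b, score, namespace = "gene") {
  if (!namespace %in% c("gene", "protein", "mrna")) {
    stop("link namespace must be gene, protein or mrna")
  }
  a <- trimws(as.character(a)); b <- trimws(as.character(b))
  score <- as.numeric(score)
  stopifnot(length(a) == length(b), length(a) == length(score))
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1)) {
    stop("link scores must lie in [0,1]")
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  df <- data.frame(a = lo, b = hi, score = score, stringsAsFactors = FALSE)
  if (nrow(df)) {
    # duplicates keep max score
    key <- paste(df$a, df$b, sep = "\r")
    df <- df[order(key, -df$score), , drop = FALSE]
    df <- df[!duplicated(paste(df$a, df$b, sep = "\r")), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, namespace = namespace, adjacency = build_adjacency(df),
            class = c("gene_links", "data.frame"))
}

build_adjacency <- function(df) {
  adj <- new.env(parent = emptyenv())
  if (nrow(df)) {
    nodes <- c(df$a, df$b)
    nbrs <- c(df$b, df$a)
    sc <- c(df$score, df$score)
    sp <- split(seq_along(nodes), nodes)
    for (n in names(sp)) {
      v <- sc[sp[[n]]]
      names(v) <- nbrs[sp[[n]]]
      assign(n, v, envir = adj)
    }
  }
  adj
}

# named numeric vector of neighbors of `node` (empty if none)
link_neighbors <- function(links, node) {
  adj <- attr(links, "adjacency")
  if (!is.null(adj) && exists(node, envir = adj, inherits = FALSE)) {
    get(node, envir = adj, inherits = FALSE)
  } else {
    stats::setNames(numeric(0), character(0))
  }
}

#' Read a weighted link set from TSV
#'
#' Three tab-separated columns: `id_a<TAB>id_b<TAB>score`. If any score in
#' the file exceeds 1 the whole file is taken to be on the STRING-style
#' 0-1000 integer scale and every score is divided by 1000, so that all
#' scores downstream are comparable with \[0,1\] similarities;
#' already-fractional files pass through unchanged.
#'
#' @inheritParams read_association_table
#' @inheritParams gene_link_set
#' @return A [gene_link_set()].
#' @export
read_gene_links <- function(path, namespace = "gene") {
  parsed <- read_tsv_lines(path)
  if (length(parsed$fields) == 0L) {
    warning("empty link file: ", path)
    return(gene_link_set(character(), character(), numeric(), namespace))
  }
  nf <- lengths(parsed$fields)
  bad <- which(nf != 3L)
  if (length(bad)) {
    stop(sprintf("%s: expected 3 tab-separated columns at line %d (got %d)",
                 path, parsed$lineno[bad[1]], nf[bad[1]]))
  }
  a <- vapply(parsed$fields, `[`, "", 1L)
  b <- vapply(parsed$fields, `[`, "", 2L)
  score <- suppressWarnings(as.numeric(vapply(parsed$fields, `[`, "", 3L)))
  badsc <- which(is.na(score))
  if (length(badsc)) {
    stop(sprintf("%s: unparsable score at line %d", path, parsed$lineno[badsc[1]]))
  }
  if (any(score > 1)) score <- score / 1000
  gene_link_set(a, b, score, namespace)
}

#' Write a link set as TSV
#' @param links a [gene_link_set()].
#' @param path output path.
#' @export
write_gene_links <- function(links, path) {
  stopifnot(inherits(links, "gene_links"))
  df <- links[order(links$a, links$b), , drop = FALSE]
  writeLines(paste(df$a, df$b, format_score(df$score), sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}

#' Construct a disease ontology
#'
#' A DAG of disease terms connected by IS_A (child to parent) edges, with
#' optional per-term direct gene annotations. Acyclicity is verified on
#' construction.
#'
#' @param terms character vector of term identifiers.
#' @param children,parents character vectors describing child -> parent
#'   IS_A edges (same length).
#' @return An object of class `disease_ontology` with elements `terms`,
#'   `parents` (named list), `children` (named list), `annotations` and
#'   `propagated` (both named lists of gene-id character vectors; empty
#'   until [propagate_annotations()] is called).
#' @export
disease_ontology <- function(terms, children = character(),
                             parents = character()) {
  terms <- unique(trimws(as.character(terms)))
  children <- trimws(as.character(children))
  parents <- trimws(as.character(parents))
  stopifnot(length(children) == length(parents))
  terms <- unique(c(terms, children, parents))
  if (any(!nzchar(terms))) stop("empty term identifiers are not allowed")
  if (any(children == parents)) stop("self IS_A edges are not allowed")
  edge_key <- paste(children, parents, sep = "\r")
  keep <- !duplicated(edge_key)
  children <- children[keep]; parents <- parents[keep]
  par_list <- lapply(stats::setNames(terms, terms), function(t) {
    sort(parents[children == t])
  })
  chl_list <- lapply(stats::setNames(terms, terms), function(t) {
    sort(children[parents == t])
  })
  onto <- structure(
    list(terms = sort(terms), parents = par_list, children = chl_list,
         annotations = stats::setNames(vector("list", length(terms)), terms),
         propagated = stats::setNames(vector("list", length(terms)), terms)),
    class = "disease_ontology")
  cyc <- find_cycle(onto)
  if (!is.null(cyc)) {
    stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  onto
}

# depth-first search for a cycle; returns one cycle path or NULL
find_cycle <- function(onto) {
  color <- stats::setNames(rep(0L, length(onto$terms)), onto$terms)
  stack <- character()
  cycle <- NULL
  visit <- function(t) {
    if (!is.null(cycle)) return(invisible())
    color[t] <<- 1L
    stack <<- c(stack, t)
    for (p in onto$parents[[t]]) {
      if (color[p] == 1L) {
        i <- match(p, stack)
        cycle <<- c(stack[i:length(stack)], p)
        return(invisible())
      }
      if (color[p] == 0L) visit(p)
    }
    stack <<- stack[-length(stack)]
    color[t] <<- 2L
  }
  for (t in onto$terms) if (color[t] == 0L) visit(t)
  cycle
}

#' @export
print.disease_ontology <- function(x, ...) {
  n_edge <- sum(lengths(x$parents))
  n_ann <- sum(lengths(x$annotations) > 0)
  cat(sprintf("Disease ontology: %d terms, %d IS_A edges, %d annotated terms\n",
              length(x$terms), n_edge, n_ann))
  invisible(x)
}

#' Root terms of an ontology
#' @param onto a [disease_ontology()].
#' @return Character vector of terms with no parent.
#' @export
ontology_roots <- function(onto) {
  onto$terms[lengths(onto$parents[onto$terms]) == 0L]
}

#' Ancestors of a term (inclusive)
#'
#' A term counts as its own ancestor, as required for common-ancestor
#' queries.
#'
#' @param onto a [disease_ontology()].
#' @param term a term identifier.
#' @return Character vector of `term` and all terms reachable via IS_A.
#' @export
term_ancestors <- function(onto, term) {
  if (!term %in% onto$terms) stop("unknown term: ", term)
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(onto$parents[frontier],
                                      use.names = FALSE)), seen)
  }
  sort(unique(seen))
}

#' Descendants of a term (inclusive)
#' @inheritParams term_ancestors
#' @return Character vector of `term` and all terms that reach it via IS_A.
#' @export
term_descendants <- function(onto, term) {
  if (!term %in% onto$terms) stop("unknown term: ", term)
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(onto$children[frontier],
                                      use.names = FALSE)), seen)
  }
  sort(unique(seen))
}

#' Read a disease ontology from OBO or a child/parent edge list
#'
#' OBO input (detected by a `format-version:` header or a `[Term]` stanza)
#' is parsed for `id:`, `is_a:` and `is_obsolete:` tags only; obsolete terms
#' are dropped together with their edges. Otherwise the file is read as a
#' 2-column TSV of child/parent pairs. A cycle raises a hard error listing
#' one offending cycle.
#'
#' @param path path to an OBO 1.2 file or a 2-column TSV.
#' @return A [disease_ontology()].
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_obo <- any(grepl("^format-version:", lines)) || any(lines == "[Term]")
  if (is_obo) {
    read_obo(lines)
  } else {
    parsed <- read_tsv_lines(path)
    nf <- lengths(parsed$fields)
    bad <- which(nf != 2L)
    if (length(bad)) {
      stop(sprintf("%s: expected 2 tab-separated columns at line %d",
                   path, parsed$lineno[bad[1]]))
    }
    children <- vapply(parsed$fields, `[`, "", 1L)
    parents <- vapply(parsed$fields, `[`, "", 2L)
    disease_ontology(unique(c(children, parents)), children, parents)
  }
}

read_obo <- function(lines) {
  lines <- trimws(lines)
  stanza_starts <- which(lines == "[Term]")
  terms <- character(); children <- character(); parents <- character()
  for (i in seq_along(stanza_starts)) {
    from <- stanza_starts[i] + 1L
    to <- if (i < length(stanza_starts)) stanza_starts[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    # a non-Term stanza header ends the term block
    hdr <- grep("^\\[", block)
    if (length(hdr)) block <- block[seq_len(hdr[1] - 1L)]
    id <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE))
    if (length(id) != 1L) next
    obsolete <- any(grepl("^is_obsolete:\\s*true", block))
    if (obsolete) next
    isa <- sub("^is_a:\\s*", "", grep("^is_a:", block, value = TRUE))
    isa <- trimws(sub("!.*$", "", isa))  # strip trailing '! name' comments
    terms <- c(terms, id)
    children <- c(children, rep(id, length(isa)))
    parents <- c(parents, isa)
  }
  # edges to obsolete/unknown parents: keep only edges between retained terms
  keep <- parents %in% terms
  disease_ontology(terms, children[keep], parents[keep])
}

#' Attach and propagate disease-gene annotations
#'
#' Direct annotations are taken from a disease-gene association table and
#' propagated up the DAG: each term's propagated set is the union of direct
#' annotations over itself and all its descendants. Propagation gives every
#' ancestor term a well-defined gene set for information-content and MICA
#' computations.
#'
#' @param onto a [disease_ontology()].
#' @param disease_gene an [association_table()] with disease on the left and
#'   gene on the right.
#' @param unknown how to treat annotated diseases absent from the ontology:
#'   `"warn"` (skip with a warning) or `"error"`.
#' @return The ontology with `annotations` and `propagated` filled in.
#' @export
propagate_annotations <- function(onto, disease_gene,
                                  unknown = c("warn", "error")) {
  stopifnot(inherits(onto, "disease_ontology"),
            inherits(disease_gene, "assoc_table"))
  unknown <- match.arg(unknown)
  miss <- setdiff(unique(disease_gene$left), onto$terms)
  if (length(miss)) {
    msg <- paste0(length(miss), " annotated disease(s) missing from ontology: ",
                  paste(utils::head(miss, 5), collapse = ", "))
    if (unknown == "error") stop(msg)
    warning(msg, " -- skipped")
  }
  keep <- disease_gene$left %in% onto$terms
  direct <- lapply(split(disease_gene$right[keep], disease_gene$left[keep]),
                   function(g) sort(unique(g)))
  onto$annotations <- stats::setNames(vector("list", length(onto$terms)),
                                      onto$terms)
  onto$annotations[names(direct)] <- direct
  onto$annotations[vapply(onto$annotations, is.null, TRUE)] <-
    list(character(0))
  # bottom-up union in reverse topological order
  order <- topo_order(onto)
  prop <- onto$annotations
  for (t in rev(order)) {
    kids <- onto$children[[t]]
    if (length(kids)) {
      prop[[t]] <- sort(unique(c(prop[[t]],
                                 unlist(prop[kids], use.names = FALSE))))
    }
  }
  onto$propagated <- prop
  onto
}

# parents-after-children order (roots last)
topo_order <- function(onto) {
  indeg <- vapply(onto$children[onto$terms], length, 0L)  # children below
  out <- character(0)
  frontier <- onto$terms[indeg == 0L]
  remaining <- indeg
  while (length(frontier)) {
    t <- frontier[1]; frontier <- frontier[-1]
    out <- c(out, t)
    for (p in onto$parents[[t]]) {
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) frontier <- c(frontier, p)
    }
  }
  rev(out)  # roots first
}

#' Per-disease direct gene sets from an association table
#'
#' @param disease_gene an [association_table()] (disease left, gene right).
#' @return Named list mapping each disease to its sorted gene-id set.
#' @export
disease_gene_sets <- function(disease_gene) {
  stopifnot(inherits(disease_gene, "assoc_table"))
  lapply(split(disease_gene$right, disease_gene$left),
         function(g) sort(unique(g)))
}

#' Read an expression matrix from TSV
#'
#' First column lncRNA id, header row of sample names, values >= 0.
#' At least 3 samples are required for the Spearman-based expression
#' similarity.
#'
#' @inheritParams read_association_table
#' @return Numeric matrix, lncRNAs in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(path, ": expected lncRNA id column plus samples")
  ids <- trimws(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) stop(path, ": missing expression values")
  if (any(m < 0)) stop(path, ": expression values must be >= 0")
  if (ncol(m) < 3L) {
    warning(path, ": fewer than 3 samples; rank correlation unavailable")
  }
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with lncRNA rownames and sample colnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  header <- paste(c("lncrna_id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format_score(m[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}
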