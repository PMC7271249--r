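#' Build an ontology DAG from child-parent-relation triples
#'
#' Represents a GO-slim-like or MeSH-tree-like hierarchy as a directed
#' acyclic graph of \code{child -> parent} edges labelled with a relation
#' (\code{is_a}, \code{part_of}, ...). Acyclicity and referential
#' integrity (every parent is a known term) are checked at construction.
#'
#' @param edges Data frame with columns \code{child}, \code{parent},
#'   \code{relation}.
#' @param terms Optional full term universe; defaults to the union of the
#'   edge endpoints.
#' @return A list of class \code{ontology_dag} with elements \code{terms},
#'   \code{edges} and a precomputed child adjacency list.
#' @export
ontology_dag <- function(edges, terms = NULL) {
  need <- c("child", "parent", "relation")
  if (!all(need %in% names(edges))) {
    stop_format("ontology edges must have columns child, parent, relation")
  }
  edges[] <- lapply(edges, as.character)
  terms <- sort(unique(c(terms, edges$child, edges$parent)))
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[c("child", "parent")],
                                       directed = TRUE, vertices = terms)
    if (!igraph::is_dag(g)) stop_format("ontology contains a cycle")
  }
  children <- split(paste(edges$child, edges$relation, sep = "\r"), edges$parent)
  structure(list(terms = terms, edges = edges, children = children),
            class = "ontology_dag")
}

#' Read an ontology from a 3-column TSV
#'
#' Columns \code{child}, \code{parent}, \code{relation} (with header).
#'
#' @param path Path to the TSV.
#' @return An [ontology_dag()].
#' @export
read_ontology <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  ontology_dag(e)
}

#' Descendant closure of an ontology term
#'
#' The transitive closure of child terms, including the term itself,
#' following the configured relation labels downward. This is the closure
#' used to decide whether a gene annotated with a specific term also
#' matches a query for one of its ancestors.
#'
#' @param dag An [ontology_dag()].
#' @param term Term ID present in the DAG.
#' @param relations Relation labels followed (default \code{is_a} and
#'   \code{part_of}).
#' @return Character vector of term IDs.
#' @export
descendants <- function(dag, term, relations = c("is_a", "part_of")) {
  if (!term %in% dag$terms) stop_notfound("unknown ontology term: ", term)
  seen <- stats::setNames(logical(length(dag$terms)), dag$terms)
  seen[term] <- TRUE
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- character()
    for (t in frontier) {
      kids <- dag$children[[t]]
      if (is.null(kids)) next
      parts <- strsplit(kids, "\r", fixed = TRUE)
      keep <- vapply(parts, function(p) p[2] %in% relations, logical(1))
      nxt <- c(nxt, vapply(parts[keep], `[[`, character(1), 1))
    }
    nxt <- unique(nxt[!seen[nxt]])
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  sort(names(seen)[seen])
}

#' Read gene-term association table
#'
#' Two tab-separated columns \code{entrez}, \code{term} (with header).
#'
#' @param path Path to the TSV.
#' @return A list of class \code{gene_annotations} mapping Entrez ID
#'   (as character name) to its set of directly annotated terms.
#' @export
read_annotations <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("entrez", "term") %in% names(a))) {
    stop_format("annotation table must have columns entrez, term")
  }
  structure(lapply(split(a$term, a$entrez), unique), class = "gene_annotations")
}

#' Does an interaction carry an ontology term?
#'
#' An interaction is associated with a term when both interactors are
#' annotated with the term itself or with one of its descendants in the
#' hierarchy. A homodimer (self-interaction) requires its single gene to
#' carry the term.
#'
#' @param pair Length-2 vector of Entrez IDs.
#' @param annotations [read_annotations()] output (or any named list of
#'   term sets keyed by Entrez as character).
#' @param dag An [ontology_dag()].
#' @param term Queried term ID.
#' @param relations Relations followed by the descendant closure.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
interaction_has_term <- function(pair, annotations, dag, term,
                                 relations = c("is_a", "part_of")) {
  desc <- descendants(dag, term, relations)
  ann <- function(g) annotations[[as.character(g)]] %||% character()
  length(intersect(ann(pair[1]), desc)) > 0 &&
    length(intersect(ann(pair[2]), desc)) > 0
}

#' Read a gene x tissue TPM expression matrix
#'
#' TSV with a \code{gene} column of Entrez IDs followed by one numeric
#' column per tissue/cell-type context. TPM values must be nonnegative.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, rows named by Entrez ID, columns by context.
#' @export
read_expression <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(t)) stop_format("expression table must have a 'gene' column")
  m <- as.matrix(t[setdiff(names(t), "gene")])
  rownames(m) <- as.character(t$gene)
  if (any(m < 0)) stop_format("TPM values must be nonnegative")
  if (anyDuplicated(colnames(m))) stop_format("context labels must be unique")
  m
}

#' Presence calls from a TPM matrix
#'
#' A gene is called present in a context when its expression is at least
#' \code{threshold} TPM (inclusive; the conventional cutoff is 1 TPM).
#'
#' @param expr Matrix from [read_expression()].
#' @param threshold Nonnegative TPM cutoff; default
#'   [default_tpm_threshold()].
#' @return Logical matrix with the same dimnames.
#' @export
presence_calls <- function(expr, threshold = default_tpm_threshold()) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop_usage("TPM threshold must be a single nonnegative number")
  }
  expr >= threshold
}

#' Tissues in which an interaction can take place
#'
#' If the products of two genes interact and are both expressed in the
#' same tissue, the interaction is assumed to take place in that tissue.
#' Genes absent from the matrix are treated as present nowhere; a
#' homodimer's tissue set is its gene's own presence set.
#'
#' @param pair Length-2 vector of Entrez IDs.
#' @param calls Logical matrix from [presence_calls()].
#' @return Character vector of context labels.
#' @export
interaction_tissues <- function(pair, calls) {
  row_of <- function(g) {
    g <- as.character(g)
    if (g %in% rownames(calls)) calls[g, ] else
      stats::setNames(rep(FALSE, ncol(calls)), colnames(calls))
  }
  both <- row_of(pair[1]) & row_of(pair[2])
  colnames(calls)[both]
}
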