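#' Assemble a scored PPI network
#'
#' Builds the undirected reference network from scored interactions. Nodes
#' are the union of pair members, annotated with their identifiers (when a
#' mapping table is given), their degree (number of interaction partners,
#' a self-loop counting once), the mean confidence score of their incident
#' interactions, and receptor / transcription-factor role flags (when a
#' role table is given). Isolated proteins cannot occur: every node enters
#' through an interaction.
#'
#' @param scored A \code{scored_ppi} data frame from [rescore()].
#' @param idmap Optional [read_idmap()] table used to attach symbol, MGI
#'   and UniProt identifiers to nodes.
#' @param roles Optional [regulatory_roles()] used to flag receptors and
#'   transcription factors.
#' @return A list of class \code{ppi_network} with \code{nodes} and
#'   \code{edges} data frames.
#' @export
build_network <- function(scored, idmap = NULL, roles = NULL) {
  entrez <- sort(unique(c(scored$entrez_a, scored$entrez_b)))
  nodes <- data.frame(entrez = entrez, stringsAsFactors = FALSE)
  if (!is.null(idmap)) {
    hit <- match(entrez, idmap$entrez)
    nodes$symbol <- idmap$symbol[hit]
    nodes$mgi <- idmap$mgi[hit]
    nodes$uniprot <- idmap$uniprot[hit]
  } else {
    nodes$symbol <- rep(NA_character_, nrow(nodes))
    nodes$mgi <- rep(NA_character_, nrow(nodes))
    nodes$uniprot <- rep(NA_character_, nrow(nodes))
  }
  deg <- integer(length(entrez))
  ssum <- numeric(length(entrez))
  ia <- match(scored$entrez_a, entrez)
  ib <- match(scored$entrez_b, entrez)
  for (i in seq_len(nrow(scored))) {
    deg[ia[i]] <- deg[ia[i]] + 1L
    ssum[ia[i]] <- ssum[ia[i]] + scored$score[i]
    if (ib[i] != ia[i]) {          # self-loops count once
      deg[ib[i]] <- deg[ib[i]] + 1L
      ssum[ib[i]] <- ssum[ib[i]] + scored$score[i]
    }
  }
  nodes$degree <- deg
  nodes$mean_score <- ifelse(deg > 0, ssum / deg, NA_real_)
  nodes$receptor <- if (is.null(roles)) rep(FALSE, nrow(nodes)) else
    entrez %in% roles$receptors
  nodes$tf <- if (is.null(roles)) rep(FALSE, nrow(nodes)) else
    entrez %in% roles$transcription_factors
  structure(list(nodes = nodes, edges = scored), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI reference network:", nrow(x$nodes), "proteins,",
      nrow(x$edges), "scored interactions\n")
  invisible(x)
}

#' @export
summary.ppi_network <- function(object, ...) {
  lv <- if (nrow(object$edges) > 0) confidence_levels(object$edges$score) else
    c(medium = NA_real_, high = NA_real_)
  out <- list(n_proteins = nrow(object$nodes), n_interactions = nrow(object$edges),
              score_summary = summary(object$edges$score), levels = lv)
  class(out) <- "summary.ppi_network"
  out
}

#' @export
print.summary.ppi_network <- function(x, ...) {
  cat("PPI reference network\n")
  cat("  proteins:     ", x$n_proteins, "\n")
  cat("  interactions: ", x$n_interactions, "\n")
  cat(sprintf("  confidence levels (quartiles): medium %.2f, high %.2f\n",
              x$levels["medium"], x$levels["high"]))
  invisible(x)
}

# Resolve a user-supplied identifier to an Entrez ID. Resolution order on
# ambiguity: all-digit strings are Entrez, then exact symbol, MGI, UniProt.
resolve_protein <- function(net, id) {
  id <- trimws(as.character(id))
  nodes <- net$nodes
  if (grepl("^[0-9]+$", id)) {
    e <- as.integer(id)
    if (e %in% nodes$entrez) return(e)
    stop_notfound("protein not found: Entrez ", id)
  }
  for (column in c("symbol", "mgi", "uniprot")) {
    hit <- which(!is.na(nodes[[column]]) & nodes[[column]] == id)
    if (length(hit) == 1L) return(nodes$entrez[hit])
    if (length(hit) > 1L) {
      stop_notfound("ambiguous ", column, " '", id, "': candidates Entrez ",
                    paste(nodes$entrez[hit], collapse = ", "))
    }
  }
  stop_notfound("protein not found: ", id)
}

#' List the interaction partners of a protein
#'
#' Accepts any valid identifier (Entrez, symbol, MGI, UniProt) and returns
#' the partner table sorted by descending confidence score, with the
#' evidence behind each interaction (publications, techniques, species
#' with interacting homologs).
#'
#' @param net A [build_network()] object.
#' @param id Protein identifier.
#' @return Data frame with partner identifiers, \code{score} and evidence
#'   detail columns; zero rows when the protein has no partners.
#' @export
protein_query <- function(net, id) {
  e <- resolve_protein(net, id)
  edges <- net$edges
  inc <- which(edges$entrez_a == e | edges$entrez_b == e)
  partner <- ifelse(edges$entrez_a[inc] == e, edges$entrez_b[inc], edges$entrez_a[inc])
  hit <- match(partner, net$nodes$entrez)
  out <- data.frame(partner_entrez = partner,
                    partner_symbol = net$nodes$symbol[hit],
                    partner_mgi = net$nodes$mgi[hit],
                    partner_uniprot = net$nodes$uniprot[hit],
                    score = edges$score[inc],
                    stringsAsFactors = FALSE)
  out$publications <- edges$studies[inc]
  out$techniques <- edges$techniques[inc]
  out$interolog_species <- edges$interolog_species[inc]
  out <- out[order(-out$score, out$partner_entrez), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Options for subnetwork queries
#'
#' @param layers 0 to keep interactions within the input set only, 1 to
#'   include interactions between the input set and its first-level
#'   neighbors (default 1).
#' @param min_connections Keep a neighbor only if it interacts with at
#'   least this many proteins from the input set (default 1).
#' @param threshold Confidence cutoff in \code{[0, 1]} (inclusive) or one
#'   of the named presets \code{"medium"} / \code{"high"} (default 0).
#' @param type_filter Optional PSI-MI interaction-type codes; an edge must
#'   carry at least one of them.
#' @param tissue_filter Optional context label; both endpoints must be
#'   called present there.
#' @param term_filters Optional ontology term IDs; the interaction must
#'   carry every listed term.
#' @param include_neighbor_edges Whether edges among surviving first-level
#'   neighbors are included in layers = 1 output (default TRUE).
#' @return A list of class \code{query_options}.
#' @export
query_options <- function(layers = 1, min_connections = 1, threshold = 0,
                          type_filter = NULL, tissue_filter = NULL,
                          term_filters = NULL, include_neighbor_edges = TRUE) {
  if (!layers %in% c(0, 1)) stop_usage("layers must be 0 or 1")
  if (is.character(threshold)) {
    preset <- confidence_presets()
    if (!threshold %in% names(preset)) {
      stop_usage("named threshold must be one of: ",
                 paste(names(preset), collapse = ", "))
    }
    threshold <- unname(preset[threshold])
  }
  if (threshold < 0 || threshold > 1) stop_usage("threshold must lie in [0, 1]")
  if (min_connections < 1) stop_usage("min_connections must be >= 1")
  structure(list(layers = layers, min_connections = min_connections,
                 threshold = threshold, type_filter = type_filter,
                 tissue_filter = tissue_filter, term_filters = term_filters,
                 include_neighbor_edges = include_neighbor_edges),
            class = "query_options")
}

#' Construct a filtered subnetwork around a query set
#'
#' With \code{layers = 1} the result contains the interactions between the
#' input proteins and their first-level neighbors (neighbors must touch at
#' least \code{min_connections} input proteins), plus interactions among
#' the surviving neighbors; with \code{layers = 0} only interactions
#' within the input set. Explicitly queried pairs with no reported
#' interaction appear with the pseudo-score -1; pseudo rows are exempt
#' from the confidence filter and excluded from all graph statistics.
#' Confidence, interaction-type, tissue and functional-term filters are
#' applied as conjunctions.
#'
#' @param net A [build_network()] object.
#' @param proteins Character vector of protein identifiers (any accepted
#'   type); identifiers not present in the network are reported in the
#'   result's \code{unmatched} element.
#' @param pairs Optional 2-column matrix/data frame of explicitly queried
#'   pairs (identifiers); absent pairs get pseudo-score -1.
#' @param opts A [query_options()].
#' @param annotations,dag Needed when \code{term_filters} is set.
#' @param calls Presence-call matrix, needed when \code{tissue_filter} is
#'   set.
#' @return A list of class \code{ppi_subnetwork} with \code{edges} (scored
#'   rows plus logical \code{pseudo}), \code{nodes}, \code{input} (resolved
#'   Entrez IDs) and \code{unmatched}.
#' @export
network_query <- function(net, proteins = character(), pairs = NULL,
                          opts = query_options(), annotations = NULL,
                          dag = NULL, calls = NULL) {
  input <- integer()
  unmatched <- character()
  for (p in proteins) {
    e <- tryCatch(resolve_protein(net, p), ppiref_notfound_error = function(c) NA)
    if (is.na(e)) unmatched <- c(unmatched, p) else input <- c(input, e)
  }
  pseudo <- NULL
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- tryCatch(resolve_protein(net, pairs[i, 1]),
                     ppiref_notfound_error = function(c) NA_integer_)
      rb <- tryCatch(resolve_protein(net, pairs[i, 2]),
                     ppiref_notfound_error = function(c) NA_integer_)
      if (!is.na(ra)) input <- c(input, ra)
      if (!is.na(rb)) input <- c(input, rb)
      present <- !is.na(ra) && !is.na(rb) &&
        pair_key(ra, rb) %in% pair_key(net$edges$entrez_a, net$edges$entrez_b)
      if (!present) {
        pseudo <- rbind(pseudo, data.frame(
          id_a = pairs[i, 1], id_b = pairs[i, 2],
          entrez_a = ra, entrez_b = rb, stringsAsFactors = FALSE))
      }
    }
  }
  input <- unique(input)
  if (length(input) == 0L && is.null(pseudo)) {
    if (length(unmatched) > 0L) {
      stop_notfound("no resolvable proteins in the input: ",
                    paste(unmatched, collapse = ", "))
    }
    stop_usage("network_query: empty input")
  }

  edges <- net$edges
  in_a <- edges$entrez_a %in% input
  in_b <- edges$entrez_b %in% input
  if (opts$layers == 0) {
    sel_edges <- edges[in_a & in_b, , drop = FALSE]
  } else {
    touching <- edges[xor(in_a, in_b) | (in_a & in_b), , drop = FALSE]
    # neighbor -> number of distinct input proteins it interacts with
    nb_rows <- edges[xor(in_a, in_b), , drop = FALSE]
    nb <- ifelse(nb_rows$entrez_a %in% input, nb_rows$entrez_b, nb_rows$entrez_a)
    anchor <- ifelse(nb_rows$entrez_a %in% input, nb_rows$entrez_a, nb_rows$entrez_b)
    conn <- tapply(anchor, nb, function(v) length(unique(v)))
    kept_nb <- as.integer(names(conn)[conn >= opts$min_connections])
    selected <- union(input, kept_nb)
    keep <- (touching$entrez_a %in% selected) & (touching$entrez_b %in% selected)
    sel_edges <- touching[keep, , drop = FALSE]
    if (opts$include_neighbor_edges && length(kept_nb) > 0) {
      among <- edges[edges$entrez_a %in% kept_nb & edges$entrez_b %in% kept_nb, ,
                     drop = FALSE]
      sel_edges <- unique(rbind(sel_edges, among))
    }
  }

  sel_edges <- apply_edge_filters(sel_edges, opts, annotations, dag, calls)
  sel_edges$pseudo <- rep(FALSE, nrow(sel_edges))

  if (!is.null(pseudo)) {
    for (i in seq_len(nrow(pseudo))) {
      row <- sel_edges[0, , drop = FALSE]
      prow <- data.frame(entrez_a = pseudo$entrez_a[i], entrez_b = pseudo$entrez_b[i])
      prow$interaction_types <- list(character())
      prow$studies <- list(character())
      prow$techniques <- list(character())
      prow$interolog_species <- list(character())
      prow$score <- -1
      prow$s_s <- NA_real_; prow$s_o <- NA_real_; prow$s_t <- NA_real_
      prow$pseudo <- TRUE
      sel_edges <- rbind(sel_edges, prow[names(sel_edges)])
    }
  }
  rownames(sel_edges) <- NULL

  real <- sel_edges[!sel_edges$pseudo, , drop = FALSE]
  node_ids <- sort(unique(c(input, real$entrez_a, real$entrez_b)))
  nodes <- net$nodes[match(node_ids, net$nodes$entrez), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(edges = sel_edges, nodes = nodes, input = sort(input),
                 unmatched = unmatched),
            class = "ppi_subnetwork")
}

apply_edge_filters <- function(edges, opts, annotations, dag, calls) {
  if (nrow(edges) == 0L) return(edges)
  keep <- edges$score >= opts$threshold
  if (!is.null(opts$type_filter)) {
    keep <- keep & vapply(edges$interaction_types,
                          function(t) any(t %in% opts$type_filter), logical(1))
  }
  if (!is.null(opts$tissue_filter)) {
    if (is.null(calls)) stop_usage("tissue filter requires presence calls")
    keep <- keep & vapply(seq_len(nrow(edges)), function(i) {
      opts$tissue_filter %in%
        interaction_tissues(c(edges$entrez_a[i], edges$entrez_b[i]), calls)
    }, logical(1))
  }
  if (!is.null(opts$term_filters)) {
    if (is.null(annotations) || is.null(dag)) {
      stop_usage("term filter requires annotations and an ontology DAG")
    }
    for (term in opts$term_filters) {
      keep <- keep & vapply(seq_len(nrow(edges)), function(i) {
        interaction_has_term(c(edges$entrez_a[i], edges$entrez_b[i]),
                             annotations, dag, term)
      }, logical(1))
    }
  }
  edges[keep, , drop = FALSE]
}

#' @export
print.ppi_subnetwork <- function(x, ...) {
  np <- sum(x$edges$pseudo)
  cat("PPI subnetwork:", nrow(x$nodes), "proteins,",
      nrow(x$edges) - np, "interactions")
  if (np > 0) cat(",", np, "queried pair(s) absent (pseudo-score -1)")
  cat("\n")
  if (length(x$unmatched) > 0) {
    cat("  unmatched identifiers:", paste(x$unmatched, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply a confidence threshold to a network or subnetwork
#'
#' Keeps interactions whose score is at least the threshold (inclusive, so
#' a median-valued edge stays inside the medium-confidence set).
#' Pseudo-score -1 rows are user-requested absences, not evidence, and are
#' exempt.
#'
#' @param x A \code{ppi_network}, \code{ppi_subnetwork} or
#'   \code{scored_ppi} data frame.
#' @param threshold Cutoff in \code{[0, 1]} or preset name
#'   (\code{"medium"}, \code{"high"}).
#' @return Object of the same shape.
#' @export
filter_confidence <- function(x, threshold) {
  if (is.character(threshold)) {
    threshold <- unname(confidence_presets()[match.arg(threshold, c("medium", "high"))])
  }
  if (threshold < 0 || threshold > 1) stop_usage("threshold must lie in [0, 1]")
  if (inherits(x, "ppi_network")) {
    kept <- x$edges[x$edges$score >= threshold, , drop = FALSE]
    roles <- list(receptors = x$nodes$entrez[x$nodes$receptor],
                  transcription_factors = x$nodes$entrez[x$nodes$tf])
    idmap <- data.frame(provider_id = as.character(x$nodes$entrez),
                        entrez = x$nodes$entrez, symbol = x$nodes$symbol,
                        mgi = x$nodes$mgi, uniprot = x$nodes$uniprot,
                        stringsAsFactors = FALSE)
    return(build_network(kept, idmap = idmap, roles = roles))
  }
  if (inherits(x, "ppi_subnetwork")) {
    keep <- x$edges$pseudo | x$edges$score >= threshold
    x$edges <- x$edges[keep, , drop = FALSE]
    real <- x$edges[!x$edges$pseudo, , drop = FALSE]
    node_ids <- sort(unique(c(x$input, real$entrez_a, real$entrez_b)))
    x$nodes <- x$nodes[x$nodes$entrez %in% node_ids, , drop = FALSE]
    return(x)
  }
  x[x$score >= threshold, , drop = FALSE]
}

#' Annotate an interaction screen against the reference network
#'
#' Adds one column to a table of candidate pairs: the confidence score of
#' the pair when it is in the network, or -1 when it is not. Row order is
#' preserved.
#'
#' @param pairs A 2-column data frame/matrix of identifiers, or the path
#'   to a tab-, comma- or semicolon-separated file of pairs.
#' @param net A [build_network()] object.
#' @return The input pairs with an extra numeric \code{score} column.
#' @export
screen_annotate <- function(pairs, net) {
  if (is.character(pairs) && length(pairs) == 1L && file.exists(pairs)) {
    pairs <- read_pair_file(pairs)
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop_format("screen input must have two identifier columns")
  ekey <- pair_key(net$edges$entrez_a, net$edges$entrez_b)
  score <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- tryCatch(resolve_protein(net, pairs[i, 1]),
                  ppiref_notfound_error = function(c) NA_integer_)
    b <- tryCatch(resolve_protein(net, pairs[i, 2]),
                  ppiref_notfound_error = function(c) NA_integer_)
    if (is.na(a) || is.na(b)) return(-1)
    hit <- match(pair_key(a, b), ekey)
    if (is.na(hit)) -1 else net$edges$score[hit]
  }, numeric(1))
  out <- pairs[, 1:2]
  names(out) <- c("id_a", "id_b")
  out$score <- score
  out
}

# Screen files accept tab, comma or semicolon separators (one pair per line).
read_pair_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t,;]")
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    stop_format("cannot parse pair on line ", bad[1L], " of ", path)
  }
  data.frame(id_a = trimws(vapply(parts, `[[`, character(1), 1)),
             id_b = trimws(vapply(parts, `[[`, character(1), 2)),
             stringsAsFactors = FALSE)
}

#' Parse a REST-style protein list
#'
#' Splits a \code{proteins=} parameter on the separators \code{","},
#' \code{";"} and \code{"|"}. Tokens containing \code{":"} denote explicit
#' protein pairs (checked for presence and given pseudo-score -1 when
#' absent).
#'
#' @param x The raw parameter string.
#' @return List with \code{proteins} (character vector) and \code{pairs}
#'   (2-column matrix or NULL).
#' @export
parse_protein_input <- function(x) {
  tokens <- trimws(unlist(strsplit(x, "[,;|]")))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop_usage("empty protein list")
  is_pair <- grepl(":", tokens, fixed = TRUE)
  pairs <- NULL
  if (any(is_pair)) {
    pp <- strsplit(tokens[is_pair], ":", fixed = TRUE)
    if (any(lengths(pp) != 2L)) stop_usage("pair tokens must be 'A:B'")
    pairs <- cbind(trimws(vapply(pp, `[[`, character(1), 1)),
                   trimws(vapply(pp, `[[`, character(1), 2)))
  }
  list(proteins = tokens[!is_pair], pairs = pairs)
}

#' Export a subnetwork
#'
#' \code{tsv} writes the edge list with identifiers, scores and evidence;
#' \code{mitab} writes PSI-MITAB 2.5 lines that round-trip through
#' [parse_mitab()]; \code{json-graph} writes a nodes/edges JSON document
#' (including any directionality overlay attributes) in place of an
#' interactive visualization.
#'
#' @param subnet A \code{ppi_subnetwork} (or \code{ppi_network}).
#' @param path Output file path.
#' @param format One of \code{"tsv"}, \code{"mitab"}, \code{"json-graph"}.
#' @param overlay Optional [infer_direction()] overlay merged into the
#'   JSON edge attributes.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(subnet, path, format = c("tsv", "mitab", "json-graph"),
                           overlay = NULL) {
  if (length(format) != 1L || !format %in% c("tsv", "mitab", "json-graph")) {
    stop_usage("unknown export format: ", paste(format, collapse = "/"),
               " (use tsv, mitab or json-graph)")
  }
  edges <- subnet$edges
  nodes <- subnet$nodes
  sym <- stats::setNames(nodes$symbol, nodes$entrez)
  if (format == "tsv") {
    flat <- data.frame(
      entrez_a = edges$entrez_a, entrez_b = edges$entrez_b,
      symbol_a = unname(sym[as.character(edges$entrez_a)]),
      symbol_b = unname(sym[as.character(edges$entrez_b)]),
      score = edges$score,
      publications = vapply(edges$studies, paste, character(1), collapse = ","),
      techniques = vapply(edges$techniques, paste, character(1), collapse = ","),
      interolog_species = vapply(edges$interolog_species, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)
    utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "mitab") {
    real <- edges[!isTRUE_col(edges$pseudo), , drop = FALSE]
    lines <- vapply(seq_len(nrow(real)), function(i) {
      first_or <- function(v, fmt) if (length(v[[1]]) > 0) sprintf(fmt, v[[1]][1]) else "-"
      paste(
        paste0("entrez gene/locuslink:", real$entrez_a[i]),
        paste0("entrez gene/locuslink:", real$entrez_b[i]),
        "-", "-", "-", "-",
        first_or(real$techniques[i], 'psi-mi:"%s"(-)'),
        "-",
        first_or(real$studies[i], "%s"),
        "taxid:10090(mouse)", "taxid:10090(mouse)",
        first_or(real$interaction_types[i], 'psi-mi:"%s"(-)'),
        "ppiref", "-",
        paste0("score:", format(real$score[i], digits = 15)),
        sep = "\t")
    }, character(1))
    writeLines(c(paste0("#", paste(paste0("col", 1:15), collapse = "\t")), lines), path)
  } else {
    jnodes <- lapply(seq_len(nrow(nodes)), function(i) {
      list(id = nodes$entrez[i], symbol = nodes$symbol[i],
           degree = nodes$degree[i], receptor = nodes$receptor[i],
           tf = nodes$tf[i])
    })
    okey <- if (!is.null(overlay)) pair_key(overlay$entrez_a, overlay$entrez_b)
    jedges <- lapply(seq_len(nrow(edges)), function(i) {
      e <- list(source = edges$entrez_a[i], target = edges$entrez_b[i],
                score = edges$score[i],
                pseudo = isTRUE(edges$pseudo[i]))
      if (!is.null(overlay)) {
        hit <- match(pair_key(edges$entrez_a[i], edges$entrez_b[i]), okey)
        if (!is.na(hit)) {
          e$orientation <- overlay$orientation[hit]
          e$on_path <- overlay$on_path[hit]
          e$effect <- overlay$effect[hit]
        }
      }
      e
    })
    jsonlite::write_json(list(nodes = jnodes, edges = jedges), path,
                         auto_unbox = TRUE, na = "null", digits = NA)
  }
  invisible(path)
}

isTRUE_col <- function(x) if (is.null(x)) FALSE else x %in% TRUE
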