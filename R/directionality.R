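#' Receptor / transcription-factor role lists
#'
#' Roles come from curated input lists and are never inferred; a protein
#' may be both a receptor and a transcription factor.
#'
#' @param receptors,transcription_factors Vectors of Entrez IDs.
#' @return A list of class \code{regulatory_roles}.
#' @export
regulatory_roles <- function(receptors = integer(), transcription_factors = integer()) {
  structure(list(receptors = unique(as.integer(receptors)),
                 transcription_factors = unique(as.integer(transcription_factors))),
            class = "regulatory_roles")
}

#' Read role lists from one-column TSVs
#'
#' Each file holds one Entrez ID per line under an \code{entrez} header.
#'
#' @param receptors_path,tfs_path File paths.
#' @return A [regulatory_roles()].
#' @export
read_roles <- function(receptors_path, tfs_path) {
  read_one <- function(p) as.integer(utils::read.delim(p)$entrez)
  regulatory_roles(read_one(receptors_path), read_one(tfs_path))
}

#' Read a source-target effect table
#'
#' TSV columns \code{source_entrez}, \code{target_entrez}, \code{effect}
#' (\code{activation} or \code{inhibition}). Keys are ordered: the same
#' pair may appear in both orientations with distinct effects.
#'
#' @param path Path to the TSV.
#' @return Data frame with integer source/target columns.
#' @export
read_effects <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_entrez", "target_entrez", "effect")
  if (!all(need %in% names(t))) {
    stop_format("effect table must have columns ", paste(need, collapse = ", "))
  }
  if (!all(t$effect %in% c("activation", "inhibition"))) {
    stop_format("effect must be 'activation' or 'inhibition'")
  }
  t$source_entrez <- as.integer(t$source_entrez)
  t$target_entrez <- as.integer(t$target_entrez)
  t[need]
}

#' Default endpoints for directionality inference
#'
#' Sources are the receptors present in the subnetwork; sinks the
#' transcription factors. Signals flow from the cell surface to the
#' nucleus, hence the receptor-to-TF orientation.
#'
#' @param subnet A \code{ppi_subnetwork} (or \code{ppi_network}).
#' @param roles A [regulatory_roles()].
#' @return List with \code{sources} and \code{sinks} (Entrez vectors).
#' @export
default_endpoints <- function(subnet, roles) {
  present <- subnet$nodes$entrez
  sources <- intersect(roles$receptors, present)
  sinks <- intersect(roles$transcription_factors, present)
  if (length(sources) == 0L) {
    stop_notfound("no receptors in the subnetwork; supply user-defined sources")
  }
  if (length(sinks) == 0L) {
    stop_notfound("no transcription factors in the subnetwork; supply user-defined sinks")
  }
  list(sources = sources, sinks = sinks)
}

#' Infer edge directionality from shortest paths
#'
#' For every (source, sink) pair, shortest paths through the subnetwork
#' are computed; an edge traversed by at least one such path is considered
#' directed with source-to-sink orientation. Edges traversed in both
#' directions across any of the paths conflict and are left undirected
#' (but flagged as on-path). Disconnected pairs contribute nothing.
#'
#' With \code{weighted = FALSE} all minimum-hop paths contribute. With
#' \code{weighted = TRUE} only the minimum-hop path with the highest
#' cumulative confidence score per (source, sink) pair contributes, ties
#' broken by the lexicographically smallest node-ID sequence so runs are
#' reproducible. \code{mode = "dijkstra"} instead treats each edge as
#' carrying cost \code{-log(score)} and uses true weighted shortest paths.
#'
#' @param subnet A \code{ppi_subnetwork} or \code{ppi_network}; pseudo
#'   rows are ignored.
#' @param sources,sinks Entrez ID vectors, subsets of the subnetwork
#'   nodes.
#' @param weighted Select the highest-confidence geodesic only.
#' @param mode \code{"hops"} (default: minimum-hop geodesics) or
#'   \code{"dijkstra"} (-log(score) edge costs).
#' @return Data frame of class \code{direction_overlay}: one row per
#'   subnetwork edge with \code{entrez_a}, \code{entrez_b} (a < b or a ==
#'   b), \code{orientation} in \code{a_to_b} / \code{b_to_a} /
#'   \code{undirected}, logical \code{on_path} and \code{effect}
#'   (\code{NA} until [overlay_effects()]).
#' @export
infer_direction <- function(subnet, sources, sinks, weighted = FALSE,
                            mode = c("hops", "dijkstra")) {
  mode <- match.arg(mode)
  edges <- subnet$edges
  if (!is.null(edges$pseudo)) edges <- edges[!edges$pseudo, , drop = FALSE]
  nodes <- sort(unique(c(edges$entrez_a, edges$entrez_b)))
  sources <- unique(as.integer(sources))
  sinks <- unique(as.integer(sinks))
  if (length(sources) == 0L || length(sinks) == 0L) {
    stop_usage("sources and sinks must be nonempty")
  }
  if (!all(sources %in% nodes)) {
    stop_notfound("source(s) not in subnetwork: ",
                  paste(setdiff(sources, nodes), collapse = ", "))
  }
  if (!all(sinks %in% nodes)) {
    stop_notfound("sink(s) not in subnetwork: ",
                  paste(setdiff(sinks, nodes), collapse = ", "))
  }

  simple <- edges[edges$entrez_a != edges$entrez_b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(simple$entrez_a),
               to = as.character(simple$entrez_b)),
    directed = FALSE, vertices = as.character(nodes))
  score_of <- stats::setNames(simple$score, pair_key(simple$entrez_a, simple$entrez_b))

  # forward[key] / backward[key]: was the edge traversed low->high / high->low
  forward <- backward <- stats::setNames(logical(length(score_of)), names(score_of))
  mark_path <- function(vs) {
    if (length(vs) < 2L) return(invisible())
    for (j in seq_len(length(vs) - 1L)) {
      a <- vs[j]; b <- vs[j + 1L]
      key <- pair_key(a, b)
      if (a <= b) forward[key] <<- TRUE else backward[key] <<- TRUE
    }
  }

  for (s in sources) {
    for (t in sinks) {
      if (s == t) next
      paths <- geodesics(g, as.character(s), as.character(t),
                         mode, score_of)
      if (length(paths) == 0L) next
      if (weighted && length(paths) > 1L) {
        paths <- list(best_confidence_path(paths, score_of))
      }
      for (p in paths) mark_path(p)
    }
  }

  ab <- sort_pair(edges$entrez_a, edges$entrez_b)
  key <- pair_key(ab[, 1], ab[, 2])
  orientation <- rep("undirected", nrow(edges))
  fw <- unname(forward[key]) %in% TRUE
  bw <- unname(backward[key]) %in% TRUE
  orientation[fw & !bw] <- "a_to_b"
  orientation[bw & !fw] <- "b_to_a"
  out <- data.frame(entrez_a = ab[, 1], entrez_b = ab[, 2],
                    orientation = orientation,
                    on_path = fw | bw,
                    effect = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("direction_overlay", "data.frame")
  out
}

# All geodesics between two vertices as integer node-ID sequences.
geodesics <- function(g, from, to, mode, score_of) {
  if (mode == "dijkstra") {
    w <- -log(pmax(unname(score_of[pair_key(
      igraph::ends(g, igraph::E(g))[, 1], igraph::ends(g, igraph::E(g))[, 2])]),
      .Machine$double.eps))
    res <- suppressWarnings(
      igraph::all_shortest_paths(g, from = from, to = to, weights = w))
  } else {
    res <- suppressWarnings(
      igraph::all_shortest_paths(g, from = from, to = to, weights = NA))
  }
  vpaths <- res$vpaths %||% res$res
  lapply(vpaths, function(v) as.integer(names(v)))
}

# Highest cumulative-confidence path; ties broken by the lexicographically
# smallest node-ID sequence.
best_confidence_path <- function(paths, score_of) {
  sums <- vapply(paths, function(p) {
    sum(unname(score_of[pair_key(p[-length(p)], p[-1])]))
  }, numeric(1))
  cand <- paths[sums >= max(sums) - 1e-12]
  if (length(cand) == 1L) return(cand[[1]])
  keys <- vapply(cand, function(p) paste(sprintf("%012d", p), collapse = "/"),
                 character(1))
  cand[[order(keys)[1L]]]
}

#' Overlay curated direction / effect annotations
#'
#' Known source-target relationships override the inferred orientation:
#' an edge with a table entry takes the table's orientation and effect
#' (activation or inhibition). Entries present in both orientations mark
#' the edge undirected with both effect labels. Table entries for pairs
#' absent from the overlay are ignored.
#'
#' @param overlay An [infer_direction()] result.
#' @param effects Table from [read_effects()].
#' @return The overlay with orientation/effect updated.
#' @export
overlay_effects <- function(overlay, effects) {
  if (nrow(effects) == 0L) return(overlay)
  okey <- pair_key(overlay$entrez_a, overlay$entrez_b)
  for (i in seq_len(nrow(overlay))) {
    a <- overlay$entrez_a[i]; b <- overlay$entrez_b[i]
    ab <- effects$source_entrez == a & effects$target_entrez == b
    ba <- effects$source_entrez == b & effects$target_entrez == a
    if (any(ab) && any(ba)) {
      overlay$orientation[i] <- "undirected"
      overlay$effect[i] <- paste(sort(unique(c(effects$effect[ab], effects$effect[ba]))),
                                 collapse = ",")
    } else if (any(ab)) {
      overlay$orientation[i] <- "a_to_b"
      overlay$effect[i] <- effects$effect[which(ab)[1L]]
    } else if (any(ba)) {
      overlay$orientation[i] <- "b_to_a"
      overlay$effect[i] <- effects$effect[which(ba)[1L]]
    }
  }
  overlay
}

#' Is a sink reachable from a source in a direction overlay?
#'
#' Follows oriented edges only (undirected on-path edges are traversable
#' in both directions). Convenience for checking that an inferred pathway
#' chain connects its endpoints.
#'
#' @param overlay An [infer_direction()] result.
#' @param from,to Entrez IDs.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
overlay_reachable <- function(overlay, from, to) {
  on <- overlay[overlay$on_path, , drop = FALSE]
  if (nrow(on) == 0L) return(FALSE)
  edges <- NULL
  for (i in seq_len(nrow(on))) {
    a <- as.character(on$entrez_a[i]); b <- as.character(on$entrez_b[i])
    edges <- switch(on$orientation[i],
                    a_to_b = rbind(edges, c(a, b)),
                    b_to_a = rbind(edges, c(b, a)),
                    undirected = rbind(edges, c(a, b), c(b, a)))
  }
  verts <- unique(c(edges[, 1], edges[, 2], as.character(from), as.character(to)))
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = TRUE,
                                     vertices = verts)
  d <- igraph::distances(g, v = as.character(from), to = as.character(to),
                         mode = "out")
  is.finite(d[1, 1])
}
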