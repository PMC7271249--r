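# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths
# (igraph geodesics, the logistic subscore, the set-union aggregation).

# Hand-write a MITAB 2.5 line from its pieces.
mitab_line <- function(id_a, id_b, method = 'psi-mi:"MI:0018"(two hybrid)',
                       pub = "pubmed:1234567",
                       type = 'psi-mi:"MI:0915"(physical association)',
                       source = "testdb") {
  paste(id_a, id_b, "-", "-", "-", "-", method, "-", pub,
        "taxid:10090(mouse)", "taxid:10090(mouse)", type, source, "-", "-",
        sep = "\t")
}

write_mitab_fixture <- function(lines, path = tempfile(fileext = ".mitab")) {
  writeLines(c("#header line", lines), path)
  path
}

write_idmap_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# All simple paths between s and t by depth-first enumeration; keeps only
# the minimum-hop ones.
oracle_min_paths <- function(edges, s, t) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges$entrez_a[i]); b <- as.character(edges$entrez_b[i])
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  found <- list()
  walk <- function(path) {
    head <- path[length(path)]
    if (head == as.character(t)) {
      found[[length(found) + 1L]] <<- as.integer(path)
      return(invisible())
    }
    for (nxt in adj[[head]]) {
      if (!nxt %in% path) walk(c(path, nxt))
    }
  }
  if (!as.character(s) %in% names(adj) || !as.character(t) %in% names(adj)) {
    if (s != t) return(list())
  }
  walk(as.character(s))
  if (length(found) == 0L) return(list())
  len <- lengths(found)
  found[len == min(len)]
}

# Exhaustive orientation oracle: enumerate all minimum-hop paths per
# (source, sink) pair, optionally restrict to the highest score-sum path
# (lexicographic node-sequence tie-break), then apply the conflict rule.
oracle_orient <- function(edges, sources, sinks, weighted = FALSE) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  score_of <- stats::setNames(edges$score, key(edges$entrez_a, edges$entrez_b))
  fw <- bw <- character()
  for (s in sources) {
    for (t in sinks) {
      if (s == t) next
      paths <- oracle_min_paths(edges, s, t)
      if (length(paths) == 0L) next
      if (weighted && length(paths) > 1L) {
        sums <- vapply(paths, function(p) {
          sum(score_of[key(p[-length(p)], p[-1])])
        }, numeric(1))
        best <- paths[sums >= max(sums) - 1e-12]
        if (length(best) > 1L) {
          ord <- order(vapply(best, function(p)
            paste(sprintf("%012d", p), collapse = "."), character(1)))
          best <- best[ord[1L]]
        }
        paths <- best
      }
      for (p in paths) {
        for (j in seq_len(length(p) - 1L)) {
          a <- p[j]; b <- p[j + 1L]
          if (a <= b) fw <- c(fw, key(a, b)) else bw <- c(bw, key(a, b))
        }
      }
    }
  }
  k <- key(edges$entrez_a, edges$entrez_b)
  orientation <- rep("undirected", nrow(edges))
  orientation[k %in% fw & !k %in% bw] <- "a_to_b"
  orientation[k %in% bw & !k %in% fw] <- "b_to_a"
  data.frame(entrez_a = pmin(edges$entrez_a, edges$entrez_b),
             entrez_b = pmax(edges$entrez_a, edges$entrez_b),
             orientation = orientation,
             on_path = k %in% fw | k %in% bw,
             stringsAsFactors = FALSE)
}

# Random connected-ish scored edge list over n nodes.
random_scored_edges <- function(n_nodes, n_edges) {
  ids <- 1000L + seq_len(n_nodes)
  a <- sample(ids, n_edges, replace = TRUE)
  b <- sample(ids, n_edges, replace = TRUE)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  df <- unique(data.frame(entrez_a = pmin(a, b), entrez_b = pmax(a, b)))
  df$score <- round(stats::runif(nrow(df), 0.05, 0.95), 3)
  df
}

# Random DAG over n terms: each non-root picks parents among earlier terms.
random_dag_edges <- function(n_terms, p_extra = 0.2) {
  terms <- sprintf("T%03d", seq_len(n_terms))
  out <- NULL
  for (i in 2:n_terms) {
    parents <- sample(seq_len(i - 1L),
                      min(i - 1L, 1L + stats::rbinom(1, 2, p_extra)))
    out <- rbind(out, data.frame(child = terms[i], parent = terms[parents],
                                 relation = "is_a", stringsAsFactors = FALSE))
  }
  out
}

# Reachability-by-DFS descendant oracle over a child->parent edge list.
oracle_descendants <- function(edges, term) {
  kids_of <- split(edges$child, edges$parent)
  seen <- term
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(kids_of[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# A tiny scored bundle set built by hand (no aggregation involved).
make_bundles <- function(pairs, studies, techniques, species = NULL) {
  out <- data.frame(entrez_a = pmin(pairs[, 1], pairs[, 2]),
                    entrez_b = pmax(pairs[, 1], pairs[, 2]))
  out$interaction_types <- rep(list("MI:0915"), nrow(out))
  out$studies <- studies
  out$techniques <- techniques
  out$interolog_species <- if (is.null(species)) rep(list(character()), nrow(out)) else species
  class(out) <- c("evidence_bundles", "data.frame")
  out
}

hippo_dir <- function() {
  d <- system.file("extdata", "hippo", package = "ppiref")
  if (nzchar(d)) d else {
    tmp <- file.path(tempdir(), "hippo-fixture")
    if (!dir.exists(tmp)) hippo_fixture(tmp)
    tmp
  }
}

# Minimal scored edge table around explicit pairs/scores.
as_scored <- function(df) {
  df$interaction_types <- rep(list("MI:0915"), nrow(df))
  df$studies <- rep(list("pubmed:1"), nrow(df))
  df$techniques <- rep(list("MI:0018"), nrow(df))
  df$interolog_species <- rep(list(character()), nrow(df))
  df$s_s <- rep(NA_real_, nrow(df))
  df$s_o <- rep(NA_real_, nrow(df))
  df$s_t <- rep(NA_real_, nrow(df))
  class(df) <- c("scored_ppi", "data.frame")
  df
}

net_from_edges <- function(df, idmap = NULL, roles = NULL) {
  build_network(as_scored(df), idmap = idmap, roles = roles)
}

# sample() without the scalar-x surprise (sample(5, 1) draws from 1:5).
resample <- function(x, n) x[sample.int(length(x), n)]
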