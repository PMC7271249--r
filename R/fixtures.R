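#' Specification for a synthetic input corpus
#'
#' Describes the shape of a seeded synthetic input set: a provider-style
#' MITAB file with controllable duplicate and unmappable-identifier rates,
#' the matching identifier map, interolog support, a technique-reliability
#' table, a small ontology with gene annotations, a TPM expression matrix
#' and role/effect tables. The same seed and spec always produce
#' byte-identical files.
#'
#' @param seed Integer RNG seed.
#' @param n_proteins Number of proteins in the universe.
#' @param n_interactions Number of distinct true interacting pairs.
#' @param duplicate_rate Fraction of evidence rows duplicated verbatim.
#' @param unmappable_rate Fraction of rows whose interactor identifiers are
#'   replaced with identifiers absent from the map (split roughly 45/45/10
#'   between A-only, B-only and both).
#' @param study_lambda Studies per pair are \code{1 + Poisson(study_lambda)}.
#' @param technique_pool Reliability table ([default_reliability()] shape)
#'   from which per-pair techniques are drawn.
#' @param max_techniques Max distinct techniques per pair.
#' @param interolog_rate Fraction of true pairs given cross-species
#'   support.
#' @param max_interolog_species Max supporting non-mouse taxa per pair.
#' @param n_tissues Number of expression contexts.
#' @param presence_prob Probability a gene is expressed (>= 1 TPM) in a
#'   context.
#' @param ontology_depth,ontology_branching Shape of the generated term
#'   tree.
#' @return A list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1, n_proteins = 60, n_interactions = 120,
                         duplicate_rate = 0.1, unmappable_rate = 0.1,
                         study_lambda = 1,
                         technique_pool = default_reliability(),
                         max_techniques = 3,
                         interolog_rate = 0.4, max_interolog_species = 3,
                         n_tissues = 6, presence_prob = 0.5,
                         ontology_depth = 3, ontology_branching = 3) {
  rates <- c(duplicate_rate, unmappable_rate, interolog_rate, presence_prob)
  if (any(rates < 0 | rates > 1)) stop_usage("rates must lie in [0, 1]")
  structure(list(seed = as.integer(seed), n_proteins = n_proteins,
                 n_interactions = n_interactions,
                 duplicate_rate = duplicate_rate,
                 unmappable_rate = unmappable_rate,
                 study_lambda = study_lambda,
                 technique_pool = technique_pool,
                 max_techniques = max_techniques,
                 interolog_rate = interolog_rate,
                 max_interolog_species = max_interolog_species,
                 n_tissues = n_tissues, presence_prob = presence_prob,
                 ontology_depth = ontology_depth,
                 ontology_branching = ontology_branching),
            class = "fixture_spec")
}

#' Generate a synthetic input corpus
#'
#' Writes every input file the pipeline consumes, plus a ground-truth
#' sidecar (the true pair list with its evidence tallies and the expected
#' discard counts) computed by direct bookkeeping during generation, so
#' the ingest/score path can be checked against it without circularity.
#'
#' Files written: \code{interactions.mitab}, \code{idmap.tsv},
#' \code{interologs.tsv}, \code{reliability.tsv}, \code{ontology.tsv},
#' \code{annotations.tsv}, \code{expression.tsv}, \code{receptors.tsv},
#' \code{tfs.tsv}, \code{effects.tsv}, \code{truth_bundles.tsv},
#' \code{truth_summary.json}, \code{manifest.json}.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if missing).
#' @return \code{outdir}, invisibly.
#' @export
generate_corpus <- function(spec, outdir) {
  if (!inherits(spec, "fixture_spec")) stop_usage("spec must be a fixture_spec()")
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop_format("cannot create output directory: ", outdir)
  }
  set.seed(spec$seed)

  n <- spec$n_proteins
  prot <- data.frame(
    entrez = 100000L + seq_len(n),
    symbol = sprintf("Gn%04d", seq_len(n)),
    mgi = sprintf("MGI:88%05d", seq_len(n)),
    uniprot = sprintf("P%05d", 10000L + seq_len(n)),
    stringsAsFactors = FALSE)
  prot$provider_id <- paste0("uniprotkb:", prot$uniprot)

  # distinct unordered pairs (self-interactions possible but rare)
  keys <- character(0)
  pairs <- NULL
  attempts <- 0L
  while (length(keys) < spec$n_interactions && attempts < 200L) {
    a <- sample.int(n, spec$n_interactions, replace = TRUE)
    b <- sample.int(n, spec$n_interactions, replace = TRUE)
    ab <- sort_pair(prot$entrez[a], prot$entrez[b])
    cand <- unique(rbind(pairs, ab))
    pairs <- cand
    keys <- pair_key(pairs[, 1], pairs[, 2])
    attempts <- attempts + 1L
  }
  pairs <- pairs[seq_len(min(nrow(pairs), spec$n_interactions)), , drop = FALSE]
  npair <- nrow(pairs)

  pool <- spec$technique_pool$mi_code
  types <- default_interaction_types()
  study_counter <- 0L
  rows <- vector("list", npair)
  truth <- vector("list", npair)
  for (i in seq_len(npair)) {
    ns <- 1L + stats::rpois(1, spec$study_lambda)
    studies <- sprintf("pubmed:%07d", 9000000L + study_counter + seq_len(ns))
    study_counter <- study_counter + ns
    kt <- sample.int(min(spec$max_techniques, length(pool)), 1)
    techs <- sample(pool, kt)
    type <- sample(types, 1)
    row_tech <- techs[(seq_len(ns) - 1L) %% kt + 1L]
    pa <- prot$provider_id[match(pairs[i, 1], prot$entrez)]
    pb <- prot$provider_id[match(pairs[i, 2], prot$entrez)]
    rows[[i]] <- data.frame(id_a = pa, id_b = pb, method = row_tech,
                            pub = studies, type = type,
                            stringsAsFactors = FALSE)
    truth[[i]] <- list(entrez_a = pairs[i, 1], entrez_b = pairs[i, 2],
                       studies = sort(studies), techniques = sort(unique(techs)),
                       types = type)
  }
  rows <- do.call(rbind, rows)

  n_dup <- round(spec$duplicate_rate * nrow(rows))
  if (n_dup > 0) rows <- rbind(rows, rows[sample.int(nrow(rows), n_dup, replace = TRUE), ])

  n_bad <- round(spec$unmappable_rate * nrow(rows))
  discard <- c(unmapped_a = 0L, unmapped_b = 0L, unmapped_both = 0L)
  rows$bad <- FALSE
  if (n_bad > 0) {
    which_bad <- sample.int(nrow(rows), n_bad)
    side <- sample(c("a", "b", "both"), n_bad, replace = TRUE,
                   prob = c(0.45, 0.45, 0.1))
    bad_id <- function(k) sprintf("uniprotkb:XBAD%04d", k)
    for (j in seq_along(which_bad)) {
      r <- which_bad[j]
      if (side[j] %in% c("a", "both")) rows$id_a[r] <- bad_id(j)
      if (side[j] %in% c("b", "both")) rows$id_b[r] <- bad_id(j + 100000L)
      discard[paste0("unmapped_", side[j])] <- discard[paste0("unmapped_", side[j])] + 1L
    }
    rows$bad[which_bad] <- TRUE
  }
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]

  # truth bundles from the generator's own bookkeeping: group surviving
  # (mappable) rows by pair and take set unions
  lut <- stats::setNames(prot$entrez, prot$provider_id)
  ok <- !rows$bad
  tb_key <- pair_key(lut[rows$id_a[ok]], lut[rows$id_b[ok]])
  grp <- split(which(ok), tb_key)
  truth_df <- data.frame(
    entrez_a = as.integer(vapply(strsplit(names(grp), "|", fixed = TRUE), `[[`, character(1), 1)),
    entrez_b = as.integer(vapply(strsplit(names(grp), "|", fixed = TRUE), `[[`, character(1), 2)))
  truth_df$studies <- vapply(grp, function(i) paste(sort(unique(rows$pub[i])), collapse = ","), character(1))
  truth_df$techniques <- vapply(grp, function(i) paste(sort(unique(rows$method[i])), collapse = ","), character(1))
  truth_df$interaction_types <- vapply(grp, function(i) paste(sort(unique(rows$type[i])), collapse = ","), character(1))
  truth_df <- truth_df[order(truth_df$entrez_a, truth_df$entrez_b), ]

  # interologs over the true pairs
  taxa_pool <- c("9606", "559292", "7227", "6239", "10116")
  has_il <- stats::runif(nrow(truth_df)) < spec$interolog_rate
  il_taxa <- vapply(seq_len(nrow(truth_df)), function(i) {
    if (!has_il[i]) return("")
    k <- sample.int(spec$max_interolog_species, 1)
    paste(sort(sample(taxa_pool, k)), collapse = ",")
  }, character(1))
  truth_df$interolog_species <- il_taxa
  interologs <- truth_df[has_il, c("entrez_a", "entrez_b")]
  interologs$taxa <- il_taxa[has_il]

  # ontology: rooted tree of the requested depth/branching
  terms <- "T00001"
  edges <- NULL
  frontier <- terms
  counter <- 1L
  for (d in seq_len(spec$ontology_depth)) {
    nxt <- character()
    for (p in frontier) {
      for (k in seq_len(spec$ontology_branching)) {
        counter <- counter + 1L
        child <- sprintf("T%05d", counter)
        rel <- if (stats::runif(1) < 0.2) "part_of" else "is_a"
        edges <- rbind(edges, data.frame(child = child, parent = p,
                                         relation = rel, stringsAsFactors = FALSE))
        nxt <- c(nxt, child)
      }
    }
    frontier <- nxt
    terms <- c(terms, nxt)
  }
  ann <- data.frame(
    entrez = rep(prot$entrez, each = 2),
    term = sample(terms, 2 * n, replace = TRUE),
    stringsAsFactors = FALSE)
  ann <- unique(ann)

  tissues <- sprintf("tissue_%02d", seq_len(spec$n_tissues))
  tpm <- matrix(0, nrow = n, ncol = spec$n_tissues,
                dimnames = list(prot$entrez, tissues))
  present <- matrix(stats::runif(n * spec$n_tissues) < spec$presence_prob,
                    nrow = n)
  tpm[present] <- round(stats::runif(sum(present), 1, 120), 2)
  tpm[!present] <- round(stats::runif(sum(!present), 0, 0.9), 3)

  receptors <- sort(sample(prot$entrez, max(1L, round(0.1 * n))))
  tfs <- sort(sample(setdiff(prot$entrez, receptors), max(1L, round(0.1 * n))))
  n_eff <- min(10L, nrow(truth_df))
  eff_idx <- sample.int(nrow(truth_df), n_eff)
  flip <- stats::runif(n_eff) < 0.5
  effects <- data.frame(
    source_entrez = ifelse(flip, truth_df$entrez_b[eff_idx], truth_df$entrez_a[eff_idx]),
    target_entrez = ifelse(flip, truth_df$entrez_a[eff_idx], truth_df$entrez_b[eff_idx]),
    effect = sample(c("activation", "inhibition"), n_eff, replace = TRUE),
    stringsAsFactors = FALSE)

  # ---- write everything ----
  p <- function(f) file.path(outdir, f)
  write_mitab_rows(rows, p("interactions.mitab"))
  utils::write.table(prot[c("provider_id", "entrez", "symbol", "mgi", "uniprot")],
                     p("idmap.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(interologs, p("interologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(spec$technique_pool, p("reliability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(edges, p("ontology.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann, p("annotations.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expr_out <- data.frame(gene = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(expr_out, p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(entrez = receptors), p("receptors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(entrez = tfs), p("tfs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(effects, p("effects.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth_df, p("truth_bundles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_rows_total = nrow(rows),
                            discards = as.list(discard),
                            n_true_pairs = nrow(truth_df)),
                       p("truth_summary.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(files = list.files(outdir),
                            spec = unclass(spec)[setdiff(names(spec), "technique_pool")]),
                       p("manifest.json"), auto_unbox = TRUE)
  invisible(outdir)
}

# Compose 15-column PSI-MITAB 2.5 lines from generator rows.
write_mitab_rows <- function(rows, path) {
  method_name <- c("MI:0077" = "nuclear magnetic resonance",
                   "MI:0067" = "light scattering", "MI:0018" = "two hybrid",
                   "MI:0019" = "coimmunoprecipitation",
                   "MI:0428" = "imaging technique", "MI:1060" = "rnai")
  type_name <- c("MI:0914" = "association", "MI:0915" = "physical association",
                 "MI:0407" = "direct interaction", "MI:0403" = "colocalization")
  nm <- function(code, tab) {
    v <- tab[code]
    ifelse(is.na(v), "-", v)
  }
  lines <- paste(
    rows$id_a, rows$id_b, "-", "-", "-", "-",
    sprintf('psi-mi:"%s"(%s)', rows$method, nm(rows$method, method_name)),
    "-", rows$pub,
    "taxid:10090(mouse)", "taxid:10090(mouse)",
    sprintf('psi-mi:"%s"(%s)', rows$type, nm(rows$type, type_name)),
    "synthetic-provider", "-", "-",
    sep = "\t")
  header <- paste0("#ID(s) interactor A\tID(s) interactor B\tAlt. ID(s) A\t",
                   "Alt. ID(s) B\tAlias(es) A\tAlias(es) B\t",
                   "Interaction detection method(s)\tPublication 1st author(s)\t",
                   "Publication Identifier(s)\tTaxid A\tTaxid B\t",
                   "Interaction type(s)\tSource database(s)\t",
                   "Interaction identifier(s)\tConfidence value(s)")
  writeLines(c(header, lines), path)
}

#' Run the full ingest-and-score pipeline on a corpus directory
#'
#' Convenience wrapper chaining [parse_mitab()],
#' [filter_interaction_types()], [map_and_discard()],
#' [aggregate_evidence()], [attach_interologs()] and [rescore()] over the
#' file layout written by [generate_corpus()] or [hippo_fixture()].
#'
#' @param dir Corpus directory.
#' @param config A [score_config()]; by default the corpus reliability
#'   table is used with the standard weights and rates.
#' @return List with \code{scored} (a \code{scored_ppi}), \code{network}
#'   (a \code{ppi_network} with identifiers and roles attached),
#'   \code{report} (discard tally) and \code{idmap}.
#' @export
build_reference <- function(dir, config = NULL) {
  rows <- parse_mitab(file.path(dir, "interactions.mitab"))
  rows <- filter_interaction_types(rows)
  idmap <- read_idmap(file.path(dir, "idmap.tsv"))
  md <- map_and_discard(rows, idmap)
  bundles <- aggregate_evidence(md$kept)
  il_path <- file.path(dir, "interologs.tsv")
  if (file.exists(il_path)) {
    bundles <- attach_interologs(bundles, read_interologs(il_path))
  }
  if (is.null(config)) {
    rel_path <- file.path(dir, "reliability.tsv")
    rel <- if (file.exists(rel_path)) read_reliability(rel_path) else default_reliability()
    config <- score_config(reliability = rel)
  }
  scored <- rescore(bundles, config)
  roles <- NULL
  rp <- file.path(dir, "receptors.tsv"); tp <- file.path(dir, "tfs.tsv")
  if (file.exists(rp) && file.exists(tp)) roles <- read_roles(rp, tp)
  net <- build_network(scored, idmap = idmap, roles = roles)
  list(scored = scored, network = net, report = md$report, idmap = idmap)
}
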