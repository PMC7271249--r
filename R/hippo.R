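#' Write the packaged Hippo-pathway fixture
#'
#' A small, fully deterministic corpus around the core Hippo signaling
#' cascade in mouse early development: Stk4 (Mst1) in complex with Sav1
#' phosphorylates Lats2, which phosphorylates Yap1 and Wwtr1 (Taz); when
#' Hippo signaling is weak, nuclear Yap1 activates Tead4 and drives
#' trophectoderm specification. The fixture carries two expression
#' contexts, \code{"trophoblast"} and \code{"stem cell"}: Tead4 is called
#' present only in the trophoblast context, so the Yap1-Tead4 interaction
#' exists in the trophoblast subnetwork but not in the stem-cell one.
#' Role files flag Tead4 as a transcription factor and list Stk4 as the
#' source endpoint (a synthetic role given to the upstream kinase so that
#' default endpoint selection works out of the box). Gene symbols and
#' Entrez IDs are the real ones; all accessions, publication IDs and
#' expression values are synthetic.
#'
#' The same file layout as [generate_corpus()] is written (minus the
#' truth sidecar). A pre-generated copy ships under
#' \code{system.file("extdata", "hippo", package = "ppiref")}.
#'
#' @param outdir Output directory (created if missing).
#' @return \code{outdir}, invisibly.
#' @examples
#' dir <- tempfile()
#' hippo_fixture(dir)
#' ref <- build_reference(dir)
#' summary(ref$network)
#' @export
hippo_fixture <- function(outdir) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop_format("cannot create output directory: ", outdir)
  }
  genes <- data.frame(
    symbol = c("Stk4", "Sav1", "Lats2", "Yap1", "Wwtr1", "Tead4"),
    entrez = c(58231L, 64010L, 50523L, 22601L, 97064L, 21679L),
    stringsAsFactors = FALSE)
  genes$mgi <- sprintf("MGI:10%05d", seq_len(nrow(genes)))
  genes$uniprot <- sprintf("P9%04d", seq_len(nrow(genes)))
  genes$provider_id <- paste0("uniprotkb:", genes$uniprot)
  eid <- stats::setNames(genes$entrez, genes$symbol)
  pid <- stats::setNames(genes$provider_id, genes$symbol)

  edges <- rbind(
    c("Stk4", "Sav1"), c("Stk4", "Lats2"), c("Sav1", "Lats2"),
    c("Lats2", "Yap1"), c("Lats2", "Wwtr1"),
    c("Yap1", "Tead4"), c("Wwtr1", "Tead4"))

  # 3 studies x alternating two-hybrid / co-IP per edge: study sub-score
  # saturates (n = 3) and technique reliabilities sum to 10
  rows <- NULL
  pub <- 8000000L
  for (i in seq_len(nrow(edges))) {
    techs <- c("MI:0018", "MI:0019", "MI:0018")
    for (s in 1:3) {
      pub <- pub + 1L
      rows <- rbind(rows, data.frame(
        id_a = pid[edges[i, 1]], id_b = pid[edges[i, 2]],
        method = techs[s], pub = sprintf("pubmed:%07d", pub),
        type = "MI:0915", stringsAsFactors = FALSE))
    }
  }
  p <- function(f) file.path(outdir, f)
  write_mitab_rows(rows, p("interactions.mitab"))
  utils::write.table(genes[c("provider_id", "entrez", "symbol", "mgi", "uniprot")],
                     p("idmap.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  interologs <- data.frame(
    entrez_a = pmin(eid[edges[, 1]], eid[edges[, 2]]),
    entrez_b = pmax(eid[edges[, 1]], eid[edges[, 2]]),
    taxa = "9606", stringsAsFactors = FALSE)
  utils::write.table(interologs, p("interologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(default_reliability(), p("reliability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ontology <- data.frame(
    child = c("T00002", "T00003"), parent = c("T00001", "T00001"),
    relation = c("is_a", "is_a"), stringsAsFactors = FALSE)
  utils::write.table(ontology, p("ontology.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- rbind(
    data.frame(entrez = genes$entrez, term = "T00003", stringsAsFactors = FALSE),
    data.frame(entrez = c(eid["Stk4"], eid["Lats2"]), term = "T00002",
               stringsAsFactors = FALSE))
  utils::write.table(ann, p("annotations.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  expr <- data.frame(
    gene = genes$entrez,
    trophoblast = c(25, 18, 30, 40, 12, 22),
    `stem cell` = c(24, 17, 28, 38, 11, 0.2),
    check.names = FALSE)
  utils::write.table(expr, p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  utils::write.table(data.frame(entrez = eid["Stk4"]), p("receptors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(entrez = eid["Tead4"]), p("tfs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  effects <- data.frame(
    source_entrez = c(eid["Stk4"], eid["Lats2"], eid["Lats2"], eid["Yap1"]),
    target_entrez = c(eid["Lats2"], eid["Yap1"], eid["Wwtr1"], eid["Tead4"]),
    effect = c("activation", "inhibition", "inhibition", "activation"),
    stringsAsFactors = FALSE)
  utils::write.table(effects, p("effects.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(files = list.files(outdir), fixture = "hippo",
                            contexts = c("trophoblast", "stem cell")),
                       p("manifest.json"), auto_unbox = TRUE)
  invisible(outdir)
}
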