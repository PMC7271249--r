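#' Read a PSI-MITAB 2.5 interaction file
#'
#' Parses the 15-column tab-separated PSI-MITAB 2.5 format into one record
#' per interaction line. PSI-MI codes (detection method, interaction type)
#' are extracted from the parenthesised-term syntax, e.g.
#' \code{psi-mi:"MI:0915"(physical association)} becomes \code{"MI:0915"}.
#' Identifier and publication columns are reduced to their first
#' \code{database:accession} token; extra columns beyond the 15 mandatory
#' ones are ignored. Lines starting with \code{#} are treated as headers.
#'
#' @param path Path to a PSI-MITAB 2.5 file.
#' @return A data frame with columns \code{id_a}, \code{id_b},
#'   \code{detection_method}, \code{publication}, \code{taxid_a},
#'   \code{taxid_b}, \code{interaction_type}, \code{source_db}. Missing
#'   values carry the MITAB token \code{"-"}.
#' @examples
#' dir <- tempfile(); hippo_fixture(dir)
#' rows <- parse_mitab(file.path(dir, "interactions.mitab"))
#' head(rows)
#' @export
parse_mitab <- function(path) {
  if (!file.exists(path)) stop_format("cannot read MITAB file: ", path)
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(data_idx) == 0L) return(empty_mitab_rows())

  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15L)) {
    bad <- data_idx[which(nf < 15L)[1L]]
    stop_format("malformed MITAB line ", bad, ": expected >= 15 columns, got ",
                nf[which(nf < 15L)[1L]])
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  data.frame(
    id_a = first_token(col(1)),
    id_b = first_token(col(2)),
    detection_method = extract_mi(col(7)),
    publication = first_token(col(9)),
    taxid_a = extract_taxid(col(10)),
    taxid_b = extract_taxid(col(11)),
    interaction_type = extract_mi(col(12)),
    source_db = strip_mi_term(col(13)),
    stringsAsFactors = FALSE
  )
}

empty_mitab_rows <- function() {
  data.frame(id_a = character(), id_b = character(),
             detection_method = character(), publication = character(),
             taxid_a = character(), taxid_b = character(),
             interaction_type = character(), source_db = character(),
             stringsAsFactors = FALSE)
}

first_token <- function(x) sub("\\|.*$", "", x)

# Pull the first "MI:nnnn" code out of a MITAB controlled-vocabulary field;
# the missing-value token "-" passes through unchanged.
extract_mi <- function(x) {
  out <- rep("-", length(x))
  m <- regmatches(x, regexpr("MI:[0-9]{4}", x))
  has <- regexpr("MI:[0-9]{4}", x) > 0
  out[has] <- m
  out
}

extract_taxid <- function(x) {
  tok <- first_token(x)
  m <- regexpr("-?[0-9]+", tok)
  out <- rep("-", length(x))
  out[m > 0] <- regmatches(tok, m)
  out
}

# "psi-mi:"MI:0469"(IntAct)" -> "IntAct"; plain names pass through.
strip_mi_term <- function(x) {
  inner <- sub("^.*\\(([^)]*)\\)\\s*$", "\\1", x)
  ifelse(grepl("\\(", x), inner, x)
}

#' Default PSI-MI interaction-type categories kept during ingest
#'
#' Association (MI:0914), physical association (MI:0915), direct
#' interaction (MI:0407) and colocalization (MI:0403).
#'
#' @return Character vector of PSI-MI codes.
#' @export
default_interaction_types <- function() {
  c("MI:0914", "MI:0915", "MI:0407", "MI:0403")
}

#' Filter interaction records by PSI-MI interaction-type category
#'
#' Keeps rows whose interaction type is one of the allowed categories. When
#' an MI-ontology DAG is supplied, descendants of the allowed codes are
#' accepted too. Row order is preserved.
#'
#' @param rows Data frame from [parse_mitab()].
#' @param allowed Character vector of PSI-MI codes; defaults to
#'   [default_interaction_types()].
#' @param dag Optional [ontology_dag()] over MI codes used to expand
#'   \code{allowed} with its descendants.
#' @return The filtered data frame.
#' @export
filter_interaction_types <- function(rows, allowed = default_interaction_types(),
                                     dag = NULL) {
  if (!is.null(dag)) {
    allowed <- unique(unlist(lapply(intersect(allowed, dag$terms),
                                    function(t) descendants(dag, t))))
  }
  rows[rows$interaction_type %in% allowed, , drop = FALSE]
}

#' Read an identifier-mapping table
#'
#' Five tab-separated columns: \code{provider_id}, \code{entrez},
#' \code{symbol}, \code{mgi}, \code{uniprot}. Every row must carry a
#' positive Entrez ID.
#'
#' @param path Path to the mapping TSV (with header).
#' @return A data frame of class \code{ppi_idmap}.
#' @export
read_idmap <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("provider_id", "entrez", "symbol", "mgi", "uniprot")
  if (!all(need %in% names(m))) {
    stop_format("idmap must have columns: ", paste(need, collapse = ", "))
  }
  m$entrez <- suppressWarnings(as.integer(m$entrez))
  if (anyNA(m$entrez) || any(m$entrez <= 0)) {
    stop_format("idmap entrez IDs must all be positive integers")
  }
  class(m) <- c("ppi_idmap", "data.frame")
  m
}

#' Map provider identifiers to Entrez IDs and discard unmappable rows
#'
#' Interactions in which one or both interactors do not map to a valid
#' Entrez ID are discarded; the tally of discards is reported.
#'
#' @param rows Data frame from [parse_mitab()] (optionally filtered).
#' @param idmap Mapping table from [read_idmap()].
#' @return A list with \code{kept} (rows plus integer columns
#'   \code{entrez_a}, \code{entrez_b}) and \code{report}, a named integer
#'   vector counting rows discarded for \code{unmapped_a},
#'   \code{unmapped_b} and \code{unmapped_both}.
#' @export
map_and_discard <- function(rows, idmap) {
  lut <- stats::setNames(idmap$entrez, idmap$provider_id)
  ea <- unname(lut[rows$id_a])
  eb <- unname(lut[rows$id_b])
  miss_a <- is.na(ea)
  miss_b <- is.na(eb)
  report <- c(unmapped_a = sum(miss_a & !miss_b),
              unmapped_b = sum(!miss_a & miss_b),
              unmapped_both = sum(miss_a & miss_b))
  kept <- rows[!miss_a & !miss_b, , drop = FALSE]
  kept$entrez_a <- ea[!miss_a & !miss_b]
  kept$entrez_b <- eb[!miss_a & !miss_b]
  rownames(kept) <- NULL
  list(kept = kept, report = report)
}

#' Aggregate mapped interaction rows into per-pair evidence bundles
#'
#' Collapses rows to one bundle per unordered Entrez pair. Studies,
#' detection techniques and interaction types are the set unions over all
#' rows of that pair, so exact duplicates (same pair, same study, same
#' method) have no effect. The MITAB missing token \code{"-"} contributes
#' nothing to any evidence set. Isolated proteins cannot exist by
#' construction: every protein enters via a pair.
#'
#' @param rows Mapped rows from [map_and_discard()]\code{$kept}.
#' @return A data frame of class \code{evidence_bundles} with integer
#'   columns \code{entrez_a <= entrez_b} and list columns
#'   \code{interaction_types}, \code{studies}, \code{techniques},
#'   \code{interolog_species} (initially empty sets).
#' @export
aggregate_evidence <- function(rows) {
  if (nrow(rows) == 0L) return(empty_bundles())
  pk <- pair_key(rows$entrez_a, rows$entrez_b)
  idx <- split(seq_len(nrow(rows)), pk)
  keys <- names(idx)
  ab <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(entrez_a = as.integer(ab[, 1]),
                    entrez_b = as.integer(ab[, 2]))
  out$interaction_types <- unname(lapply(idx, function(i) evidence_union(rows$interaction_type[i])))
  out$studies <- unname(lapply(idx, function(i) evidence_union(rows$publication[i])))
  out$techniques <- unname(lapply(idx, function(i) evidence_union(rows$detection_method[i])))
  out$interolog_species <- rep(list(character()), nrow(out))
  out <- out[order(out$entrez_a, out$entrez_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("evidence_bundles", "data.frame")
  out
}

empty_bundles <- function() {
  out <- data.frame(entrez_a = integer(), entrez_b = integer())
  out$interaction_types <- list()
  out$studies <- list()
  out$techniques <- list()
  out$interolog_species <- list()
  class(out) <- c("evidence_bundles", "data.frame")
  out
}

#' Read an interolog-support table
#'
#' Tab-separated columns \code{entrez_a}, \code{entrez_b}, \code{taxa}
#' (comma-separated NCBI taxon IDs of non-mouse species in which homologs
#' of the pair also interact).
#'
#' @param path Path to the TSV (with header).
#' @param mouse_taxid Taxon excluded from every species set (default
#'   \code{"10090"}).
#' @return Data frame with integer pair columns and a list column
#'   \code{taxa}.
#' @export
read_interologs <- function(path, mouse_taxid = "10090") {
  t <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("entrez_a", "entrez_b", "taxa") %in% names(t))) {
    stop_format("interolog table must have columns entrez_a, entrez_b, taxa")
  }
  taxa <- lapply(strsplit(t$taxa, ","), function(v) {
    v <- trimws(v)
    sort(unique(v[nzchar(v) & v != mouse_taxid]))
  })
  data.frame(entrez_a = as.integer(t$entrez_a),
             entrez_b = as.integer(t$entrez_b)) -> out
  out$taxa <- taxa
  out
}

#' Attach cross-species interolog support to evidence bundles
#'
#' For each bundle, \code{interolog_species} becomes the taxon set recorded
#' for its pair in the table, or the empty set when the pair is absent.
#' All other evidence is unchanged.
#'
#' @param bundles [aggregate_evidence()] output.
#' @param interologs Table from [read_interologs()].
#' @return The bundles with \code{interolog_species} filled in.
#' @export
attach_interologs <- function(bundles, interologs) {
  if (nrow(bundles) == 0L) return(bundles)
  tkey <- pair_key(interologs$entrez_a, interologs$entrez_b)
  taxa <- lapply(split(interologs$taxa, tkey), function(x) evidence_union(x))
  bkey <- pair_key(bundles$entrez_a, bundles$entrez_b)
  hit <- match(bkey, names(taxa))
  bundles$interolog_species <- lapply(seq_along(bkey), function(i) {
    if (is.na(hit[i])) character() else taxa[[hit[i]]]
  })
  bundles
}

#' @export
print.evidence_bundles <- function(x, ...) {
  cat("Evidence bundles:", nrow(x), "protein pair(s)\n")
  if (nrow(x) > 0) {
    cat(sprintf("  studies per pair: median %g, max %g\n",
                stats::median(lengths(x$studies)), max(lengths(x$studies))))
    cat(sprintf("  pairs with interolog support: %d\n",
                sum(lengths(x$interolog_species) > 0)))
  }
  invisible(x)
}
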