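#' Default detection-technique reliability table
#'
#' Expert-assigned 0-10 quality weights for experimental PPI-detection
#' techniques, keyed by PSI-MI detection-method code. The shipped table
#' carries the three anchor classes: structure-resolving assays such as
#' nuclear magnetic resonance or light scattering (10), two-hybrid and
#' co-immunoprecipitation (5) and microscopy- or RNAi-based approaches (1).
#' A full provider table can be loaded with [read_reliability()] and passed
#' to [score_config()].
#'
#' @return Data frame with columns \code{mi_code}, \code{name},
#'   \code{reliability}.
#' @export
default_reliability <- function() {
  data.frame(
    mi_code = c("MI:0077", "MI:0067", "MI:0018", "MI:0019", "MI:0428", "MI:1060"),
    name = c("nuclear magnetic resonance", "light scattering",
             "two hybrid", "coimmunoprecipitation",
             "imaging technique (microscopy)", "rnai-based approach"),
    reliability = c(10, 10, 5, 5, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Read a technique-reliability table
#'
#' @param path TSV with header columns \code{mi_code}, \code{name},
#'   \code{reliability}; reliabilities must lie in \code{[0, 10]}.
#' @return Data frame in the same shape as [default_reliability()].
#' @export
read_reliability <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mi_code", "name", "reliability") %in% names(t))) {
    stop_format("reliability table must have columns mi_code, name, reliability")
  }
  t$reliability <- as.numeric(t$reliability)
  if (anyNA(t$reliability) || any(t$reliability < 0 | t$reliability > 10)) {
    stop_format("reliability values must lie in [0, 10]")
  }
  t[c("mi_code", "name", "reliability")]
}

#' Configuration of the confidence score
#'
#' Bundles the sub-score weights, the saturation rates and the technique
#' reliability table. Defaults follow the published calibration: weights
#' w_s = 0.6 (studies), w_o = 0.1 (interolog species), w_t = 0.3
#' (technique quality), chosen by a grid search in the sister human
#' database, and rates alpha_s = 1 (the study sub-score saturates near
#' n = 3), alpha_o = 1.5 (saturation near 2 species) and alpha_t = 0.5
#' (saturation once two mid-reliability techniques sum to ~10).
#'
#' @param w_s,w_o,w_t Nonnegative sub-score weights; must sum to 1.
#' @param alpha_s,alpha_o,alpha_t Positive saturation rates.
#' @param reliability Technique-reliability table
#'   ([default_reliability()] shape).
#' @param unknown_reliability Reliability assumed for detection-method
#'   codes missing from the table (default 1, the lowest anchor class); a
#'   warning is emitted when used.
#' @return A list of class \code{score_config}.
#' @export
score_config <- function(w_s = 0.6, w_o = 0.1, w_t = 0.3,
                         alpha_s = 1, alpha_o = 1.5, alpha_t = 0.5,
                         reliability = default_reliability(),
                         unknown_reliability = 1) {
  w <- c(w_s, w_o, w_t)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop_usage("score weights must be nonnegative")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop_usage("score weights must sum to 1 (got ", format(sum(w)), ")")
  }
  a <- c(alpha_s, alpha_o, alpha_t)
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop_usage("saturation rates alpha must be positive")
  }
  if (any(reliability$reliability < 0 | reliability$reliability > 10)) {
    stop_usage("reliability values must lie in [0, 10]")
  }
  structure(list(w_s = w_s, w_o = w_o, w_t = w_t,
                 alpha_s = alpha_s, alpha_o = alpha_o, alpha_t = alpha_t,
                 reliability = reliability,
                 unknown_reliability = unknown_reliability),
            class = "score_config")
}

#' Saturating evidence sub-score
#'
#' Maps a nonnegative evidence quantity n to \code{2 / (1 + exp(-alpha * n))
#' - 1}, a logistic transform into \code{[0, 1)} that is zero at n = 0,
#' strictly increasing in n and approaches 1 as evidence accumulates, with
#' \code{alpha} controlling how quickly it saturates.
#'
#' @param n Nonnegative evidence quantity (vectorised).
#' @param alpha Positive saturation rate.
#' @return Values in \code{[0, 1)}.
#' @examples
#' subscore(3, 1)    # study sub-score near saturation at three studies
#' subscore(10, 0.5) # technique sub-score for a reliability sum of 10
#' @export
subscore <- function(n, alpha) {
  if (any(!is.finite(n)) || any(n < 0)) stop_usage("subscore: n must be >= 0")
  if (!is.finite(alpha) || alpha <= 0) stop_usage("subscore: alpha must be > 0")
  2 / (1 + exp(-alpha * n)) - 1
}

#' Summed reliability of the distinct techniques supporting a pair
#'
#' The technique sub-score's evidence quantity: reliabilities are summed
#' once per distinct PSI-MI detection-method code, regardless of how many
#' studies used the technique. Codes absent from the table contribute the
#' configured fallback reliability, with a warning.
#'
#' @param techniques Character vector (or set) of PSI-MI codes.
#' @param config A [score_config()].
#' @return Nonnegative reliability sum.
#' @export
technique_evidence <- function(techniques, config = score_config()) {
  codes <- unique(techniques[techniques != "-" & nzchar(techniques)])
  if (length(codes) == 0L) return(0)
  lut <- stats::setNames(config$reliability$reliability, config$reliability$mi_code)
  r <- unname(lut[codes])
  if (anyNA(r)) {
    warning("unknown detection-method code(s) ",
            paste(codes[is.na(r)], collapse = ", "),
            "; assuming reliability ", config$unknown_reliability,
            call. = FALSE)
    r[is.na(r)] <- config$unknown_reliability
  }
  sum(r)
}

#' Confidence score of one evidence bundle
#'
#' The score is a weighted sum of three saturating sub-scores,
#' \code{S = w_s * s_s + w_o * s_o + w_t * s_t}, where the evidence
#' quantity is the number of supporting studies for s_s, the number of
#' non-mouse species with interacting homologs for s_o, and the summed
#' reliability of the distinct detection techniques for s_t.
#'
#' @param bundle One row of an \code{evidence_bundles} data frame (or any
#'   list with \code{studies}, \code{techniques}, \code{interolog_species}).
#' @param config A [score_config()].
#' @return Named numeric vector \code{c(score, s_s, s_o, s_t)}.
#' @export
confidence_score <- function(bundle, config = score_config()) {
  if (!inherits(config, "score_config")) {
    stop_usage("config must be created with score_config()")
  }
  studies <- unlist(bundle$studies, use.names = FALSE)
  species <- unlist(bundle$interolog_species, use.names = FALSE)
  techs <- unlist(bundle$techniques, use.names = FALSE)
  s_s <- subscore(length(unique(studies[studies != "-"])), config$alpha_s)
  s_o <- subscore(length(unique(species)), config$alpha_o)
  s_t <- subscore(technique_evidence(techs, config), config$alpha_t)
  c(score = config$w_s * s_s + config$w_o * s_o + config$w_t * s_t,
    s_s = s_s, s_o = s_o, s_t = s_t)
}

#' Score a set of evidence bundles
#'
#' Applies [confidence_score()] to every bundle. Deterministic and
#' order-independent; suitable for re-scoring with user-specified weights,
#' rates or reliability tables.
#'
#' @param bundles [aggregate_evidence()] output (interologs attached or
#'   not).
#' @param config A [score_config()].
#' @return Data frame of class \code{scored_ppi}: the bundle columns plus
#'   numeric \code{score}, \code{s_s}, \code{s_o}, \code{s_t}.
#' @export
rescore <- function(bundles, config = score_config()) {
  if (!inherits(config, "score_config")) {
    stop_usage("config must be created with score_config()")
  }
  n <- nrow(bundles)
  sc <- matrix(0, nrow = n, ncol = 4,
               dimnames = list(NULL, c("score", "s_s", "s_o", "s_t")))
  for (i in seq_len(n)) sc[i, ] <- confidence_score(bundles[i, ], config)
  out <- bundles
  out$score <- sc[, "score"]
  out$s_s <- sc[, "s_s"]
  out$s_o <- sc[, "s_o"]
  out$s_t <- sc[, "s_t"]
  class(out) <- c("scored_ppi", "data.frame")
  out
}

#' Quartile-based confidence levels of a score distribution
#'
#' The medium-confidence threshold is the median of the supplied scores and
#' the high-confidence threshold the upper quartile (linear-interpolation
#' quantiles). For the published reference snapshot these thresholds are
#' 0.53 and 0.6; use [confidence_presets()] for those constants.
#'
#' @param scores Numeric vector of confidence scores (nonempty).
#' @return Named vector \code{c(medium, high)}.
#' @export
confidence_levels <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop_usage("confidence_levels: no scores supplied")
  q <- stats::quantile(scores, c(0.5, 0.75), type = 7, names = FALSE)
  c(medium = q[1], high = q[2])
}

#' Published confidence-level presets
#'
#' Named thresholds from the reference score distribution: medium = median
#' (0.53), high = upper quartile (0.6).
#'
#' @return Named vector \code{c(medium = 0.53, high = 0.6)}.
#' @export
confidence_presets <- function() {
  c(medium = 0.53, high = 0.6)
}

#' Default TPM presence-call threshold
#'
#' A gene counts as present in a tissue when its expression is at least
#' this many transcripts per million.
#'
#' @return The threshold, 1 TPM.
#' @export
default_tpm_threshold <- function() 1

#' Read a flat key=value scoring configuration file
#'
#' Recognised keys: \code{w_s}, \code{w_o}, \code{w_t}, \code{alpha_s},
#' \code{alpha_o}, \code{alpha_t}, \code{reliability} (path to a
#' reliability TSV, resolved relative to the config file),
#' \code{unknown_reliability}. Missing keys keep their defaults.
#'
#' @param path Path to the config file; \code{NULL} returns the defaults.
#' @return A [score_config()].
#' @export
read_score_config <- function(path = NULL) {
  if (is.null(path)) return(score_config())
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop_format("config lines must be key=value")
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  known <- c("w_s", "w_o", "w_t", "alpha_s", "alpha_o", "alpha_t",
             "reliability", "unknown_reliability")
  if (any(!keys %in% known)) {
    stop_format("unknown config key(s): ",
                paste(setdiff(keys, known), collapse = ", "))
  }
  args <- list()
  for (i in seq_along(keys)) {
    if (keys[i] == "reliability") {
      rel_path <- vals[i]
      if (!file.exists(rel_path)) {
        rel_path <- file.path(dirname(path), vals[i])
      }
      args$reliability <- read_reliability(rel_path)
    } else {
      args[[keys[i]]] <- as.numeric(vals[i])
    }
  }
  do.call(score_config, args)
}

#' @export
print.score_config <- function(x, ...) {
  cat("Confidence-score configuration\n")
  cat(sprintf("  weights: w_s=%g (studies), w_o=%g (interologs), w_t=%g (techniques)\n",
              x$w_s, x$w_o, x$w_t))
  cat(sprintf("  rates:   alpha_s=%g, alpha_o=%g, alpha_t=%g\n",
              x$alpha_s, x$alpha_o, x$alpha_t))
  cat(sprintf("  reliability table: %d technique(s); unknown code fallback %g\n",
              nrow(x$reliability), x$unknown_reliability))
  invisible(x)
}

#' @export
print.scored_ppi <- function(x, ...) {
  cat("Scored interactions:", nrow(x), "pair(s)\n")
  if (nrow(x) > 0) {
    cat(sprintf("  score range: %.2f - %.2f (median %.2f)\n",
                min(x$score), max(x$score), stats::median(x$score)))
  }
  invisible(x)
}

#' Write / read scored interactions as TSV
#'
#' The on-disk form keeps the evidence sets as comma-joined strings in the
#' columns \code{interaction_types}, \code{studies}, \code{techniques},
#' \code{interolog_species}, so a scored network round-trips losslessly.
#'
#' @param scored A \code{scored_ppi} data frame.
#' @param path Output TSV path.
#' @return \code{write_scored} returns \code{path} invisibly;
#'   \code{read_scored} returns a \code{scored_ppi} data frame.
#' @export
write_scored <- function(scored, path) {
  flat <- data.frame(entrez_a = scored$entrez_a, entrez_b = scored$entrez_b,
                     score = scored$score, s_s = scored$s_s,
                     s_o = scored$s_o, s_t = scored$s_t,
                     interaction_types = vapply(scored$interaction_types, paste, character(1), collapse = ","),
                     studies = vapply(scored$studies, paste, character(1), collapse = ","),
                     techniques = vapply(scored$techniques, paste, character(1), collapse = ","),
                     interolog_species = vapply(scored$interolog_species, paste, character(1), collapse = ","),
                     stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scored
#' @export
read_scored <- function(path) {
  flat <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(entrez_a = "integer", entrez_b = "integer",
                                           interaction_types = "character",
                                           studies = "character",
                                           techniques = "character",
                                           interolog_species = "character"))
  split_set <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                  function(v) v[nzchar(v)])
  out <- flat[c("entrez_a", "entrez_b")]
  out$interaction_types <- split_set(flat$interaction_types)
  out$studies <- split_set(flat$studies)
  out$techniques <- split_set(flat$techniques)
  out$interolog_species <- split_set(flat$interolog_species)
  out$score <- flat$score
  out$s_s <- flat$s_s
  out$s_o <- flat$s_o
  out$s_t <- flat$s_t
  class(out) <- c("scored_ppi", "data.frame")
  out
}
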