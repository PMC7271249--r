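# Internal helpers shared across modules: classed conditions (the CLI maps
# them to exit codes) and unordered-pair canonicalisation.

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("ppiref_usage_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("ppiref_format_error", "error")))
}

stop_notfound <- function(...) {
  stop(errorCondition(paste0(...), class = c("ppiref_notfound_error", "error")))
}

# Canonical unordered-pair key: smaller Entrez first.
pair_key <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

sort_pair <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  cbind(entrez_a = pmin(a, b), entrez_b = pmax(a, b))
}

# Set union that drops the MITAB missing-value token and empties.
evidence_union <- function(values) {
  v <- unique(unlist(values, use.names = FALSE))
  v <- v[!is.na(v) & v != "" & v != "-"]
  sort(v)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
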