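## Entity tagging: pluggable tagger backends (a deterministic gazetteer
## backend ships with the package), gene alias normalization, and
## precision/recall/F1 scoring of taggers.

#' Build a gazetteer tagger backend
#'
#' Returns a tagger function (text -> mention data frame) that matches a
#' fixed surface-form dictionary case-insensitively at word boundaries.
#' Neural taggers can be plugged in behind the same contract: a function
#' taking the abstract text and returning a data frame with columns
#' `surface`, `start`, `end` (0-based half-open character offsets) and
#' `entity_type`.
#'
#' @param gazetteer Data frame with columns `surface` and `entity_type`
#'   (values among gene/disease/cell_type/pathway/other), or a path to a
#'   two-column TSV with those columns.
#' @return A function of one argument (`text`) usable as the `backend` of
#'   [tag_entities()].
#' @examples
#' gz <- data.frame(surface = c("IL15", "NK cells"),
#'                  entity_type = c("gene", "cell_type"))
#' tagger <- gazetteer_tagger(gz)
#' tagger("IL15 activates NK cells.")
#' @export
gazetteer_tagger <- function(gazetteer) {
  if (is.character(gazetteer) && length(gazetteer) == 1L) {
    gazetteer <- utils::read.delim(gazetteer, colClasses = "character",
                                   quote = "", stringsAsFactors = FALSE)
  }
  ## Generator output uses `name`; accept both spellings.
  if (is.null(gazetteer$surface) && !is.null(gazetteer$name)) {
    gazetteer$surface <- gazetteer$name
  }
  stopifnot(is.data.frame(gazetteer),
            all(c("surface", "entity_type") %in% names(gazetteer)))
  check_node_type(gazetteer$entity_type, "entity_type")
  surfaces <- gazetteer$surface
  types <- gazetteer$entity_type
  function(text) {
    out <- list()
    for (i in seq_along(surfaces)) {
      m <- gregexpr(surface_pattern(surfaces[[i]]), text,
                    perl = TRUE, ignore.case = TRUE)[[1L]]
      if (m[[1L]] == -1L) next
      len <- attr(m, "match.length")
      out[[length(out) + 1L]] <- data.frame(
        surface = substring(text, m, m + len - 1L),
        start = as.integer(m) - 1L,
        end = as.integer(m) + len - 1L,
        entity_type = types[[i]], stringsAsFactors = FALSE)
    }
    if (!length(out)) return(empty_mentions())
    do.call(rbind, out)
  }
}

empty_mentions <- function() {
  data.frame(surface = character(), start = integer(), end = integer(),
             entity_type = character(), normalized_id = character(),
             stringsAsFactors = FALSE)
}

#' Tag entity mentions in an abstract
#'
#' Runs a tagger backend over a record's text and post-processes the raw
#' mentions: offsets are validated against the text, mentions are sorted by
#' start offset, and overlapping mentions of the same entity type are
#' merged to the longest span (so "natural killer cell" beats the nested
#' "killer cell").  Gene mentions are normalized through `aliases` when an
#' alias table is supplied.
#'
#' @param record A single corpus record (one row of an `ickg_corpus`, or
#'   any list with `abstract_id` and `text`).
#' @param backend A tagger contract: function(text) -> mention data frame
#'   (see [gazetteer_tagger()]).
#' @param aliases Optional [alias_table()] used to fill `normalized_id`
#'   for gene mentions.
#' @return A data frame of mentions with columns `surface`, `start`, `end`
#'   (0-based, half-open), `entity_type`, `normalized_id`.
#' @export
tag_entities <- function(record, backend, aliases = NULL) {
  text <- as.character(record$text)
  if (!length(text) || is.na(text) || !nzchar(text)) return(empty_mentions())
  raw <- tryCatch(backend(text), error = function(e) {
    stop(sprintf("tagger backend failed on abstract %s: %s",
                 as.character(record$abstract_id), conditionMessage(e)),
         call. = FALSE)
  })
  if (is.null(raw) || !nrow(raw)) return(empty_mentions())
  stopifnot(all(c("surface", "start", "end", "entity_type") %in% names(raw)))
  check_node_type(raw$entity_type, "entity_type")
  bad <- raw$start < 0 | raw$end <= raw$start | raw$end > nchar(text)
  if (any(bad)) {
    ickg_validation_error(sprintf(
      "tagger returned %d mention(s) with offsets outside the text", sum(bad)))
  }
  ## Longest-match rule, per entity type: drop any mention overlapping a
  ## longer kept mention of the same type.
  keep <- logical(nrow(raw))
  for (tp in unique(raw$entity_type)) {
    idx <- which(raw$entity_type == tp)
    ord <- idx[order(-(raw$end[idx] - raw$start[idx]), raw$start[idx])]
    kept <- integer()
    for (i in ord) {
      overlaps <- any(raw$start[i] < raw$end[kept] & raw$end[i] > raw$start[kept])
      if (!overlaps) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  m <- raw[keep, , drop = FALSE]
  m <- m[order(m$start, m$end), , drop = FALSE]
  m$normalized_id <- NA_character_
  if (!is.null(aliases)) {
    is_gene <- m$entity_type == "gene"
    m$normalized_id[is_gene] <-
      vapply(m$surface[is_gene], normalize_gene, character(1), aliases = aliases)
  }
  rownames(m) <- NULL
  m
}

#' Build a gene alias table
#'
#' An alias table maps case-folded alias strings to canonical gene
#' symbols; canonical symbols always map to themselves.
#'
#' @param aliases Data frame with columns `alias` and `canonical`, or a
#'   path to a two-column TSV.
#' @return An object of class `alias_table`.
#' @examples
#' at <- alias_table(data.frame(alias = "p53", canonical = "TP53"))
#' normalize_gene("P53", at)
#' @export
alias_table <- function(aliases) {
  if (is.character(aliases) && length(aliases) == 1L) {
    aliases <- utils::read.delim(aliases, colClasses = "character",
                                 quote = "", stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(aliases),
            all(c("alias", "canonical") %in% names(aliases)))
  canonical <- toupper(aliases$canonical)
  map <- stats::setNames(canonical, tolower(aliases$alias))
  ## self-maps for every canonical symbol
  self <- stats::setNames(canonical, tolower(canonical))
  map <- c(map, self[!names(self) %in% names(map)])
  structure(list(map = map), class = "alias_table")
}

#' Normalize a gene surface form to its canonical symbol
#'
#' Case-insensitive lookup in an alias table; returns `NA` when no alias
#' matches (unknown gene).
#'
#' @param surface Character surface form.
#' @param aliases An [alias_table()].
#' @return Canonical symbol (uppercase) or `NA_character_`.
#' @export
normalize_gene <- function(surface, aliases) {
  if (is.null(aliases)) return(NA_character_)
  stopifnot(inherits(aliases, "alias_table"))
  hit <- aliases$map[tolower(surface)]
  if (is.na(hit)) NA_character_ else unname(hit)
}

#' Score predicted entity mentions against a gold standard
#'
#' Entity-level mode (default) counts a true positive when a predicted
#' mention matches a gold mention exactly in span and entity type.
#' Token-level mode labels each whitespace-delimited token of `text` by
#' any covering mention and scores (token, type) labels; it requires
#' `text`.  Precision = TP/(TP+FP), Recall = TP/(TP+FN), F1 their harmonic
#' mean (0 when TP = 0).
#'
#' @param predicted,gold Mention data frames as returned by
#'   [tag_entities()], referring to the same text.
#' @param mode `"entity"` or `"token"`.
#' @param text The underlying text (token mode only).
#' @return A list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
evaluate_ner <- function(predicted, gold, mode = c("entity", "token"),
                         text = NULL) {
  mode <- match.arg(mode)
  if (mode == "entity") {
    pk <- mention_keys(predicted)
    gk <- mention_keys(gold)
    tp <- length(intersect(pk, gk))
    fp <- length(setdiff(pk, gk))
    fn <- length(setdiff(gk, pk))
  } else {
    if (is.null(text)) ickg_validation_error("token mode requires `text`")
    pk <- token_labels(predicted, text)
    gk <- token_labels(gold, text)
    tp <- length(intersect(pk, gk))
    fp <- length(setdiff(pk, gk))
    fn <- length(setdiff(gk, pk))
  }
  prf(tp, fp, fn)
}

mention_keys <- function(m) {
  if (is.null(m) || !nrow(m)) return(character())
  unique(paste(m$start, m$end, m$entity_type, sep = ":"))
}

## (token index, type) labels: a token is labeled with a mention's type
## when the mention span overlaps the token span.
token_labels <- function(m, text) {
  toks <- gregexpr("\\S+", text)[[1L]]
  if (toks[[1L]] == -1L || is.null(m) || !nrow(m)) return(character())
  tstart <- as.integer(toks) - 1L
  tend <- tstart + attr(toks, "match.length")
  out <- character()
  for (i in seq_len(nrow(m))) {
    hit <- which(m$start[i] < tend & m$end[i] > tstart)
    out <- c(out, paste(hit, m$entity_type[i], sep = ":"))
  }
  unique(out)
}

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, tp = tp, fp = fp, fn = fn)
}
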