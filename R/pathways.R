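## Pathway / biomedical-concept phrase mining: grammar-rule candidate
## extraction behind a pluggable chunking contract, lexical filters
## (Levenshtein similarity to a vocabulary, biomedical suffixes and
## substrings), and an LLM-style refinement contract with a deterministic
## identity mock.

## Frozen English stop-word list (edge-stripping + single-token exclusion).
STOP_WORDS <- c(
  "a", "an", "the", "this", "that", "these", "those", "its", "their", "our",
  "his", "her", "your", "my", "some", "any", "each", "every", "no", "such",
  "other", "another", "both", "several", "various", "many", "few", "more",
  "most", "less", "least", "all", "results", "result", "findings", "finding",
  "study", "studies", "data", "analysis", "analyses", "method", "methods",
  "approach", "approaches", "role", "roles", "effect", "effects", "level",
  "levels", "number", "numbers", "group", "groups", "case", "cases",
  "report", "reports", "conclusion", "conclusions", "background", "aim",
  "aims", "objective", "objectives", "patient", "patients", "significant",
  "present", "novel", "new", "recent", "important", "potential", "different")

## Function words at which the rule-based chunker splits a sentence into
## candidate noun-phrase runs: auxiliaries, common verbs (incl. the
## relation trigger verbs), prepositions, conjunctions, pronouns.
CHUNK_BREAK_WORDS <- c(
  "is", "are", "was", "were", "be", "been", "being", "am",
  "has", "have", "had", "having", "do", "does", "did", "done",
  "can", "could", "may", "might", "must", "shall", "should", "will", "would",
  "of", "in", "on", "at", "by", "for", "with", "without", "from", "to",
  "into", "onto", "over", "under", "between", "among", "through", "via",
  "during", "after", "before", "within", "across", "against", "than", "as",
  "and", "or", "but", "nor", "while", "whereas", "because", "although",
  "that", "which", "who", "whom", "whose", "when", "where", "whether", "if",
  "we", "they", "it", "he", "she", "i", "you", "not", "also", "here", "thus",
  "therefore", "however", "moreover", "furthermore",
  "activates", "activate", "activated", "inhibits", "inhibit", "inhibited",
  "induces", "induce", "induced", "promotes", "promote", "promoted",
  "suppresses", "suppress", "suppressed", "enhances", "enhance", "enhanced",
  "upregulates", "upregulated", "downregulates", "downregulated",
  "represses", "repress", "repressed", "blocks", "block", "blocked",
  "increases", "increase", "increased", "decreases", "decrease", "decreased",
  "shows", "show", "showed", "shown", "demonstrates", "demonstrate",
  "demonstrated", "reveals", "reveal", "revealed", "suggests", "suggest",
  "suggested", "indicates", "indicate", "indicated", "remains", "remain",
  "remained", "plays", "play", "played", "regulates", "regulate", "regulated",
  "mediates", "mediate", "mediated", "targets", "target", "targeted",
  "expresses", "express", "expressed", "requires", "require", "required",
  "leads", "lead", "led", "results", "resulted", "found", "finds", "observed")

## Biomedical suffix and substring filter lists.
BIOMED_SUFFIXES <- c("ase", "in", "ion", "itis", "osis", "oma", "icity", "pathy")
BIOMED_SUBSTRINGS <- c("cell", "gene", "protein", "receptor", "antibody",
                       "immune", "tumor", "cancer", "virus", "bacteria")

#' Rule-based noun-phrase chunking backend
#'
#' The default `pos_backend` for [extract_candidate_phrases()]: splits a
#' sentence at punctuation and at a fixed lexicon of function words and
#' verbs, and returns the remaining token runs as noun-phrase chunks.  Any
#' backend with the same contract (function(sentence) -> list of character
#' token vectors, in order of appearance) can replace it, e.g. a wrapper
#' around a neural chunker.
#'
#' @return A chunking function.
#' @export
rule_chunker <- function() {
  function(sentence) {
    toks <- unlist(strsplit(sentence, "\\s+"))
    toks <- toks[nzchar(toks)]
    chunks <- list()
    cur <- character()
    for (tok in toks) {
      clean <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", tok)
      trailing_punct <- grepl("[.,;:!?]$", tok)
      if (!nzchar(clean) || tolower(clean) %in% CHUNK_BREAK_WORDS) {
        if (length(cur)) chunks[[length(chunks) + 1L]] <- cur
        cur <- character()
      } else {
        cur <- c(cur, clean)
        if (trailing_punct) {
          chunks[[length(chunks) + 1L]] <- cur
          cur <- character()
        }
      }
    }
    if (length(cur)) chunks[[length(chunks) + 1L]] <- cur
    chunks
  }
}

#' Extract candidate biomedical phrases from a sentence
#'
#' Applies the grammar rules to one sentence: noun-phrase chunks are taken
#' from the chunking backend, determiners/stop words are stripped from the
#' chunk edges, and only multi-token phrases survive.  Phrases are
#' whitespace-normalized and lowercased; order of appearance is preserved.
#'
#' @param sentence A single sentence.
#' @param pos_backend A chunking contract (default [rule_chunker()]).
#' @return A data frame with columns `phrase`, `source_sentence`,
#'   `passed_filters` (empty at this stage).
#' @examples
#' extract_candidate_phrases("IL-15 enhances natural killer cell cytotoxicity")
#' @export
extract_candidate_phrases <- function(sentence, pos_backend = rule_chunker()) {
  chunks <- pos_backend(sentence)
  phrases <- character()
  for (ch in chunks) {
    toks <- tolower(ch)
    while (length(toks) && toks[[1L]] %in% STOP_WORDS) toks <- toks[-1L]
    while (length(toks) && toks[[length(toks)]] %in% STOP_WORDS)
      toks <- toks[-length(toks)]
    if (length(toks) >= 2L) phrases <- c(phrases, paste(toks, collapse = " "))
  }
  phrases <- unique(phrases)
  data.frame(phrase = phrases,
             source_sentence = rep(sentence, length(phrases)),
             passed_filters = rep("", length(phrases)),
             stringsAsFactors = FALSE)
}

#' Normalized Levenshtein similarity
#'
#' `1 - distance / max(nchar(a), nchar(b))`, in \[0, 1\].
#'
#' @param a,b Character strings (vectorized over `b`).
#' @return Numeric similarity values.
#' @export
levenshtein_similarity <- function(a, b) {
  d <- as.numeric(utils::adist(a, b))
  denom <- pmax(nchar(a), nchar(b))
  ifelse(denom == 0, 1, 1 - d / denom)
}

#' Filter candidate phrases for biomedical relevance
#'
#' A phrase is kept if any of three filters fires: (1) its normalized
#' Levenshtein similarity to some vocabulary term reaches
#' `similarity_threshold`; (2) some token ends with a biomedical suffix
#' ("ase", "in", "ion", "itis", "osis", "oma", "icity", "pathy") -- the
#' two-letter suffix "in" is guarded to the phrase's head (final) token
#' with at least 4 characters, so prepositions and short words do not
#' flood the results; (3) it contains a biomedical substring ("cell",
#' "gene", "protein", "receptor", "antibody", "immune", "tumor", "cancer",
#' "virus", "bacteria").  Each kept phrase records which filters fired.
#'
#' @param phrases Candidate-phrase data frame from
#'   [extract_candidate_phrases()] (or a character vector of phrases).
#' @param vocabulary Character vector of known biomedical terms (one term
#'   per line if read from a file).
#' @param similarity_threshold Similarity cutoff in \[0, 1\] (default 0.85).
#' @return The kept subset with `passed_filters` filled in
#'   (semicolon-joined filter names among `vocabulary`, `suffix`,
#'   `substring`).
#' @export
filter_biomedical_phrases <- function(phrases, vocabulary = character(),
                                      similarity_threshold = 0.85) {
  if (similarity_threshold < 0 || similarity_threshold > 1) {
    ickg_validation_error("similarity_threshold must be in [0, 1]")
  }
  if (is.character(phrases)) {
    phrases <- data.frame(phrase = phrases, source_sentence = "",
                          passed_filters = "", stringsAsFactors = FALSE)
  }
  if (!nrow(phrases)) return(phrases)
  fired <- lapply(phrases$phrase, function(p) {
    f <- character()
    if (length(vocabulary) &&
        any(levenshtein_similarity(p, vocabulary) >= similarity_threshold)) {
      f <- c(f, "vocabulary")
    }
    toks <- strsplit(p, " ", fixed = TRUE)[[1L]]
    head_tok <- toks[[length(toks)]]
    suffix_hit <- any(vapply(BIOMED_SUFFIXES, function(s) {
      if (s == "in") {
        nchar(head_tok) >= 4L && endsWith(head_tok, "in")
      } else {
        any(endsWith(toks, s))
      }
    }, logical(1)))
    if (suffix_hit) f <- c(f, "suffix")
    if (any(vapply(BIOMED_SUBSTRINGS, grepl, logical(1), x = p, fixed = TRUE))) {
      f <- c(f, "substring")
    }
    f
  })
  keep <- lengths(fired) > 0L
  out <- phrases[keep, , drop = FALSE]
  out$passed_filters <- vapply(fired[keep], paste, character(1), collapse = ";")
  rownames(out) <- NULL
  out
}

#' Refine phrases through a text-review backend
#'
#' The refinement contract mirrors an LLM "keep only the informative
#' terms" pass: the backend receives the phrase list and returns the
#' retained sublist.  The output is always a subset of the input, in input
#' order; terms the backend returns that were not in the input are
#' discarded with a warning (anti-hallucination contract).
#'
#' @param phrases Candidate-phrase data frame (or character vector).
#' @param llm_backend function(character vector) -> character vector.
#'   Defaults to [identity_reviewer()].
#' @return The retained subset, same shape as the input.
#' @export
refine_phrases <- function(phrases, llm_backend = identity_reviewer()) {
  vec_input <- is.character(phrases)
  if (vec_input) {
    phrases <- data.frame(phrase = phrases, source_sentence = "",
                          passed_filters = "", stringsAsFactors = FALSE)
  }
  kept <- llm_backend(phrases$phrase)
  extra <- setdiff(kept, phrases$phrase)
  if (length(extra)) {
    warning(sprintf("review backend returned %d term(s) not in the input; discarded: %s",
                    length(extra), paste(extra, collapse = ", ")))
  }
  out <- phrases[phrases$phrase %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  if (vec_input) out$phrase else out
}

#' Deterministic review backends
#'
#' `identity_reviewer()` retains every term; `droplist_reviewer(drop)`
#' retains every term not in `drop`.  Both satisfy the refinement
#' contract and are used as deterministic stand-ins for an LLM reviewer.
#'
#' @param drop Character vector of terms to drop.
#' @return A review backend function.
#' @rdname reviewers
#' @export
identity_reviewer <- function() function(terms) terms

#' @rdname reviewers
#' @export
droplist_reviewer <- function(drop) function(terms) setdiff(terms, drop)
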