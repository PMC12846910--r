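## Corpus handling: loading abstract records and generating synthetic corpora
## with a planted ground-truth relation graph.

CORPUS_FIELDS <- c("abstract_id", "year", "title", "text", "cell_type_tag")
CELL_TYPE_TAGS <- c("T", "B", "NK", "macrophage", "other")

## Verb lexicons used by the synthetic templates and the mock relation
## backend.  The two sets are disjoint so direction recovery is exact.
ACTIVATE_VERBS <- c("activates", "induces", "promotes", "upregulates", "enhances")
INHIBIT_VERBS  <- c("inhibits", "suppresses", "represses", "downregulates", "blocks")

#' Load an abstract corpus from TSV or JSON-lines
#'
#' Reads abstract records (one per row/line) and retains those published
#' within `[year_min, year_max]`, preserving file order.  The canonical
#' dialect is a TSV with header columns `abstract_id`, `year`, `title`,
#' `text`, `cell_type_tag` (the last two optional); a JSON-lines file with
#' one object per line and the same fields is also accepted.
#'
#' @param path Path to a corpus file.
#' @param year_min,year_max Inclusive publication-year window (defaults
#'   2020--2024, the retention window used when building the graphs).
#' @param format `"auto"` (by extension: `.json`/`.jsonl` means JSON-lines,
#'   anything else TSV), `"tsv"`, or `"jsonl"`.
#' @return A data frame of class `ickg_corpus` with columns `abstract_id`,
#'   `year`, `title`, `text`, `cell_type_tag`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("abstract_id\tyear\ttitle\ttext",
#'              "p1\t2021\tt\tIL15 activates NK cells."), tf)
#' load_corpus(tf)
#' @export
load_corpus <- function(path, year_min = 2020L, year_max = 2024L,
                        format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    ickg_input_error(sprintf("corpus file not found: %s", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  recs <- if (format == "tsv") read_corpus_tsv(path) else read_corpus_jsonl(path)
  validate_corpus(recs, path)
  keep <- recs$year >= year_min & recs$year <= year_max
  recs <- recs[keep, , drop = FALSE]
  rownames(recs) <- NULL
  class(recs) <- c("ickg_corpus", "data.frame")
  recs
}

read_corpus_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L && ncol(df) <= 1L) {
    return(empty_corpus())
  }
  missing_cols <- setdiff(c("abstract_id", "year", "text"), names(df))
  if (length(missing_cols)) {
    ickg_input_error(sprintf("corpus TSV %s: missing required column(s): %s",
                             path, paste(missing_cols, collapse = ", ")))
  }
  if (is.null(df$title)) df$title <- rep("", nrow(df))
  if (is.null(df$cell_type_tag)) df$cell_type_tag <- rep("other", nrow(df))
  df$year <- suppressWarnings(as.integer(df$year))
  df[, CORPUS_FIELDS]
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_corpus())
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) ickg_input_error(
                      sprintf("corpus JSONL %s line %d: %s", path, i, conditionMessage(e))))
    miss <- setdiff(c("abstract_id", "year", "text"), names(rec))
    if (length(miss)) {
      ickg_input_error(sprintf("corpus JSONL %s line %d: missing field(s): %s",
                               path, i, paste(miss, collapse = ", ")))
    }
    data.frame(abstract_id = as.character(rec$abstract_id),
               year = as.integer(rec$year),
               title = if (is.null(rec$title)) "" else as.character(rec$title),
               text = as.character(rec$text),
               cell_type_tag = if (is.null(rec$cell_type_tag)) "other"
                               else as.character(rec$cell_type_tag),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

empty_corpus <- function() {
  data.frame(abstract_id = character(), year = integer(), title = character(),
             text = character(), cell_type_tag = character(),
             stringsAsFactors = FALSE)
}

validate_corpus <- function(recs, path = "<corpus>") {
  if (!nrow(recs)) return(invisible(recs))
  bad_id <- which(is.na(recs$abstract_id) | !nzchar(recs$abstract_id))
  if (length(bad_id)) {
    ickg_input_error(sprintf("%s: record %d has an empty abstract_id",
                             path, bad_id[[1L]]))
  }
  bad_text <- which(is.na(recs$text) | !nzchar(trimws(recs$text)))
  if (length(bad_text)) {
    ickg_input_error(sprintf("%s: record %d (abstract_id %s) has empty text",
                             path, bad_text[[1L]], recs$abstract_id[bad_text[[1L]]]))
  }
  bad_year <- which(is.na(recs$year))
  if (length(bad_year)) {
    ickg_input_error(sprintf("%s: record %d has a non-integer year",
                             path, bad_year[[1L]]))
  }
  dup <- recs$abstract_id[duplicated(recs$abstract_id)]
  if (length(dup)) {
    ickg_validation_error(sprintf("%s: duplicate abstract_id(s): %s",
                                  path, paste(unique(dup), collapse = ", ")))
  }
  invisible(recs)
}

#' Write a corpus to TSV
#'
#' @param corpus An `ickg_corpus` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  utils::write.table(as.data.frame(corpus)[, CORPUS_FIELDS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic abstract corpus with a planted relation graph
#'
#' Emits template abstracts ("SYG01 activates SYG02 in NK cells.") for a
#' randomly planted set of directed activate/inhibit relations among
#' synthetic genes and pathway concepts, so that the gazetteer tagger and
#' the deterministic verb-lookup relation backend recover exactly the
#' planted triples.  Optionally plants a hub gene with a fixed set of
#' activated downstream gene targets, and a pathway concept activated by a
#' dedicated set of member genes, for perturbation and annotation
#' benchmarks.
#'
#' One abstract is emitted per (relation, support) pair, so the number of
#' abstracts equals `sum(support per relation)` and each assembled edge
#' weight equals its planted distinct-abstract support count.
#'
#' @param n_genes Number of synthetic genes (symbols `SYG01`, ...).
#' @param n_pathways Number of synthetic pathway concepts
#'   (`"sp01 signaling"`, ...).
#' @param n_relations Number of background relations planted among the
#'   entities (in addition to any hub/pathway structure).
#' @param abstracts_per_relation Supporting abstracts per relation.
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @param cell_type Cell-type tag for every abstract.
#' @param hub_targets If > 0, gene `SYG01` is a hub that activates the next
#'   `hub_targets` genes (one relation each).  The hub and its targets are
#'   excluded as sources of background relations so the hub's true
#'   downstream set is exactly the planted target set (a well-defined
#'   perturbation ground truth).
#' @param pathway_genes If > 0, the last `pathway_genes` genes each activate
#'   pathway `"sp01 signaling"`.
#' @param p_activate Probability that a background relation is an
#'   activation (default 0.72, mirroring the roughly 3:1 activate:inhibit
#'   ratio of literature-derived immune graphs).
#' @return A list with elements `corpus` (an `ickg_corpus`), `truth` (the
#'   planted ground truth: `entities`, `triples`, `support`, and the
#'   planted `hub`/`hub_targets`/`pathway`/`pathway_genes` when present)
#'   and `gazetteer` (a surface/entity_type data frame for tagging).
#' @examples
#' sim <- generate_synthetic_corpus(n_genes = 6, n_relations = 5,
#'                                  abstracts_per_relation = 2, seed = 1)
#' nrow(sim$corpus)  # 10 abstracts
#' @export
generate_synthetic_corpus <- function(n_genes = 20L, n_pathways = 5L,
                                      n_relations = 30L,
                                      abstracts_per_relation = 2L,
                                      seed = 1L,
                                      cell_type = c("NK", "T", "B", "macrophage"),
                                      hub_targets = 0L, pathway_genes = 0L,
                                      p_activate = 0.72) {
  cell_type <- match.arg(cell_type)
  stopifnot(n_genes >= 1, n_pathways >= 0, n_relations >= 0,
            abstracts_per_relation >= 1)
  if (hub_targets > 0 && n_genes < hub_targets + 1L) {
    ickg_validation_error("n_genes must exceed hub_targets")
  }
  if (pathway_genes > 0 && (n_pathways < 1L || n_genes < pathway_genes)) {
    ickg_validation_error("pathway_genes requires >= 1 pathway and enough genes")
  }

  genes <- sprintf("SYG%02d", seq_len(n_genes))
  pathways <- if (n_pathways > 0) sprintf("sp%02d signaling", seq_len(n_pathways))
              else character()
  entities <- data.frame(
    name = c(genes, pathways),
    entity_type = c(rep("gene", n_genes), rep("pathway", length(pathways))),
    stringsAsFactors = FALSE)

  planted <- empty_triples()
  if (hub_targets > 0) {
    planted <- rbind(planted, data.frame(
      source = genes[[1L]], source_type = "gene",
      target = genes[1L + seq_len(hub_targets)], target_type = "gene",
      direction = "activate", stringsAsFactors = FALSE))
  }
  member_genes <- character()
  if (pathway_genes > 0) {
    member_genes <- genes[(n_genes - pathway_genes + 1L):n_genes]
    planted <- rbind(planted, data.frame(
      source = member_genes, source_type = "gene",
      target = pathways[[1L]], target_type = "pathway",
      direction = "activate", stringsAsFactors = FALSE))
  }

  n_ent <- nrow(entities)
  max_pairs <- n_ent * (n_ent - 1L)
  if (n_relations + nrow(planted) > max_pairs) {
    ickg_validation_error(sprintf(
      "requested %d relations but only %d ordered pairs exist",
      n_relations + nrow(planted), max_pairs))
  }

  with_seed(seed, {
    ## Background relations: distinct ordered (source, target) pairs not
    ## already used by the planted structure.  The hub and its targets
    ## never act as background sources, keeping the planted downstream
    ## set closed.
    taken <- paste(planted$source, planted$target)
    protected_sources <- if (hub_targets > 0) {
      c(genes[[1L]], genes[1L + seq_len(hub_targets)])
    } else {
      character()
    }
    bg <- empty_triples()
    if (n_relations > 0) {
      picked <- 0L
      while (picked < n_relations) {
        i <- sample.int(n_ent, 1L)
        j <- sample.int(n_ent, 1L)
        if (i == j) next
        if (entities$name[[i]] %in% protected_sources) next
        key <- paste(entities$name[[i]], entities$name[[j]])
        if (key %in% taken) next
        taken <- c(taken, key)
        dir <- if (stats::runif(1) < p_activate) "activate" else "inhibit"
        bg <- rbind(bg, data.frame(
          source = entities$name[[i]], source_type = entities$entity_type[[i]],
          target = entities$name[[j]], target_type = entities$entity_type[[j]],
          direction = dir, stringsAsFactors = FALSE))
        picked <- picked + 1L
      }
    }
    triples <- rbind(planted, bg)

    n_abs <- nrow(triples) * abstracts_per_relation
    support <- empty_support()
    rows <- vector("list", n_abs)
    k <- 0L
    for (r in seq_len(nrow(triples))) {
      verbs <- if (triples$direction[[r]] == "activate") ACTIVATE_VERBS else INHIBIT_VERBS
      for (a in seq_len(abstracts_per_relation)) {
        k <- k + 1L
        id <- sprintf("SYN%05d", k)
        verb <- sample(verbs, 1L)
        yr <- sample(2020:2024, 1L)
        txt <- sprintf(
          "%s %s %s in %s cells. These findings highlight potential therapeutic implications.",
          triples$source[[r]], verb, triples$target[[r]], cell_type)
        rows[[k]] <- data.frame(
          abstract_id = id, year = yr,
          title = sprintf("Synthetic study %05d", k),
          text = txt, cell_type_tag = cell_type, stringsAsFactors = FALSE)
        support <- rbind(support, data.frame(
          source = triples$source[[r]], target = triples$target[[r]],
          direction = triples$direction[[r]], abstract_id = id,
          stringsAsFactors = FALSE))
      }
    }
    corpus <- do.call(rbind, rows)
    class(corpus) <- c("ickg_corpus", "data.frame")

    truth <- list(entities = entities, triples = triples, support = support,
                  cell_type = cell_type)
    if (hub_targets > 0) {
      truth$hub <- genes[[1L]]
      truth$hub_targets <- genes[1L + seq_len(hub_targets)]
    }
    if (pathway_genes > 0) {
      truth$pathway <- pathways[[1L]]
      truth$pathway_genes <- member_genes
    }
    list(corpus = corpus, truth = truth, gazetteer = entities)
  })
}

empty_triples <- function() {
  data.frame(source = character(), source_type = character(),
             target = character(), target_type = character(),
             direction = character(), stringsAsFactors = FALSE)
}

empty_support <- function() {
  data.frame(source = character(), target = character(),
             direction = character(), abstract_id = character(),
             stringsAsFactors = FALSE)
}

#' PubMed E-utilities request URLs for a corpus query
#'
#' Pure URL construction for the optional online retrieval interface: an
#' `esearch` URL for the query restricted to a publication-year window,
#' and an `efetch` URL template for downloading the matching abstracts.
#' The query string is passed verbatim (e.g.
#' `'"NK cell" AND "cancer immunotherapy"'`).  No network access happens
#' here; a fetch step can download these URLs and write the standard
#' corpus TSV.
#'
#' @param query PubMed query string, used verbatim.
#' @param year_min,year_max Publication-year window.
#' @param retmax Maximum number of records to request.
#' @return A list with `esearch` and `efetch` URL strings (the latter
#'   containing an `{IDS}` placeholder for the comma-joined PMIDs).
#' @export
pubmed_eutils_urls <- function(query, year_min = 2020L, year_max = 2024L,
                               retmax = 10000L) {
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  term <- sprintf("(%s) AND (\"%d\"[Date - Publication] : \"%d\"[Date - Publication])",
                  query, year_min, year_max)
  list(
    esearch = sprintf("%s/esearch.fcgi?db=pubmed&retmax=%d&term=%s",
                      base, as.integer(retmax), utils::URLencode(term, reserved = TRUE)),
    efetch = sprintf("%s/efetch.fcgi?db=pubmed&rettype=abstract&retmode=xml&id={IDS}",
                     base))
}

#' @export
print.ickg_corpus <- function(x, ...) {
  cat(sprintf("<ickg_corpus> %d abstracts, years %s\n", nrow(x),
              if (nrow(x)) paste(range(x$year), collapse = "-") else "-"))
  if (nrow(x)) {
    utils::str(utils::head(as.data.frame(x), 3), nchar.max = 60)
  }
  invisible(x)
}
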