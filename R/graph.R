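## The ICKG container: a typed, signed, weighted, provenance-tracked
## directed multigraph.  Nodes are unique by (name, node_type); parallel
## activate and inhibit edges between the same node pair are retained so
## literature disagreement is preserved.  igraph backs serialization and
## standard graph algorithms.

#' Assemble an immune cell knowledge graph from relation triples
#'
#' Creates one node per distinct (name, node type) entity and one edge per
#' (source, target, direction), weighted by the number of DISTINCT
#' supporting abstracts; the supporting abstract ids are stored per edge
#' as provenance.  Node names are case-folded before merging: gene names
#' are uppercased (through the alias table when given), other node types
#' lowercased.  Entities sharing a name but tagged with different types
#' become distinct nodes.
#'
#' @param triples Triples data frame (`source`, `source_type`, `target`,
#'   `target_type`, `direction`, `abstract_id`), as produced by
#'   [extract_relations_corpus()] or [read_triples()].
#' @param aliases Optional [alias_table()] applied to gene node names.
#' @return An object of class `ickg` with components `nodes` (data frame:
#'   `key`, `name`, `node_type`) and `edges` (data frame: `source`,
#'   `target` node keys, `direction`, `weight`, list-column `provenance`).
#' @examples
#' tr <- data.frame(source = "A", source_type = "gene", target = "B",
#'                  target_type = "gene", direction = "activate",
#'                  abstract_id = c("p1", "p2"))
#' g <- assemble_graph(tr)
#' g$edges$weight  # 2
#' @export
assemble_graph <- function(triples, aliases = NULL) {
  need <- c("source", "source_type", "target", "target_type", "direction",
            "abstract_id")
  stopifnot(all(need %in% names(triples)))
  if (nrow(triples)) {
    if (any(!nzchar(triples$source)) || any(!nzchar(triples$target))) {
      ickg_validation_error("triple with empty entity name")
    }
    check_direction(triples$direction)
    check_node_type(c(triples$source_type, triples$target_type))
  }
  fold <- function(name, type) {
    out <- character(length(name))
    is_gene <- type == "gene"
    gn <- toupper(name[is_gene])
    if (!is.null(aliases) && length(gn)) {
      canon <- vapply(gn, normalize_gene, character(1), aliases = aliases)
      gn <- ifelse(is.na(canon), gn, canon)
    }
    out[is_gene] <- gn
    out[!is_gene] <- tolower(name[!is_gene])
    out
  }
  triples$source <- fold(triples$source, triples$source_type)
  triples$target <- fold(triples$target, triples$target_type)

  nodes <- unique(rbind(
    data.frame(name = triples$source, node_type = triples$source_type,
               stringsAsFactors = FALSE),
    data.frame(name = triples$target, node_type = triples$target_type,
               stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$name, nodes$node_type), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes$key <- node_keys(nodes$name, nodes$node_type)

  key_of <- stats::setNames(nodes$key, paste(nodes$name, nodes$node_type))
  src_key <- key_of[paste(triples$source, triples$source_type)]
  tgt_key <- key_of[paste(triples$target, triples$target_type)]

  edge_id <- paste(src_key, tgt_key, triples$direction, sep = "\r")
  ## distinct-abstract provenance per (source, target, direction)
  prov <- lapply(split(triples$abstract_id, edge_id),
                 function(x) sort(unique(x)))
  ids <- names(prov)
  parts <- strsplit(ids, "\r", fixed = TRUE)
  edges <- data.frame(
    source = vapply(parts, `[[`, character(1), 1L),
    target = vapply(parts, `[[`, character(1), 2L),
    direction = vapply(parts, `[[`, character(1), 3L),
    weight = lengths(prov), stringsAsFactors = FALSE)
  edges$provenance <- unname(prov)
  edges <- edges[order(edges$source, edges$target, edges$direction), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  new_ickg(nodes[, c("key", "name", "node_type")], edges)
}

## Display keys: the bare name when unique across the graph, otherwise
## "name|type" to disambiguate cross-type collisions.
node_keys <- function(name, node_type) {
  dup_names <- unique(name[duplicated(name)])
  ifelse(name %in% dup_names, paste(name, node_type, sep = "|"), name)
}

new_ickg <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "ickg")
}

#' Create an empty knowledge graph
#' @return An `ickg` with no nodes or edges.
#' @export
empty_ickg <- function() {
  nodes <- data.frame(key = character(), name = character(),
                      node_type = character(), stringsAsFactors = FALSE)
  edges <- data.frame(source = character(), target = character(),
                      direction = character(), weight = integer(),
                      stringsAsFactors = FALSE)
  edges$provenance <- list()
  new_ickg(nodes, edges)
}

#' @export
print.ickg <- function(x, ...) {
  st <- graph_stats(x)
  cat(sprintf("<ickg> %d nodes, %d edges (%d activate / %d inhibit)\n",
              st$n_nodes, st$n_edges, st$n_activate, st$n_inhibit))
  tc <- st$node_type_counts
  if (length(tc)) {
    cat("  nodes by type:",
        paste(sprintf("%s=%d", names(tc), tc), collapse = ", "), "\n")
  }
  invisible(x)
}

## Resolve user-supplied node identifiers (keys or bare names) to row
## indices in g$nodes; errors list all unresolved identifiers.
match_nodes <- function(g, x, node_type = NULL) {
  nodes <- g$nodes
  if (!is.null(node_type)) nodes_ok <- nodes$node_type %in% node_type
  idx <- integer(length(x))
  missing <- character()
  for (i in seq_along(x)) {
    hit <- which(nodes$key == x[[i]])
    if (!length(hit)) hit <- which(nodes$name == x[[i]])
    if (!length(hit) && any(nodes$node_type == "gene")) {
      hit <- which(nodes$name == toupper(x[[i]]) & nodes$node_type == "gene")
    }
    if (!length(hit)) hit <- which(nodes$name == tolower(x[[i]]))
    if (!is.null(node_type) && length(hit)) hit <- hit[nodes_ok[hit]]
    if (length(hit) != 1L) {
      missing <- c(missing, x[[i]])
      idx[[i]] <- NA_integer_
    } else {
      idx[[i]] <- hit
    }
  }
  if (length(missing)) {
    ickg_validation_error(sprintf("node(s) not found (or ambiguous): %s",
                                  paste(missing, collapse = ", ")))
  }
  idx
}

#' Summary statistics of a knowledge graph
#'
#' Exact node and edge counts by type/direction, plus per-node degree
#' centrality (total multigraph degree, in + out including parallel
#' edges, divided by n - 1).
#'
#' @param g An `ickg`.
#' @return A list of class `ickg_stats`: `n_nodes`, `n_edges`,
#'   `n_activate`, `n_inhibit`, `node_type_counts`, `total_weight`,
#'   `degree_centrality` (named numeric vector).
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "ickg"))
  n <- nrow(g$nodes)
  type_counts <- if (n) table(factor(g$nodes$node_type, levels = NODE_TYPES))
                 else table(factor(character(), levels = NODE_TYPES))
  deg <- stats::setNames(numeric(n), g$nodes$key)
  if (n && nrow(g$edges)) {
    d <- table(factor(c(g$edges$source, g$edges$target), levels = g$nodes$key))
    if (n > 1L) deg <- as.numeric(d) / (n - 1L) else deg[] <- 0
    names(deg) <- g$nodes$key
  }
  structure(list(
    n_nodes = n,
    n_edges = nrow(g$edges),
    n_activate = sum(g$edges$direction == "activate"),
    n_inhibit = sum(g$edges$direction == "inhibit"),
    node_type_counts = c(type_counts),
    total_weight = sum(g$edges$weight),
    degree_centrality = deg), class = "ickg_stats")
}

#' @export
print.ickg_stats <- function(x, ...) {
  cat(sprintf("nodes: %d  edges: %d (activate %d, inhibit %d)  total weight: %d\n",
              x$n_nodes, x$n_edges, x$n_activate, x$n_inhibit, x$total_weight))
  cat("node types:", paste(sprintf("%s=%d", names(x$node_type_counts),
                                   x$node_type_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Subgraph of top-weight edges
#'
#' Keeps edges whose weight reaches the `(1 - fraction)` quantile of the
#' edge-weight distribution (ties kept), dropping nodes left isolated.
#' `fraction = 0.005` reproduces a "top 0.5% weight" core subgraph.
#'
#' @param g An `ickg` with at least one edge.
#' @param fraction Fraction of edges to retain, in (0, 1].
#' @return An `ickg`.
#' @export
top_edge_subgraph <- function(g, fraction) {
  stopifnot(inherits(g, "ickg"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    ickg_validation_error("fraction must be in (0, 1]")
  }
  if (!nrow(g$edges)) ickg_validation_error("graph has no edges")
  thr <- stats::quantile(g$edges$weight, probs = 1 - fraction, names = FALSE)
  keep <- g$edges$weight >= thr
  edges <- g$edges[keep, , drop = FALSE]
  used <- unique(c(edges$source, edges$target))
  nodes <- g$nodes[g$nodes$key %in% used, , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  new_ickg(nodes, edges)
}

#' Convert an ICKG to an igraph object
#'
#' With `collapse = FALSE` (default) the full multigraph is returned,
#' with edge attributes `direction`, `weight`, `provenance`
#' (semicolon-joined).  With `collapse = TRUE` parallel activate/inhibit
#' edges between the same ordered node pair are merged into a single edge
#' whose `weight` is the summed weight (the transition weight used by the
#' reasoning layer); the dominant sign (larger weight, ties resolved to
#' activate) is kept in `direction`.
#'
#' @param g An `ickg`.
#' @param collapse Merge parallel signed edges.
#' @return An igraph directed graph.
#' @export
as_igraph <- function(g, collapse = FALSE) {
  stopifnot(inherits(g, "ickg"))
  edges <- if (collapse) collapse_edges(g) else g$edges
  prov <- if (!is.null(edges$provenance)) {
    vapply(edges$provenance, paste, character(1), collapse = ";")
  } else {
    rep("", nrow(edges))
  }
  ed <- data.frame(from = edges$source, to = edges$target,
                   direction = edges$direction, weight = edges$weight,
                   provenance = prov, stringsAsFactors = FALSE)
  vd <- data.frame(name = g$nodes$key, label = g$nodes$name,
                   node_type = g$nodes$node_type, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = vd)
}

## Collapse parallel signed edges: one row per ordered (source, target)
## with summed weight, dominant direction and pooled provenance.
collapse_edges <- function(g) {
  e <- g$edges
  if (!nrow(e)) return(e)
  id <- paste(e$source, e$target, sep = "\r")
  rows <- lapply(split(seq_len(nrow(e)), id), function(ix) {
    w <- sum(e$weight[ix])
    dom <- if (length(ix) == 1L) {
      e$direction[[ix]]
    } else {
      wa <- sum(e$weight[ix][e$direction[ix] == "activate"])
      wi <- sum(e$weight[ix][e$direction[ix] == "inhibit"])
      if (wi > wa) "inhibit" else "activate"
    }
    data.frame(source = e$source[[ix[1L]]], target = e$target[[ix[1L]]],
               direction = dom, weight = w, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$provenance <- unname(lapply(split(seq_len(nrow(e)), id), function(ix)
    sort(unique(unlist(e$provenance[ix])))))
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a knowledge graph
#'
#' Two dialects: GraphML (via igraph; node attributes `label`,
#' `node_type`, edge attributes `direction`, `weight`, `provenance` as
#' semicolon-joined abstract ids) and an edge-list TSV with columns
#' `source`, `source_type`, `target`, `target_type`, `direction`,
#' `weight`, `provenance`.  `read_graph_file(write_graph_file(g))`
#' reproduces `g` exactly, including provenance.
#'
#' @param g An `ickg`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"graphml"`, or `"tsv"`.
#' @return `write_graph_file` returns `path` invisibly;
#'   `read_graph_file` returns an `ickg`.
#' @rdname graph_io
#' @export
write_graph_file <- function(g, path, format = c("auto", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  }
  if (format == "graphml") {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  } else {
    type_of <- stats::setNames(g$nodes$node_type, g$nodes$key)
    df <- data.frame(
      source = g$edges$source,
      source_type = unname(type_of[g$edges$source]),
      target = g$edges$target,
      target_type = unname(type_of[g$edges$target]),
      direction = g$edges$direction,
      weight = g$edges$weight,
      provenance = vapply(g$edges$provenance, paste, character(1),
                          collapse = ";"),
      stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname graph_io
#' @export
read_graph_file <- function(path, format = c("auto", "graphml", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) ickg_input_error(sprintf("graph file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  }
  if (format == "graphml") {
    ig <- tryCatch(igraph::read_graph(path, format = "graphml"),
                   error = function(e) ickg_input_error(
                     sprintf("malformed GraphML %s: %s", path, conditionMessage(e))))
    vd <- igraph::as_data_frame(ig, what = "vertices")
    ed <- igraph::as_data_frame(ig, what = "edges")
    check_node_type(vd$node_type)
    if (nrow(ed)) check_direction(ed$direction)
    nodes <- data.frame(key = vd$name,
                        name = if (!is.null(vd$label)) vd$label else vd$name,
                        node_type = vd$node_type, stringsAsFactors = FALSE)
    edges <- data.frame(source = ed$from, target = ed$to,
                        direction = ed$direction,
                        weight = as.integer(round(ed$weight)),
                        stringsAsFactors = FALSE)
    edges$provenance <- strsplit(ed$provenance, ";", fixed = TRUE)
  } else {
    df <- utils::read.delim(path, colClasses = "character", quote = "",
                            stringsAsFactors = FALSE)
    need <- c("source", "source_type", "target", "target_type", "direction",
              "weight", "provenance")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      ickg_input_error(sprintf("graph TSV %s: missing column(s): %s", path,
                               paste(miss, collapse = ", ")))
    }
    check_node_type(c(df$source_type, df$target_type))
    if (nrow(df)) check_direction(df$direction)
    nodes <- unique(rbind(
      data.frame(key = df$source, node_type = df$source_type,
                 stringsAsFactors = FALSE),
      data.frame(key = df$target, node_type = df$target_type,
                 stringsAsFactors = FALSE)))
    nodes$name <- sub("\\|[a-z_]+$", "", nodes$key)
    nodes <- nodes[, c("key", "name", "node_type")]
    edges <- data.frame(source = df$source, target = df$target,
                        direction = df$direction,
                        weight = as.integer(df$weight),
                        stringsAsFactors = FALSE)
    edges$provenance <- strsplit(df$provenance, ";", fixed = TRUE)
  }
  nodes <- nodes[order(nodes$name, nodes$node_type), , drop = FALSE]
  ord <- order(edges$source, edges$target, edges$direction)
  edges <- edges[ord, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  g <- new_ickg(nodes, edges)
  validate_ickg(g)
  g
}

validate_ickg <- function(g) {
  stopifnot(inherits(g, "ickg"))
  if (anyDuplicated(g$nodes$key)) ickg_validation_error("duplicate node keys")
  if (nrow(g$edges)) {
    if (!all(g$edges$source %in% g$nodes$key) ||
        !all(g$edges$target %in% g$nodes$key)) {
      ickg_validation_error("edge endpoint not present in node table")
    }
    if (any(g$edges$weight != lengths(g$edges$provenance))) {
      ickg_validation_error("edge weight != number of provenance abstract ids")
    }
    if (anyDuplicated(paste(g$edges$source, g$edges$target, g$edges$direction))) {
      ickg_validation_error("duplicate (source, target, direction) edge")
    }
  }
  invisible(g)
}

#' Build a knowledge graph from a corpus in one call
#'
#' Runs the full assembly pipeline: entity tagging, relation extraction,
#' and graph assembly.
#'
#' @param corpus An `ickg_corpus`.
#' @param tagger Tagger backend.
#' @param backend Relation backend.
#' @param aliases Optional [alias_table()].
#' @param verbose Log per-stage counts.
#' @return An `ickg`.
#' @export
build_graph_from_corpus <- function(corpus, tagger,
                                    backend = verb_lookup_backend(),
                                    aliases = NULL, verbose = FALSE) {
  triples <- extract_relations_corpus(corpus, tagger, backend = backend,
                                      aliases = aliases, verbose = verbose)
  g <- assemble_graph(triples, aliases = aliases)
  if (verbose) {
    st <- graph_stats(g)
    message(sprintf("assembled graph: %d nodes, %d edges", st$n_nodes, st$n_edges))
  }
  g
}
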