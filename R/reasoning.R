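## Knowledge-graph reasoning: personalized PageRank with a permutation
## null, temperature-softmax random walks, in-silico perturbation,
## gene-set annotation, explanation subgraphs, concept association and
## similarity, and the degree-preserving shuffle control.
##
## PageRank runs on transition weights only (parallel activate/inhibit
## edges are collapsed to their summed weight); inhibition enters the
## results solely through path-parity sign labels on explanation paths.

#' PageRank configuration
#'
#' @param alpha Damping factor in (0, 1); probability of following an
#'   edge rather than restarting (default 0.85).
#' @param tol L1 convergence tolerance of the iterative solver.
#' @param max_iter Iteration cap of the iterative solver.
#' @return A list of class `pagerank_config`.
#' @export
pagerank_config <- function(alpha = 0.85, tol = 1e-12, max_iter = 1000L) {
  if (alpha <= 0 || alpha >= 1) ickg_validation_error("alpha must be in (0, 1)")
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter)),
            class = "pagerank_config")
}

#' Random-walk configuration
#'
#' @param temperature Softmax temperature T > 0: transition probabilities
#'   are proportional to exp(w / T) over out-edge weights w.
#' @param n_walks Walks per start node (default 1000).
#' @param walk_length Steps per walk (default 20).
#' @param seed Integer seed.
#' @return A list of class `random_walk_config`.
#' @export
random_walk_config <- function(temperature = 1, n_walks = 1000L,
                               walk_length = 20L, seed = 1L) {
  if (temperature <= 0) ickg_validation_error("temperature must be > 0")
  if (n_walks < 1L || walk_length < 1L) {
    ickg_validation_error("n_walks and walk_length must be >= 1")
  }
  structure(list(temperature = temperature, n_walks = as.integer(n_walks),
                 walk_length = as.integer(walk_length),
                 seed = as.integer(seed)),
            class = "random_walk_config")
}

## Collapsed transition structure shared by the reasoning operations.
pr_structure <- function(g) {
  ce <- collapse_edges(g)
  n <- nrow(g$nodes)
  si <- match(ce$source, g$nodes$key)
  ti <- match(ce$target, g$nodes$key)
  s <- numeric(n)
  if (nrow(ce)) {
    agg <- rowsum(ce$weight, si)
    s[as.integer(rownames(agg))] <- agg[, 1L]
  }
  list(n = n, src = si, tgt = ti, w = ce$weight, out_strength = s,
       dangling = which(s == 0), keys = g$nodes$key)
}

## PageRank operator: returns function(v) -> stationary score vector for
## restart distribution v.  Small graphs use an exact dense linear solve
## of x = alpha P^T x + alpha (d.x) v + (1 - alpha) v; larger graphs fall
## back to edge-list power iteration.  Dangling nodes redistribute their
## mass to the restart (personalization) vector.
pagerank_operator <- function(g, cfg = pagerank_config(), dense_cap = 800L) {
  st <- pr_structure(g)
  alpha <- cfg$alpha
  n <- st$n
  if (n == 0L) ickg_validation_error("graph is empty")
  d_ind <- rep(FALSE, n); d_ind[st$dangling] <- TRUE
  if (n <= dense_cap) {
    M <- matrix(0, n, n)  # M = P^T
    if (length(st$w)) {
      p <- st$w / st$out_strength[st$src]
      M[cbind(st$tgt, st$src)] <- M[cbind(st$tgt, st$src)] + p
    }
    A <- diag(n) - alpha * M
    Ainv <- solve(A)
    function(v) {
      z <- as.numeric(Ainv %*% v)
      dz <- sum(z[d_ind])
      x <- ((1 - alpha) / (1 - alpha * dz)) * z
      x / sum(x)
    }
  } else {
    p_edge <- if (length(st$w)) st$w / st$out_strength[st$src] else numeric()
    function(v) {
      x <- v
      for (it in seq_len(cfg$max_iter)) {
        flow <- numeric(n)
        if (length(p_edge)) {
          agg <- rowsum(x[st$src] * p_edge, st$tgt)
          flow[as.integer(rownames(agg))] <- agg[, 1L]
        }
        x_new <- alpha * (flow + sum(x[d_ind]) * v) + (1 - alpha) * v
        if (sum(abs(x_new - x)) < cfg$tol) { x <- x_new; break }
        x <- x_new
      }
      x / sum(x)
    }
  }
}

## Restart vector: uniform mass over the personalization node indices
## (uniform over all nodes when empty).
restart_vector <- function(n, idx = NULL) {
  v <- numeric(n)
  if (is.null(idx) || !length(idx)) v[] <- 1 / n else v[idx] <- 1 / length(idx)
  v
}

#' Personalized PageRank over a knowledge graph
#'
#' Computes stationary PageRank scores with edge weights as transition
#' weights (parallel signed edges summed; sign ignored at this stage),
#' restart distribution uniform over the personalization nodes (uniform
#' over all nodes when empty), and dangling-node mass redistributed to
#' the restart distribution.
#'
#' @param g An `ickg`.
#' @param personalization Character vector of node keys/names to restart
#'   at, or `NULL`/empty for the unpersonalized ranking.
#' @param cfg A [pagerank_config()].
#' @return Named numeric vector of scores over all node keys, summing to 1.
#' @export
personalized_pagerank <- function(g, personalization = NULL,
                                  cfg = pagerank_config()) {
  stopifnot(inherits(g, "ickg"))
  idx <- if (length(personalization)) match_nodes(g, personalization) else NULL
  op <- pagerank_operator(g, cfg)
  x <- op(restart_vector(nrow(g$nodes), idx))
  stats::setNames(x, g$nodes$key)
}

#' Permutation significance of PageRank scores
#'
#' Scores every candidate node with personalized PageRank seeded on the
#' observed seed set, then re-scores under `n_perm` random same-size seed
#' sets drawn without replacement from the permutation pool (by default,
#' all nodes sharing the observed seed set's node type(s): random gene
#' sets for gene seeds).  The p-value of a node is `n / n_perm`, where
#' `n` counts permutations whose score is greater than or equal to the
#' observed score; the 95% CI is the 2.5th and 97.5th percentile of its
#' permutation distribution.
#'
#' @param g An `ickg`.
#' @param seed_set Character vector of seed node keys/names (non-empty).
#' @param candidate_nodes Nodes to score (default: all nodes outside the
#'   seed set).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer RNG seed.
#' @param cfg A [pagerank_config()].
#' @param permute_from Optional character vector overriding the
#'   permutation pool.
#' @param p_floor `"n/N"` reports p = n/n_perm as defined (p can be 0);
#'   `"add-one"` reports the positively biased (n+1)/(n_perm+1) variant.
#' @return A data frame of class `ickg_node_scores` with columns `node`,
#'   `node_type`, `score`, `p`, `ci_low`, `ci_high`; attribute `n_perm`.
#' @export
permutation_test <- function(g, seed_set, candidate_nodes = NULL,
                             n_perm = 1000L, seed = 1L,
                             cfg = pagerank_config(), permute_from = NULL,
                             p_floor = c("n/N", "add-one")) {
  stopifnot(inherits(g, "ickg"))
  p_floor <- match.arg(p_floor)
  if (!length(seed_set)) ickg_validation_error("seed_set must be non-empty")
  if (n_perm < 1L) ickg_validation_error("n_perm must be >= 1")
  seed_idx <- sort(unique(match_nodes(g, seed_set)))
  k <- length(seed_idx)

  pool <- if (is.null(permute_from)) {
    which(g$nodes$node_type %in% unique(g$nodes$node_type[seed_idx]))
  } else {
    unique(match_nodes(g, permute_from))
  }
  if (length(pool) < k) {
    ickg_validation_error(sprintf(
      "permutation pool has %d node(s) but the seed set has %d",
      length(pool), k))
  }

  cand_idx <- if (is.null(candidate_nodes)) {
    setdiff(seq_len(nrow(g$nodes)), seed_idx)
  } else {
    unique(match_nodes(g, candidate_nodes))
  }

  op <- pagerank_operator(g, cfg)
  n <- nrow(g$nodes)
  observed <- op(restart_vector(n, seed_idx))[cand_idx]

  perm <- with_seed(seed, {
    m <- matrix(0, nrow = n_perm, ncol = length(cand_idx))
    for (b in seq_len(n_perm)) {
      draw <- if (length(pool) == 1L) pool else sample(pool, k)
      m[b, ] <- op(restart_vector(n, draw))[cand_idx]
    }
    m
  })

  ge <- colSums(sweep(perm, 2L, observed, `>=`))
  p <- if (p_floor == "n/N") ge / n_perm else (ge + 1) / (n_perm + 1)
  ci <- apply(perm, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)

  out <- data.frame(node = g$nodes$key[cand_idx],
                    node_type = g$nodes$node_type[cand_idx],
                    score = unname(observed), p = p,
                    ci_low = ci[1L, ], ci_high = ci[2L, ],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed_set") <- g$nodes$key[seed_idx]
  class(out) <- c("ickg_node_scores", "data.frame")
  out
}

#' Softmax transition probabilities of the adjusted random walk
#'
#' Out-neighbor transition probabilities from one node:
#' `exp(w/T) / sum(exp(w/T))` over the node's (collapsed) out-edge
#' weights.
#'
#' @param g An `ickg`.
#' @param node A node key/name.
#' @param temperature Softmax temperature T > 0.
#' @return Named numeric vector over out-neighbor keys (empty for sinks).
#' @export
transition_probabilities <- function(g, node, temperature = 1) {
  if (temperature <= 0) ickg_validation_error("temperature must be > 0")
  i <- match_nodes(g, node)
  st <- pr_structure(g)
  sel <- st$src == i
  if (!any(sel)) return(stats::setNames(numeric(0), character(0)))
  w <- st$w[sel] / temperature
  p <- exp(w - max(w))
  stats::setNames(p / sum(p), st$keys[st$tgt[sel]])
}

#' Adjusted random walk with temperature-softmax transitions
#'
#' From each start node, performs `n_walks` walks of `walk_length` steps.
#' Each step moves to an out-neighbor with probability proportional to
#' `exp(w/T)`; a walk ends early at a node with no out-edges.  Node
#' importance is the visit frequency over all walk positions (including
#' the start position), normalized to sum to 1.
#'
#' @param g An `ickg`.
#' @param start_nodes Character vector of start node keys/names.
#' @param cfg A [random_walk_config()].
#' @return Named numeric vector of normalized visit frequencies.
#' @export
adjusted_random_walk <- function(g, start_nodes,
                                 cfg = random_walk_config()) {
  stopifnot(inherits(g, "ickg"), inherits(cfg, "random_walk_config"))
  starts <- unique(match_nodes(g, start_nodes))
  st <- pr_structure(g)
  ## per-node out-neighbor index lists and softmax probabilities
  nbr <- split(st$tgt, factor(st$src, levels = seq_len(st$n)))
  prb <- lapply(split(st$w, factor(st$src, levels = seq_len(st$n))), function(w) {
    if (!length(w)) return(numeric(0))
    e <- exp(w / cfg$temperature - max(w / cfg$temperature))
    e / sum(e)
  })
  visits <- numeric(st$n)
  with_seed(cfg$seed, {
    for (s0 in starts) {
      for (walk in seq_len(cfg$n_walks)) {
        cur <- s0
        visits[cur] <- visits[cur] + 1
        for (step in seq_len(cfg$walk_length)) {
          nb <- nbr[[cur]]
          if (!length(nb)) break
          cur <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L,
                                                            prob = prb[[cur]])]
          visits[cur] <- visits[cur] + 1
        }
      }
    }
  })
  stats::setNames(visits / sum(visits), st$keys)
}

#' Explanation subgraph of shortest paths
#'
#' For each reachable target, selects one shortest path (by hop count)
#' from `source`; ties are broken by the larger minimum edge weight along
#' the path, then lexicographically by predecessor key.  The union of the
#' selected paths is returned as a subgraph carrying every parallel
#' signed edge (with weight and provenance) of each traversed hop.  The
#' sign of a hop is the dominant direction of its parallel edges (larger
#' summed weight; ties resolve to activate); a target's inferred sign is
#' the parity of inhibiting hops on its path (even = activated, odd =
#' inhibited).
#'
#' @param g An `ickg`.
#' @param source Source node key/name.
#' @param targets Character vector of target node keys/names.
#' @return A list of class `ickg_paths`: `paths` (named list of node-key
#'   vectors), `signs` (named character, "activated"/"inhibited"),
#'   `n_inhibit_hops` (named integer), `unreachable` (character),
#'   `subgraph` (an `ickg`).
#' @export
explain_paths <- function(g, source, targets) {
  stopifnot(inherits(g, "ickg"))
  src <- match_nodes(g, source)
  tgt <- unique(match_nodes(g, targets))
  ce <- collapse_edges(g)
  n <- nrow(g$nodes)
  ei <- match(ce$source, g$nodes$key)
  ej <- match(ce$target, g$nodes$key)

  ## BFS distances from src
  dist <- rep(Inf, n); dist[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- unique(ej[ei %in% frontier])
    nxt <- nxt[is.infinite(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- dist[frontier[[1L]]] + 1  # all frontier nodes share a depth
    frontier <- nxt
  }

  ## Predecessor DP in order of increasing depth: maximize the bottleneck
  ## (minimum edge weight) of the chosen shortest path; break remaining
  ## ties on the lexicographically smallest predecessor key.
  bott <- rep(-Inf, n); bott[src] <- Inf
  pred <- rep(NA_integer_, n)
  reach <- which(is.finite(dist) & dist > 0)
  for (v in reach[order(dist[reach])]) {
    ins <- which(ej == v & dist[ei] == dist[v] - 1)
    if (!length(ins)) next
    cand_b <- pmin(bott[ei[ins]], ce$weight[ins])
    best <- ins[cand_b == max(cand_b)]
    if (length(best) > 1L) best <- best[order(g$nodes$key[ei[best]])][1L]
    pred[v] <- ei[best]
    bott[v] <- min(bott[pred[v]], ce$weight[best])
  }

  hop_sign <- stats::setNames(ce$direction, paste(ei, ej))
  paths <- list(); signs <- character(); nih <- integer()
  unreachable <- character()
  used_hops <- character()
  for (t in tgt) {
    if (t == src) next
    if (!is.finite(dist[t])) {
      unreachable <- c(unreachable, g$nodes$key[t]); next
    }
    path <- t
    while (path[[1L]] != src) path <- c(pred[path[[1L]]], path)
    hops <- paste(path[-length(path)], path[-1L])
    used_hops <- union(used_hops, hops)
    k <- sum(hop_sign[hops] == "inhibit")
    key_t <- g$nodes$key[t]
    paths[[key_t]] <- g$nodes$key[path]
    signs[[key_t]] <- if (k %% 2 == 0) "activated" else "inhibited"
    nih[[key_t]] <- k
  }

  ## Subgraph: all parallel signed edges of every traversed hop.
  if (length(used_hops)) {
    all_hop <- paste(match(g$edges$source, g$nodes$key),
                     match(g$edges$target, g$nodes$key))
    edges <- g$edges[all_hop %in% used_hops, , drop = FALSE]
    used_nodes <- unique(c(edges$source, edges$target))
    nodes <- g$nodes[g$nodes$key %in% used_nodes, , drop = FALSE]
    rownames(edges) <- rownames(nodes) <- NULL
    sub <- new_ickg(nodes, edges)
  } else {
    sub <- empty_ickg()
  }
  structure(list(source = g$nodes$key[src], paths = paths, signs = signs,
                 n_inhibit_hops = nih, unreachable = unreachable,
                 subgraph = sub),
            class = "ickg_paths")
}

#' @export
print.ickg_paths <- function(x, ...) {
  cat(sprintf("<ickg_paths> from %s: %d reachable target(s), %d unreachable\n",
              x$source, length(x$paths), length(x$unreachable)))
  for (t in utils::head(names(x$paths), 10)) {
    cat(sprintf("  %s [%s]: %s\n", t, x$signs[[t]],
                paste(x$paths[[t]], collapse = " -> ")))
  }
  invisible(x)
}

#' In-silico perturbation of a gene
#'
#' Seeds personalized PageRank on the perturbed gene and ranks all other
#' reachable gene nodes by score; each ranked gene carries an inferred
#' sign from the parity of inhibiting hops along its explanation path
#' (even = activated, odd = inhibited) and the path itself.
#'
#' @param g An `ickg`.
#' @param gene The perturbed gene node key/name.
#' @param cfg A [pagerank_config()].
#' @param n_top Optionally truncate the ranking to the top `n_top` genes.
#' @return A list of class `ickg_perturbation`: `perturbed_gene`,
#'   `ranked_genes` (data frame `gene`, `score`, `inferred_sign`),
#'   `paths` (an `ickg_paths`), `scores` (full score vector).
#' @export
in_silico_perturbation <- function(g, gene, cfg = pagerank_config(),
                                   n_top = NULL) {
  gi <- match_nodes(g, gene, node_type = "gene")
  scores <- personalized_pagerank(g, g$nodes$key[gi], cfg)
  gene_keys <- g$nodes$key[g$nodes$node_type == "gene"]
  gene_keys <- setdiff(gene_keys, g$nodes$key[gi])
  pth <- explain_paths(g, g$nodes$key[gi], gene_keys)
  reach <- names(pth$paths)
  df <- data.frame(gene = reach, score = unname(scores[reach]),
                   inferred_sign = unname(pth$signs[reach]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$gene), , drop = FALSE]
  if (!is.null(n_top)) df <- utils::head(df, n_top)
  rownames(df) <- NULL
  structure(list(perturbed_gene = g$nodes$key[gi], ranked_genes = df,
                 paths = pth, scores = scores),
            class = "ickg_perturbation")
}

#' @export
print.ickg_perturbation <- function(x, ...) {
  cat(sprintf("<ickg_perturbation> %s: %d ranked downstream gene(s)\n",
              x$perturbed_gene, nrow(x$ranked_genes)))
  print(utils::head(x$ranked_genes, 10))
  invisible(x)
}

#' Annotate a gene set with knowledge-graph concepts
#'
#' Seeds personalized PageRank on the mapped query genes and ranks
#' pathway-type nodes by score, attaching permutation p-values and 95%
#' CIs (random same-size gene seed sets).  Query genes never appear in
#' the output; unmapped query genes are reported in the `unmapped`
#' attribute.
#'
#' @param g An `ickg`.
#' @param genes Character vector of query gene symbols.
#' @param aliases Optional [alias_table()] tried when a symbol does not
#'   match a node directly.
#' @param n_perm Permutations for the significance test.
#' @param seed Integer RNG seed.
#' @param cfg A [pagerank_config()].
#' @return An `ickg_node_scores` data frame of pathway nodes ranked by
#'   score (empty when no pathway node is reachable), with attribute
#'   `unmapped`.
#' @export
annotate_gene_set <- function(g, genes, aliases = NULL, n_perm = 1000L,
                              seed = 1L, cfg = pagerank_config()) {
  stopifnot(inherits(g, "ickg"))
  genes <- unique(genes)
  mapped <- character(); unmapped <- character()
  for (gn in genes) {
    cand <- unique(c(gn, if (!is.null(aliases)) normalize_gene(gn, aliases)))
    cand <- cand[!is.na(cand)]
    idx <- NULL
    for (cc in cand) {
      idx <- tryCatch(match_nodes(g, cc, node_type = "gene"),
                      error = function(e) NULL)
      if (!is.null(idx)) break
    }
    if (is.null(idx)) unmapped <- c(unmapped, gn)
    else mapped <- c(mapped, g$nodes$key[idx])
  }
  mapped <- sort(unique(mapped))  # set semantics: query order is irrelevant
  if (!length(mapped)) {
    ickg_nomap_error(sprintf("no query gene maps into the graph (tried: %s)",
                             paste(genes, collapse = ", ")))
  }
  pathway_nodes <- g$nodes$key[g$nodes$node_type == "pathway"]
  if (!length(pathway_nodes)) {
    res <- empty_node_scores()
  } else {
    res <- permutation_test(g, mapped, candidate_nodes = pathway_nodes,
                            n_perm = n_perm, seed = seed, cfg = cfg)
    res <- res[res$score > 1e-15, , drop = FALSE]  # unreachable terms drop out
    rownames(res) <- NULL
  }
  attr(res, "unmapped") <- unmapped
  attr(res, "mapped") <- mapped
  res
}

empty_node_scores <- function() {
  out <- data.frame(node = character(), node_type = character(),
                    score = numeric(), p = numeric(), ci_low = numeric(),
                    ci_high = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("ickg_node_scores", "data.frame")
  out
}

#' Genes significantly associated with a concept node
#'
#' Seeds personalized PageRank on a single concept node (for example a
#' cell type or disease) and returns the gene nodes whose permutation
#' p-value (null: random same-type concept seeds) falls strictly below
#' the significance threshold.
#'
#' @param g An `ickg`.
#' @param concept The concept node key/name.
#' @param significance Strict p-value threshold (default 0.05).
#' @param n_perm,seed,cfg Passed to [permutation_test()].
#' @return Character vector of gene node keys.
#' @export
concept_associated_genes <- function(g, concept, significance = 0.05,
                                     n_perm = 1000L, seed = 1L,
                                     cfg = pagerank_config()) {
  ci <- match_nodes(g, concept)
  gene_nodes <- g$nodes$key[g$nodes$node_type == "gene"]
  if (!length(gene_nodes)) return(character())
  res <- permutation_test(g, g$nodes$key[ci], candidate_nodes = gene_nodes,
                          n_perm = n_perm, seed = seed, cfg = cfg)
  res$node[res$p < significance & res$score > 1e-15]
}

#' Pairwise concept similarity by shared associated genes
#'
#' Entry (i, j) is the Jaccard index of the significantly associated gene
#' sets of concepts i and j; the diagonal is 1 when a concept's gene set
#' is non-empty (0 otherwise, by the empty-set convention).
#'
#' @param g An `ickg`.
#' @param concepts Character vector (>= 2) of concept node keys/names.
#' @param ... Passed to [concept_associated_genes()].
#' @return A symmetric numeric matrix with concept keys as dimnames.
#' @export
concept_similarity_matrix <- function(g, concepts, ...) {
  if (length(concepts) < 2L) ickg_validation_error("need >= 2 concepts")
  keys <- g$nodes$key[match_nodes(g, concepts)]
  sets <- lapply(keys, function(k) concept_associated_genes(g, k, ...))
  m <- matrix(0, length(keys), length(keys), dimnames = list(keys, keys))
  for (i in seq_along(keys)) {
    for (j in seq_len(i)) {
      m[i, j] <- m[j, i] <- jaccard_index(sets[[i]], sets[[j]])
    }
  }
  m
}

#' Degree-preserving shuffle of a knowledge graph
#'
#' Randomizes connectivity with attempted double-edge swaps (two edges
#' a->b, c->d become a->d, c->b) while preserving every node's in- and
#' out-degree, the edge-weight multiset, the sign multiset, node types,
#' and per-edge provenance.  Swaps creating self-loops or duplicate
#' (source, target, direction) edges are rejected; `10 * n_edges` swaps
#' are attempted.
#'
#' @param g An `ickg` (>= 2 edges; smaller graphs are returned unchanged
#'   with a warning).
#' @param seed Integer seed; the same seed yields the same shuffle.
#' @return A shuffled `ickg`.
#' @export
shuffle_graph <- function(g, seed = 1L) {
  stopifnot(inherits(g, "ickg"))
  e <- g$edges
  if (nrow(e) < 2L) {
    warning("graph too small to swap; returned unchanged")
    return(g)
  }
  n_e <- nrow(e)
  with_seed(seed, {
    existing <- new.env(hash = TRUE, parent = emptyenv())
    ekey <- function(s, t, d) paste(s, t, d, sep = "\r")
    for (i in seq_len(n_e)) assign(ekey(e$source[i], e$target[i], e$direction[i]),
                                   TRUE, envir = existing)
    for (att in seq_len(10L * n_e)) {
      ij <- sample.int(n_e, 2L)
      i <- ij[[1L]]; j <- ij[[2L]]
      a <- e$source[i]; b <- e$target[i]; c_ <- e$source[j]; d <- e$target[j]
      if (a == d || c_ == b) next
      k1_new <- ekey(a, d, e$direction[i]); k2_new <- ekey(c_, b, e$direction[j])
      if (exists(k1_new, envir = existing, inherits = FALSE) ||
          exists(k2_new, envir = existing, inherits = FALSE) ||
          k1_new == k2_new) next
      rm(list = c(ekey(a, b, e$direction[i]), ekey(c_, d, e$direction[j])),
         envir = existing)
      assign(k1_new, TRUE, envir = existing)
      assign(k2_new, TRUE, envir = existing)
      e$target[i] <- d; e$target[j] <- b
    }
  })
  ord <- order(e$source, e$target, e$direction)
  e <- e[ord, , drop = FALSE]
  rownames(e) <- NULL
  new_ickg(g$nodes, e)
}

#' Write a node-score table to TSV or JSON
#'
#' @param scores An `ickg_node_scores` data frame.
#' @param path Output path (`.json` writes JSON, anything else TSV).
#' @return `path`, invisibly.
#' @export
write_node_scores <- function(scores, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(scores), path, digits = NA,
                         auto_unbox = FALSE, pretty = TRUE)
  } else {
    utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
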