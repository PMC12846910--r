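## Test fixtures and independent oracles, built in code.

## Build an ickg directly from an edge table (source, target, direction,
## weight), expanding each edge into `weight` distinct supporting
## abstract ids.  Node types default to gene; `types` is a named vector
## overriding the type of specific nodes.
make_graph <- function(edges, types = NULL) {
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(edges))) {
    tys <- function(nm) {
      if (!is.null(types) && nm %in% names(types)) types[[nm]] else "gene"
    }
    for (w in seq_len(edges$weight[[i]])) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        source = edges$source[[i]], source_type = tys(edges$source[[i]]),
        target = edges$target[[i]], target_type = tys(edges$target[[i]]),
        direction = edges$direction[[i]],
        abstract_id = sprintf("FIX%05d", k), stringsAsFactors = FALSE)
    }
  }
  assemble_graph(do.call(rbind, rows))
}

edge_table <- function(source, target, direction = "activate", weight = 1L) {
  data.frame(source = source, target = target, direction = direction,
             weight = weight, stringsAsFactors = FALSE)
}

## Random weighted digraph as an ickg: n nodes, m distinct ordered pairs,
## integer weights in 1..max_w, random directions, no self-loops.
random_ickg <- function(n, m, seed, max_w = 5L, types = NULL) {
  set.seed(seed)
  nodes <- sprintf("G%02d", seq_len(n))
  pairs <- expand.grid(s = nodes, t = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  pick <- pairs[sample.int(nrow(pairs), min(m, nrow(pairs))), ]
  make_graph(edge_table(pick$s, pick$t,
                        direction = sample(c("activate", "inhibit"),
                                           nrow(pick), replace = TRUE),
                        weight = sample.int(max_w, nrow(pick), replace = TRUE)),
             types = types)
}

## Independent PageRank oracle: dense power iteration over the collapsed
## weight matrix, written without any package internals.  Dangling rows
## redistribute their mass to the restart vector.
oracle_pagerank <- function(g, personalization = NULL, alpha = 0.85,
                            iters = 5000L, tol = 1e-15) {
  nodes <- g$nodes$key
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(g$edges))) {
    W[g$edges$source[[i]], g$edges$target[[i]]] <-
      W[g$edges$source[[i]], g$edges$target[[i]]] + g$edges$weight[[i]]
  }
  v <- stats::setNames(numeric(n), nodes)
  if (is.null(personalization) || !length(personalization)) {
    v[] <- 1 / n
  } else {
    v[personalization] <- 1 / length(personalization)
  }
  s <- rowSums(W)
  P <- W
  P[s > 0, ] <- P[s > 0, , drop = FALSE] / s[s > 0]
  dang <- s == 0
  x <- v
  for (it in seq_len(iters)) {
    xn <- alpha * (as.numeric(crossprod(P, x)) + sum(x[dang]) * v) +
      (1 - alpha) * v
    if (sum(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  stats::setNames(x / sum(x), nodes)
}

## All size-k subsets of a pool (small pools only), as a list.
all_subsets <- function(pool, k) {
  cmb <- utils::combn(pool, k)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}
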