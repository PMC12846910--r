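## Benchmarking machinery: Jaccard overlap, directional confusion
## matrices with alias expansion, KEGG interaction simplification, GMM
## dichotomization, PPI structural metrics, and embedding coherence
## metrics.

#' Jaccard index of two sets
#'
#' `|A n B| / |A u B|`; 0 when both sets are empty (by convention).
#'
#' @param a,b Vectors treated as sets.
#' @return A fraction in \[0, 1\].
#' @examples
#' jaccard_index(c("A", "B"), c("B", "C"))  # 1/3
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

KEGG_ACTIVATE_SUBTYPES <- c("activation", "activation-indirect effect",
                            "activation-indirect")
KEGG_INHIBIT_SUBTYPES <- c("inhibition", "inhibition-indirect effect",
                           "inhibition-repression", "repression-indirect effect")

#' Simplify a KEGG interaction subtype to a direction
#'
#' Maps the KEGG-defined interaction subtypes onto the two directions
#' used by the knowledge graph: "activation", "activation-indirect
#' effect" and "activation-indirect" become `activate`; "inhibition",
#' "inhibition-indirect effect", "inhibition-repression" and
#' "repression-indirect effect" become `inhibit`; every other subtype
#' (e.g. "binding/association") is `excluded`.
#'
#' @param subtype Character vector of KEGG interaction subtype strings.
#' @return Character vector over `{"activate", "inhibit", "excluded"}`.
#' @export
simplify_kegg_interaction <- function(subtype) {
  s <- tolower(trimws(subtype))
  out <- rep("excluded", length(s))
  out[s %in% KEGG_ACTIVATE_SUBTYPES] <- "activate"
  out[s %in% KEGG_INHIBIT_SUBTYPES] <- "inhibit"
  out
}

#' Directional confusion matrix between predicted and reference relations
#'
#' Gene pairs are matched after alias normalization (and uppercasing) of
#' both endpoints; only ordered pairs present in BOTH the predicted and
#' the reference set populate the matrix.  Cells: A = both activate,
#' B = predicted activate / reference inhibit, C = predicted inhibit /
#' reference activate, D = both inhibit; E = A+B+C+D is the overlap
#' count.  Pairs carrying both directions on one side are ambiguous and
#' resolve to the direction with more rows (ties are dropped).
#'
#' @param pred Predicted triples data frame (`source`, `target`,
#'   `direction`; extra columns ignored).
#' @param reference Reference data frame with `source`, `target`,
#'   `direction`.
#' @param aliases Optional [alias_table()] applied to all endpoints.
#' @return A list of class `ickg_confusion` with `A`, `B`, `C`, `D`, `E`.
#' @export
relation_confusion <- function(pred, reference, aliases = NULL) {
  norm_side <- function(df) {
    if (!nrow(df)) return(stats::setNames(character(), character()))
    canon <- function(x) {
      x <- toupper(x)
      if (!is.null(aliases)) {
        c2 <- vapply(x, normalize_gene, character(1), aliases = aliases)
        x <- ifelse(is.na(c2), x, c2)
      }
      x
    }
    key <- paste(canon(df$source), canon(df$target), sep = "\r")
    dirs <- split(df$direction, key)
    res <- vapply(dirs, function(d) {
      na <- sum(d == "activate"); ni <- sum(d == "inhibit")
      if (na > ni) "activate" else if (ni > na) "inhibit" else NA_character_
    }, character(1))
    res[!is.na(res)]
  }
  p <- norm_side(pred)
  r <- norm_side(reference)
  common <- intersect(names(p), names(r))
  A <- sum(p[common] == "activate" & r[common] == "activate")
  B <- sum(p[common] == "activate" & r[common] == "inhibit")
  C <- sum(p[common] == "inhibit" & r[common] == "activate")
  D <- sum(p[common] == "inhibit" & r[common] == "inhibit")
  structure(list(A = A, B = B, C = C, D = D, E = A + B + C + D),
            class = "ickg_confusion")
}

#' @export
print.ickg_confusion <- function(x, ...) {
  m <- matrix(c(x$A, x$C, x$B, x$D), 2, 2,
              dimnames = list(predicted = c("activate", "inhibit"),
                              reference = c("activate", "inhibit")))
  print(m)
  cat("overlap E =", x$E, "\n")
  invisible(x)
}

#' Precision / recall / F1 from a directional confusion matrix
#'
#' Precision = A/(A+B), Recall = A/(A+C),
#' F1 = 2 * Precision * Recall / (Precision + Recall); any metric with a
#' zero denominator is 0.
#'
#' @param m An `ickg_confusion` (or list with `A`, `B`, `C`).
#' @return A list with `precision`, `recall`, `f1`.
#' @examples
#' prf_from_confusion(list(A = 30, B = 10, C = 10))  # 0.75 each
#' @export
prf_from_confusion <- function(m) {
  prf(m$A, m$B, m$C)[c("precision", "recall", "f1")]
}

#' Dichotomize values with a two-component Gaussian mixture
#'
#' Fits a two-component Gaussian mixture model and labels every value by
#' its assigned component; the component with the higher fitted mean is
#' `"High"`, the other `"Low"`.  The fit uses a conjugate prior so
#' perfectly separated zero-variance clusters remain fittable.
#'
#' @param values Numeric vector (>= 4 values, >= 2 distinct).
#' @param seed Integer seed (the EM fit is deterministic; the seed guards
#'   reproducibility of any stochastic initialization).
#' @return Character vector of labels in `{"High", "Low"}` with
#'   attributes `means` (component means, Low then High).
#' @examples
#' gmm_dichotomize(c(0, 0, 0, 1, 1, 1))
#' @importFrom mclust Mclust mclustBIC priorControl defaultPrior
#' @export
gmm_dichotomize <- function(values, seed = 0L) {
  values <- as.numeric(values)
  if (length(values) < 4L) ickg_validation_error("need >= 4 values")
  if (length(unique(values)) < 2L) {
    ickg_validation_error("all values identical: degenerate mixture fit")
  }
  fit <- with_seed(seed, {
    suppressWarnings(mclust::Mclust(values, G = 2,
                                    prior = mclust::priorControl(),
                                    verbose = FALSE))
  })
  if (is.null(fit)) ickg_validation_error("mixture fit failed")
  mu <- fit$parameters$mean
  high_comp <- which.max(mu)
  labels <- ifelse(fit$classification == high_comp, "High", "Low")
  attr(labels, "means") <- sort(unname(mu))
  labels
}

#' Structural metrics of a protein-protein interaction network
#'
#' Builds an undirected network from a weighted pair list and computes
#' density (`2|E| / (n (n-1))`), the average local clustering
#' coefficient (nodes of degree < 2 count as 0), and the modularity of a
#' greedy modularity community partition.
#'
#' @param edges Data frame whose first two columns are the interacting
#'   node pairs; an optional `score` column provides edge weights for
#'   the community search.
#' @param nodes Optional character vector of node names including
#'   isolated nodes.
#' @return A list with `density`, `clustering`, `modularity`,
#'   `n_nodes`, `n_edges`.
#' @export
ppi_network_metrics <- function(edges, nodes = NULL) {
  if (is.null(edges) || !nrow(edges)) {
    return(list(density = 0, clustering = 0, modularity = NA_real_,
                n_nodes = length(unique(nodes)), n_edges = 0L))
  }
  ed <- data.frame(from = as.character(edges[[1L]]),
                   to = as.character(edges[[2L]]), stringsAsFactors = FALSE)
  if (!is.null(edges$score)) ed$weight <- as.numeric(edges$score)
  verts <- unique(c(ed$from, ed$to, nodes))
  if (length(verts) < 2L) ickg_validation_error("need >= 2 nodes")
  ig <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
  ig <- igraph::simplify(ig, edge.attr.comb = "max")
  comm <- igraph::cluster_fast_greedy(ig)
  list(density = igraph::edge_density(ig),
       clustering = igraph::transitivity(ig, type = "localaverage",
                                         isolates = "zero"),
       modularity = igraph::modularity(comm),
       n_nodes = igraph::vcount(ig),
       n_edges = igraph::ecount(ig))
}

#' Within-cluster sum of squares of an embedding set
#'
#' `sum_i || x_i - centroid ||^2` over the rows of the embedding matrix.
#'
#' @param points Numeric matrix (rows = points) or numeric vector
#'   (treated as 1-D points).
#' @return Non-negative scalar.
#' @examples
#' wcss(c(0, 2))  # 2
#' @export
wcss <- function(points) {
  x <- as.matrix(points)
  if (!nrow(x)) ickg_validation_error("empty embedding set")
  ctr <- colMeans(x)
  sum(sweep(x, 2L, ctr)^2)
}

#' Euclidean distance between the centroids of two embedding sets
#'
#' @param a,b Numeric matrices (rows = points) of matching dimension.
#' @return Non-negative scalar.
#' @export
centroid_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) ickg_validation_error("empty embedding set")
  if (ncol(a) != ncol(b)) ickg_validation_error("embedding dimension mismatch")
  sqrt(sum((colMeans(a) - colMeans(b))^2))
}

#' Two-component principal projection for plotting
#'
#' Projects embedding vectors onto their first two principal components
#' (plotting convenience only; metrics are computed in the original
#' space).
#'
#' @param points Numeric matrix (rows = points).
#' @return A matrix with two columns `PC1`, `PC2`.
#' @export
embed_project <- function(points) {
  x <- as.matrix(points)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$x))
  out <- p$x[, seq_len(k), drop = FALSE]
  if (k == 1L) out <- cbind(out, 0)
  colnames(out) <- c("PC1", "PC2")
  out
}

#' Deterministic hashing text-embedding backend
#'
#' A stand-in for a neural sentence embedder satisfying the embedding
#' contract (character vector -> numeric matrix): each word is hashed
#' into one of `dim` buckets and the bucket counts are L2-normalized.
#' Deterministic, so embedding-based metrics are testable offline.
#'
#' @param dim Embedding dimension.
#' @return A function(texts) -> matrix with `dim` columns.
#' @export
hash_embedder <- function(dim = 16L) {
  function(texts) {
    m <- matrix(0, length(texts), dim)
    for (i in seq_along(texts)) {
      words <- unlist(strsplit(tolower(texts[[i]]), "[^a-z0-9]+"))
      words <- words[nzchar(words)]
      for (w in words) {
        h <- sum(utf8ToInt(w) * seq_along(utf8ToInt(w))) %% dim + 1L
        m[i, h] <- m[i, h] + 1
      }
      nrm <- sqrt(sum(m[i, ]^2))
      if (nrm > 0) m[i, ] <- m[i, ] / nrm
    }
    rownames(m) <- names(texts)
    m
  }
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) ickg_input_error(sprintf("GMT file not found: %s", path))
  fgsea::gmtPathways(path)
}
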