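test_that("pagerank on a symmetric 2-cycle is uniform and sums to 1", {
  g <- make_graph(rbind(edge_table("A", "B"), edge_table("B", "A")))
  pr <- personalized_pagerank(g)
  expect_equal(unname(pr), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
})

test_that("personalization guarantees the restart mass lower bound", {
  ## A has no in-edges; restart on A keeps at least (1 - alpha) of the mass
  g <- make_graph(edge_table("A", c("B", "C")))
  pr <- personalized_pagerank(g, "A", pagerank_config(alpha = 0.85))
  expect_gte(pr[["A"]], 0.15)
  expect_error(personalized_pagerank(g, "NOPE"), "not found")
})

test_that("pagerank matches the independent power-iteration oracle", {
  for (s in 1:10) {
    g <- random_ickg(12L, 30L, seed = s)
    seeds <- if (s %% 2 == 0) g$nodes$key[1:2] else NULL
    mine <- personalized_pagerank(g, seeds)
    oracle <- oracle_pagerank(g, seeds)
    expect_lt(sum(abs(mine - oracle[names(mine)])), 1e-8)
    expect_equal(sum(mine), 1, tolerance = 1e-9)
  }
})

test_that("permutation p equals n/n_perm and matches the exhaustive null", {
  g0 <- random_ickg(6L, 14L, seed = 41, max_w = 9L)
  ## add a pathway candidate fed by two genes
  g <- make_graph(rbind(
    edge_table(g0$edges$source, g0$edges$target, g0$edges$direction,
               g0$edges$weight),
    edge_table(c("G01", "G03"), "pw1", weight = c(2L, 4L))),
    types = c(pw1 = "pathway"))
  genes <- g$nodes$key[g$nodes$node_type == "gene"]
  expect_length(genes, 6L)
  seed_set <- c("G01", "G02")

  res <- permutation_test(g, seed_set, candidate_nodes = "pw1",
                          n_perm = 1000L, seed = 8)
  ## p is exactly a count over 1000
  expect_equal(res$p * 1000, round(res$p * 1000))
  expect_true(res$ci_low <= res$ci_high)

  ## exhaustive oracle over all choose(6, 2) = 15 seed subsets
  obs <- personalized_pagerank(g, seed_set)[["pw1"]]
  subsets <- all_subsets(genes, 2L)
  expect_length(subsets, 15L)
  null_scores <- vapply(subsets, function(ss)
    personalized_pagerank(g, ss)[["pw1"]], numeric(1))
  p_exact <- mean(null_scores >= obs)
  se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(res$p - p_exact), 3 * se + 1e-12)
})

test_that("permutation edge cases: unbeatable candidate, add-one flag, pool size", {
  g <- make_graph(rbind(edge_table(c("G1", "G2", "G3"), "hub", weight = 5L),
                        edge_table(sprintf("G%d", 4:8), sprintf("G%d", 5:9))),
                  types = c(hub = "pathway"))
  ## permuting over genes that never reach the hub: the observed score
  ## beats every permutation, so p = 0 exactly (n/n_perm with n = 0)
  res <- permutation_test(g, c("G1", "G2", "G3"), candidate_nodes = "hub",
                          n_perm = 200L, seed = 1,
                          permute_from = sprintf("G%d", 4:9))
  expect_equal(res$p, 0)
  res2 <- permutation_test(g, c("G1", "G2", "G3"), candidate_nodes = "hub",
                           n_perm = 200L, seed = 1,
                           permute_from = sprintf("G%d", 4:9),
                           p_floor = "add-one")
  expect_equal(res2$p, 1 / 201)
  expect_error(permutation_test(g, g$nodes$key[g$nodes$node_type == "gene"][1:3],
                                permute_from = c("G1", "G2")),
               "pool")
  expect_error(permutation_test(g, character()), "non-empty")
})

test_that("permutation test is deterministic under a fixed seed", {
  g <- random_ickg(10L, 25L, seed = 6)
  a <- permutation_test(g, g$nodes$key[1:2], n_perm = 50L, seed = 99)
  b <- permutation_test(g, g$nodes$key[1:2], n_perm = 50L, seed = 99)
  expect_identical(a, b)
})

test_that("random-walk transitions follow the exp(w/T) softmax", {
  g <- make_graph(edge_table("S", c("A", "B"), weight = c(1L, 2L)))
  p <- transition_probabilities(g, "S", temperature = 1)
  expect_equal(unname(p[c("A", "B")]),
               c(exp(1), exp(2)) / (exp(1) + exp(2)), tolerance = 1e-12)
  ## equal weights -> uniform for every temperature
  geq <- make_graph(edge_table("S", c("A", "B", "C"), weight = 2L))
  for (T in c(0.1, 1, 10)) {
    expect_equal(unname(transition_probabilities(geq, "S", T)), rep(1/3, 3))
  }
  ## T -> Inf converges to uniform over out-neighbors
  pT <- transition_probabilities(g, "S", temperature = 1e6)
  expect_equal(unname(pT), c(0.5, 0.5), tolerance = 1e-5)
  expect_error(transition_probabilities(g, "S", temperature = 0), "temperature")
  expect_error(random_walk_config(temperature = -1), "temperature")
})

test_that("visit frequencies are normalized, reproducible, and stop at sinks", {
  g <- make_graph(rbind(edge_table("S", c("A", "B"), weight = c(1L, 3L)),
                        edge_table("A", "C")))
  cfg <- random_walk_config(n_walks = 200L, walk_length = 5L, seed = 17)
  f1 <- adjusted_random_walk(g, "S", cfg)
  f2 <- adjusted_random_walk(g, "S", cfg)
  expect_identical(f1, f2)
  expect_equal(sum(f1), 1)
  expect_true(all(f1 >= 0))
  ## B is a sink: walks through B must end there (never exceed the start count)
  expect_lte(f1[["B"]], f1[["S"]])
})

test_that("sampled single-step frequencies match the closed form (chi-square)", {
  g <- make_graph(edge_table("S", c("A", "B", "C"), weight = c(1L, 2L, 4L)))
  n <- 10000L
  f <- adjusted_random_walk(g, "S",
                            random_walk_config(n_walks = n, walk_length = 1L,
                                               seed = 23))
  counts <- round(f[c("A", "B", "C")] * 2 * n)  # start node holds half the visits
  expect_equal(sum(counts), n)
  p_theory <- transition_probabilities(g, "S", 1)[c("A", "B", "C")]
  gof <- stats::chisq.test(counts, p = p_theory)
  expect_gt(gof$p.value, 0.001)
})

test_that("perturbation ranks along chains with sign parity", {
  ## G -> A -> B, both activating: closer node scores higher, both activated
  g <- make_graph(rbind(edge_table("G", "A"), edge_table("A", "B")))
  res <- in_silico_perturbation(g, "G")
  expect_equal(res$ranked_genes$gene, c("A", "B"))
  expect_true(res$ranked_genes$score[1] > res$ranked_genes$score[2])
  expect_equal(res$ranked_genes$inferred_sign, c("activated", "activated"))

  ## inhibition flips parity once
  g2 <- make_graph(rbind(edge_table("G", "A", "activate"),
                         edge_table("A", "B", "inhibit")))
  res2 <- in_silico_perturbation(g2, "G")
  signs <- stats::setNames(res2$ranked_genes$inferred_sign, res2$ranked_genes$gene)
  expect_equal(unname(signs["A"]), "activated")
  expect_equal(unname(signs["B"]), "inhibited")

  ## double inhibition restores activation
  g3 <- make_graph(rbind(edge_table("G", "A", "inhibit"),
                         edge_table("A", "B", "inhibit")))
  expect_equal(in_silico_perturbation(g3, "G")$ranked_genes$inferred_sign,
               c("inhibited", "activated"))
  expect_error(in_silico_perturbation(g, "ABSENT"), "not found")
})

test_that("explanation paths: shortest hops, weight tie-break, unreachable", {
  g <- make_graph(edge_table("S", "T"))
  res <- explain_paths(g, "S", "T")
  expect_equal(res$paths$T, c("S", "T"))

  ## two 2-hop routes; the one through the weight-5 edge wins
  g2 <- make_graph(rbind(edge_table("S", "M1", weight = 5L),
                         edge_table("S", "M2", weight = 1L),
                         edge_table("M1", "T", weight = 1L),
                         edge_table("M2", "T", weight = 1L)))
  res2 <- explain_paths(g2, "S", "T")
  expect_equal(res2$paths$T, c("S", "M1", "T"))

  g3 <- make_graph(rbind(edge_table("S", "A"), edge_table("X", "Y")))
  res3 <- explain_paths(g3, "S", c("A", "Y"))
  expect_equal(res3$unreachable, "Y")
  expect_false("Y" %in% names(res3$paths))
  expect_false("Y" %in% res3$subgraph$nodes$key)
  ## subgraph preserves edge metadata
  expect_equal(res3$subgraph$edges$direction, "activate")
  expect_true(all(lengths(res3$subgraph$edges$provenance) ==
                    res3$subgraph$edges$weight))
})

test_that("gene-set annotation recovers structure and is set-semantic", {
  sim <- generate_synthetic_corpus(n_genes = 20, n_pathways = 5,
                                   n_relations = 25, seed = 13,
                                   pathway_genes = 4)
  g <- build_graph_from_corpus(sim$corpus, gazetteer_tagger(sim$gazetteer))
  ann <- annotate_gene_set(g, sim$truth$pathway_genes, n_perm = 500, seed = 2)
  expect_equal(ann$node[1], sim$truth$pathway)
  expect_lt(ann$p[1], 0.05)
  expect_true(all(ann$node_type == "pathway"))
  expect_false(any(sim$truth$pathway_genes %in% ann$node))
  ## permuting the query order changes nothing
  ann2 <- annotate_gene_set(g, rev(sim$truth$pathway_genes), n_perm = 500, seed = 2)
  expect_identical(as.data.frame(ann), as.data.frame(ann2))
  ## unmapped genes reported; none mappable -> classed error
  ann3 <- annotate_gene_set(g, c(sim$truth$pathway_genes, "NOSUCHGENE"),
                            n_perm = 100, seed = 2)
  expect_equal(attr(ann3, "unmapped"), "NOSUCHGENE")
  expect_error(annotate_gene_set(g, c("NOPE1", "NOPE2")),
               class = "ickg_nomap_error")
})

test_that("annotation is empty when no pathway node is reachable", {
  g <- make_graph(rbind(edge_table("G1", "G2"),
                        edge_table("P1", "P2")),
                  types = c(P1 = "pathway", P2 = "pathway"))
  ann <- annotate_gene_set(g, c("G1", "G2"), n_perm = 50, seed = 1)
  expect_equal(nrow(ann), 0L)
})

test_that("concept association recovers dedicated neighbor genes", {
  ## 40 cell-type concepts; CT01 feeds three dedicated genes, the rest
  ## feed random background genes
  set.seed(71)
  cts <- sprintf("CT%02d", 1:40)
  bg <- sprintf("BG%02d", 1:50)
  edges <- edge_table("CT01", c("PG1", "PG2", "PG3"), weight = 2L)
  for (k in 2:40) {
    edges <- rbind(edges, edge_table(cts[k], sample(bg, 3), weight = 1L))
  }
  edges <- rbind(edges, edge_table(sample(bg, 20), sample(bg, 20)))
  edges <- edges[edges$source != edges$target, ]
  g <- make_graph(edges, types = stats::setNames(rep("cell_type", 40), cts))
  hits <- concept_associated_genes(g, "CT01", significance = 0.05,
                                   n_perm = 1000, seed = 5)
  expect_setequal(hits, c("PG1", "PG2", "PG3"))
  ## threshold 0 can never be met with a strict inequality
  expect_length(concept_associated_genes(g, "CT01", significance = 0,
                                         n_perm = 200, seed = 5), 0L)
  ## a concept with no outgoing edges is associated with nothing
  g2 <- make_graph(edge_table(c("G1", "G2"), "CTX"),
                   types = c(CTX = "cell_type"))
  expect_length(concept_associated_genes(g2, "CTX", n_perm = 100, seed = 1), 0L)
})

test_that("concept similarity is a Jaccard matrix with unit diagonal", {
  ## B is shared by two of the 100 concepts, so its permutation p is
  ## about 2/100 for either seed concept, safely below 0.05
  set.seed(72)
  cts <- sprintf("CT%03d", 1:100)
  edges <- rbind(edge_table("CT001", c("A", "B"), weight = 3L),
                 edge_table("CT002", c("B", "C"), weight = 3L))
  for (k in 3:100) edges <- rbind(edges,
    edge_table(cts[k], sprintf("BG%02d", sample(30, 2)), weight = 1L))
  g <- make_graph(edges, types = stats::setNames(rep("cell_type", 100), cts))
  m <- concept_similarity_matrix(g, c("CT001", "CT002"), significance = 0.05,
                                 n_perm = 1000, seed = 9)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), c(1, 1))
  ## keys are case-folded for non-gene node types
  expect_equal(m["ct001", "ct002"], 1/3)  # {A,B} vs {B,C}
  expect_error(concept_similarity_matrix(g, "CT001"), ">= 2")
})

test_that("degree-preserving shuffle keeps degrees, weights, signs; deterministic", {
  g <- random_ickg(15L, 40L, seed = 3)
  s1 <- shuffle_graph(g, seed = 11)
  s2 <- shuffle_graph(g, seed = 11)
  expect_identical(s1, s2)
  deg <- function(gg) list(
    out = sort(table(factor(gg$edges$source, levels = gg$nodes$key))),
    inn = sort(table(factor(gg$edges$target, levels = gg$nodes$key))))
  expect_equal(deg(s1), deg(g))
  expect_equal(sort(s1$edges$weight), sort(g$edges$weight))
  expect_equal(table(s1$edges$direction), table(g$edges$direction))
  expect_identical(s1$nodes, g$nodes)
  ## connectivity actually changed
  expect_false(identical(paste(s1$edges$source, s1$edges$target),
                         paste(g$edges$source, g$edges$target)))
  tiny <- make_graph(edge_table("A", "B"))
  expect_warning(same <- shuffle_graph(tiny, 1), "too small")
  expect_identical(same, tiny)
})
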