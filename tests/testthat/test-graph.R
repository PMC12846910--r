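test_that("assembly counts distinct supporting abstracts per signed edge", {
  tr <- data.frame(source = "A", source_type = "gene",
                   target = "B", target_type = "gene",
                   direction = "activate", abstract_id = c("p1", "p2"),
                   stringsAsFactors = FALSE)
  g <- assemble_graph(tr)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 2L)
  expect_setequal(g$edges$provenance[[1]], c("p1", "p2"))

  ## parallel activate/inhibit edges coexist
  tr2 <- rbind(tr[1, ], within(tr[1, ], {direction <- "inhibit"; abstract_id <- "p3"}))
  g2 <- assemble_graph(tr2)
  expect_equal(nrow(g2$edges), 2L)
  expect_equal(sort(g2$edges$direction), c("activate", "inhibit"))
  expect_equal(g2$edges$weight, c(1L, 1L))

  ## duplicate triple from the same abstract counts once
  tr3 <- tr; tr3$abstract_id <- c("p1", "p1")
  expect_equal(assemble_graph(tr3)$edges$weight, 1L)

  expect_error(assemble_graph(within(tr, source <- "")), "empty entity name")
})

test_that("total edge weight equals the distinct (s,t,dir,abstract) tuples", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 40L
    tr <- data.frame(
      source = sample(LETTERS[1:6], n, replace = TRUE),
      source_type = "gene",
      target = sample(letters[1:5], n, replace = TRUE),
      target_type = "pathway",
      direction = sample(c("activate", "inhibit"), n, replace = TRUE),
      abstract_id = sample(sprintf("p%d", 1:8), n, replace = TRUE),
      stringsAsFactors = FALSE)
    g <- assemble_graph(tr)
    n_distinct <- nrow(unique(data.frame(toupper(tr$source), tr$target,
                                         tr$direction, tr$abstract_id)))
    expect_equal(sum(g$edges$weight), n_distinct)
  }
})

test_that("name case-folding merges mentions; cross-type collisions stay distinct", {
  tr <- data.frame(source = c("il15", "IL15", "apoptosis"),
                   source_type = c("gene", "gene", "pathway"),
                   target = c("Apoptosis", "apoptosis", "NK Cells"),
                   target_type = c("pathway", "pathway", "cell_type"),
                   direction = "activate",
                   abstract_id = c("p1", "p2", "p3"), stringsAsFactors = FALSE)
  g <- assemble_graph(tr)
  expect_setequal(g$nodes$name, c("IL15", "apoptosis", "nk cells"))
  expect_equal(g$edges$weight[g$edges$source == "IL15"], 2L)

  ## same folded string under two types -> two nodes keyed name|type
  tr2 <- data.frame(source = c("G1", "G2"), source_type = c("gene", "gene"),
                    target = c("Apoptosis", "apoptosis"),
                    target_type = c("pathway", "cell_type"),
                    direction = "activate", abstract_id = c("p1", "p2"),
                    stringsAsFactors = FALSE)
  g2 <- assemble_graph(tr2)
  expect_true(all(c("apoptosis|pathway", "apoptosis|cell_type") %in% g2$nodes$key))
})

test_that("graph statistics count nodes, signed edges, and degree centrality", {
  g <- make_graph(rbind(
    edge_table("A", "B", "activate", 1L),
    edge_table("A", "B", "inhibit", 1L)))
  st <- graph_stats(g)
  expect_equal(st$n_nodes, 2L)
  expect_equal(st$n_activate, 1L)
  expect_equal(st$n_inhibit, 1L)
  expect_equal(st$n_edges, st$n_activate + st$n_inhibit)

  ## star: hub with 4 spokes has degree centrality 1
  star <- make_graph(edge_table("HUB", c("S1", "S2", "S3", "S4")))
  stc <- graph_stats(star)
  expect_equal(unname(stc$degree_centrality["HUB"]), 1)
  expect_equal(sum(stc$node_type_counts), stc$n_nodes)

  ## planted graph stats match the generator's truth
  sim <- generate_synthetic_corpus(n_genes = 8, n_pathways = 2,
                                   n_relations = 10, seed = 3)
  gg <- build_graph_from_corpus(sim$corpus, gazetteer_tagger(sim$gazetteer))
  stg <- graph_stats(gg)
  expect_equal(stg$n_edges, nrow(sim$truth$triples))
  expect_equal(stg$n_activate, sum(sim$truth$triples$direction == "activate"))
  used <- unique(c(sim$truth$triples$source, sim$truth$triples$target))
  expect_equal(stg$n_nodes, length(used))
})

test_that("top-weight subgraph keeps the weight quantile with ties", {
  w <- c(1L, 1L, 1L, 1L, 10L)
  g <- make_graph(edge_table(sprintf("A%d", 1:5), sprintf("B%d", 1:5),
                             weight = w))
  expect_equal(top_edge_subgraph(g, 1.0)$edges$weight, g$edges$weight)
  top <- top_edge_subgraph(g, 0.2)
  expect_equal(top$edges$weight, 10L)
  expect_equal(nrow(top$nodes), 2L)  # isolated nodes dropped
  ## all-equal weights: everything survives any fraction (tie rule)
  geq <- make_graph(edge_table(sprintf("A%d", 1:5), sprintf("B%d", 1:5)))
  expect_equal(nrow(top_edge_subgraph(geq, 0.005)$edges), 5L)
  expect_error(top_edge_subgraph(g, 0), "fraction")
  expect_error(top_edge_subgraph(g, 1.5), "fraction")
})

test_that("GraphML and TSV serialization round-trip exactly with provenance", {
  sim <- generate_synthetic_corpus(n_genes = 7, n_pathways = 2,
                                   n_relations = 9,
                                   abstracts_per_relation = 2, seed = 19)
  g <- build_graph_from_corpus(sim$corpus, gazetteer_tagger(sim$gazetteer))
  for (fmt in c("graphml", "tsv")) {
    tf <- tempfile(fileext = paste0(".", if (fmt == "graphml") "graphml" else "tsv"))
    write_graph_file(g, tf, format = fmt)
    back <- read_graph_file(tf, format = fmt)
    expect_equal(back$nodes, g$nodes, info = fmt)
    expect_equal(back$edges, g$edges, info = fmt)
  }
  ## both dialects agree on stats
  t1 <- tempfile(fileext = ".graphml"); t2 <- tempfile(fileext = ".tsv")
  write_graph_file(g, t1); write_graph_file(g, t2)
  expect_equal(graph_stats(read_graph_file(t1))[c("n_nodes", "n_edges")],
               graph_stats(read_graph_file(t2))[c("n_nodes", "n_edges")])
})

test_that("unknown node types and malformed graph files are rejected", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("source\tsource_type\ttarget\ttarget_type\tdirection\tweight\tprovenance",
               "A\tgene\tB\tplanet\tactivate\t1\tp1"), tf)
  expect_error(read_graph_file(tf), "node_type")
  bad <- tempfile(fileext = ".graphml")
  writeLines("<graphml><unclosed>", bad)
  expect_error(read_graph_file(bad), "malformed|GraphML")
})

test_that("collapsed igraph view sums parallel signed edges", {
  g <- make_graph(rbind(edge_table("A", "B", "activate", 3L),
                        edge_table("A", "B", "inhibit", 1L),
                        edge_table("B", "C", "inhibit", 2L)))
  ig <- as_igraph(g, collapse = TRUE)
  ed <- igraph::as_data_frame(ig)
  ab <- ed[ed$from == "A" & ed$to == "B", ]
  expect_equal(ab$weight, 4)
  expect_equal(ab$direction, "activate")  # dominant sign
  expect_equal(nrow(ed), 2L)
})
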