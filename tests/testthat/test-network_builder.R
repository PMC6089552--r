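test_that("regulation flags follow the fold-change and FDR thresholds", {
  expr <- data.frame(gene = c("A", "B", "C", "D"),
                     log2fc = c(1.2, -0.5, -2.0, 1.8),
                     fdr = c(0.005, 0.001, 0.02, 0.009))
  reg <- annotate_regulation(c("A", "B", "C", "D", "Z"), expr)
  expect_equal(reg$regulated, c("UP", "NONE", "NONE", "UP", "NONE"))
  expect_true(is.na(reg$log2fc[reg$gene == "Z"]))
  reg2 <- annotate_regulation("C", expr, fdr_max = 0.05)
  expect_equal(reg2$regulated, "DOWN")
})

test_that("PPI filtering is strict at the 0.8 boundary, experimental only", {
  edges <- data.frame(gene_a = c("A", "A", "A"), gene_b = c("B", "C", "D"),
                      channel = c("experimental", "experimental", "textmining"),
                      score = c(0.85, 0.80, 0.99))
  kept <- filter_ppi(edges)
  expect_equal(kept$gene_b, "B")   # 0.80 dropped (strict), textmining dropped
  expect_equal(nrow(filter_ppi(edges, channels = c("experimental", "textmining"))),
               2L)
})

test_that("a small network assembles with the expected nodes and edges", {
  cand <- data.frame(gene = c("A", "B"), exclusive = c(TRUE, FALSE),
                     enriched = c(FALSE, TRUE))
  tmap <- list(CMP1 = c("A", "B", "X"))
  ppi <- data.frame(gene_a = "A", gene_b = "B", channel = "experimental",
                    score = 0.9)
  net <- build_network(cand, tmap, hit_set = "CMP1", ppi = ppi)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(net$nodes$type,
                  c("COMPOUND", "TARGET_EXCLUSIVE", "TARGET_ENRICHED"))
  # PPI edges never touch a compound node
  compounds <- net$nodes$id[net$nodes$type == "COMPOUND"]
  ppi_e <- net$edges[net$edges$type == "PPI", ]
  expect_false(any(c(ppi_e$from, ppi_e$to) %in% compounds))
  # every edge endpoint resolves
  expect_true(all(c(net$edges$from, net$edges$to) %in% net$nodes$id))
})

test_that("orphan candidates are excluded and empty input gives empty network", {
  cand <- data.frame(gene = c("A", "Z"), exclusive = TRUE, enriched = FALSE)
  tmap <- list(CMP1 = "A")
  ppi <- data.frame(gene_a = character(), gene_b = character(),
                    channel = character(), score = numeric())
  expect_warning(net <- build_network(cand, tmap, "CMP1", ppi), "Z")
  expect_false("Z" %in% net$nodes$id)
  empty <- build_network(cand[0, ], tmap, "CMP1", ppi)
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("network export round-trips and is byte-deterministic", {
  cand <- data.frame(gene = c("A", "B", "C"),
                     exclusive = c(TRUE, FALSE, TRUE),
                     enriched = c(TRUE, TRUE, FALSE))
  tmap <- list(CMP1 = c("A", "B"), CMP2 = c("C", "B"))
  ppi <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                    channel = "experimental", score = c(0.9, 0.85))
  reg <- data.frame(gene = c("A", "B", "C"), log2fc = c(1.5, NA, -2),
                    regulated = c("UP", "NONE", "DOWN"))
  net <- build_network(cand, tmap, c("CMP1", "CMP2"), ppi, reg,
                       direct_targets = "A")
  pre <- file.path(withr::local_tempdir(), "net")
  files <- export_network(net, pre)
  expect_true(all(file.exists(paste0(pre, c(".sif", ".nodes.tsv",
                                            ".edges.tsv", ".graphml")))))
  sif <- readLines(paste0(pre, ".sif"))
  expect_equal(length(sif), nrow(net$edges))
  expect_true(all(grepl("\t(targets|ppi)\t", sif)))
  back <- read_network_tables(pre)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  g <- igraph::read_graph(paste0(pre, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  # rebuilding and re-exporting is byte-identical
  pre2 <- file.path(withr::local_tempdir(), "net")
  export_network(build_network(cand, tmap, c("CMP1", "CMP2"), ppi, reg,
                               direct_targets = "A"), pre2)
  for (ext in c(".sif", ".nodes.tsv", ".edges.tsv", ".graphml"))
    expect_identical(readLines(paste0(pre, ext)), readLines(paste0(pre2, ext)))
  expect_error(export_network(net, pre, formats = "gml"), "unknown export")
  # empty network: empty SIF, header-only node table
  emptyn <- build_network(cand[0, ], tmap, "CMP1", ppi)
  export_network(emptyn, pre)
  expect_equal(readLines(paste0(pre, ".sif")), character(0))
  expect_equal(length(readLines(paste0(pre, ".nodes.tsv"))), 1L)
})
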