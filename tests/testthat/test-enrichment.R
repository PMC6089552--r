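test_that("one-sided Fisher p matches exhaustive enumeration", {
  expect_equal(fisher_exact(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(fisher_exact(3, 0, 0, 0), 1)    # degenerate margin
  expect_equal(fisher_exact(5, 0, 5, 0), 1)    # b = d = 0
  for (n in 1:9) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      expect_equal(fisher_exact(a, b, c, d),
                   oracle_fisher_greater(a, b, c, d), tolerance = 1e-12)
    }
  }
  expect_error(fisher_exact(-1, 0, 0, 1), "nonnegative")
  expect_error(fisher_exact(0, 0, 0, 0), "empty")
  # two-sided agrees with the classical test
  expect_equal(fisher_exact(8, 2, 1, 5, sided = "two.sided"),
               fisher.test(matrix(c(8, 2, 1, 5), 2, byrow = TRUE))$p.value)
})

test_that("BH adjustment matches the literal step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(99)
  for (i in 1:10) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))   # monotone in sorted-p order
  }
})

test_that("exclusive and enriched target genes are identified correctly", {
  # gene E: 1 hit, 0 non-hits -> exclusive regardless of q
  # gene U: targeted by equal fractions of hits and non-hits -> no candidate
  # gene V: targeted by all hits and 2 non-hits -> enriched, not exclusive
  map <- c(
    lapply(1:10, function(i) c("V", if (i %% 2) "U", sprintf("B%02d", i))),
    lapply(11:40, function(i) c(if (i %% 2) "U", sprintf("B%02d", i)))
  )
  names(map) <- sprintf("C%02d", 1:40)
  map$C01 <- c(map$C01, "E")
  map$C11 <- c(map$C11, "V"); map$C12 <- c(map$C12, "V")
  hits <- sprintf("C%02d", 1:10)
  res <- candidate_genes(map, hits, q_threshold = 0.05)
  expect_true(res$exclusive[res$gene == "E"])
  expect_true(res$candidate[res$gene == "E"])
  expect_equal(res$c[res$gene == "E"], 0L)
  expect_true(res$enriched[res$gene == "V"])
  expect_false(res$exclusive[res$gene == "V"])
  expect_false(res$candidate[res$gene == "U"])
  # 2x2 margins add up to the background split
  expect_true(all(res$a + res$b == 10L))
  expect_true(all(res$c + res$d == 30L))
  # p-values match the enumeration oracle row by row
  for (i in seq_len(nrow(res)))
    expect_equal(res$p[i],
                 oracle_fisher_greater(res$a[i], res$b[i], res$c[i], res$d[i]),
                 tolerance = 1e-12)
  # invariance under compound relabeling
  perm <- sample(names(map))
  map2 <- map[perm]
  res2 <- candidate_genes(map2, hits)
  expect_equal(res2[order(res2$gene), ], res[order(res$gene), ],
               ignore_attr = TRUE)
  expect_warning(candidate_genes(map, character(0)), "empty candidate")
})

test_that("term enrichment ranks a self-term first and matches Fisher", {
  genes <- sprintf("G%02d", 1:8)
  background <- sprintf("G%02d", 1:60)
  ann <- rbind(
    data.frame(term = "T:self", gene = genes),
    data.frame(term = "T:disjoint", gene = sprintf("G%02d", 40:50)),
    data.frame(term = "T:half", gene = c(genes[1:4], sprintf("G%02d", 30:35))))
  res <- term_enrichment(genes, ann, background, q_threshold = 2)
  expect_equal(res$term[1], "T:self")
  expect_equal(res$p[res$term == "T:disjoint"], 1)
  for (i in seq_len(nrow(res))) {
    tg <- unique(ann$gene[ann$term == res$term[i]])
    a <- length(intersect(genes, tg))
    expect_equal(res$p[i],
                 oracle_fisher_greater(a, 8 - a, length(tg) - a,
                                       60 - 8 - (length(tg) - a)),
                 tolerance = 1e-12)
  }
  # EASE variant is more conservative
  res_e <- term_enrichment(genes, ann, background, q_threshold = 2, ease = TRUE)
  expect_true(all(res_e$p[match(res$term, res_e$term)] >= res$p))
  expect_error(term_enrichment(c(genes, "NOT_THERE"), ann, background),
               "NOT_THERE")
})

test_that("planted selective-target genes are recovered as candidates", {
  cfg <- simulation_config(seed = 17)
  sc <- generate_screen(cfg)
  tt <- generate_target_table(sc$truth, cfg)
  tmap <- merge_target_sets(filter_affinity_records(tt$affinity),
                            filter_interaction_records(tt$interaction))
  hits <- sc$truth$compounds$compound_id[
    sc$truth$compounds$class == "HIGH_SELECTIVE"]
  res <- candidate_genes(tmap, hits)
  planted <- sc$truth$genes$gene[sc$truth$genes$planted_selective]
  expect_true(all(planted %in% res$gene[res$candidate]))
})
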