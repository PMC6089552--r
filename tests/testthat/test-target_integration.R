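test_that("affinity filtering applies every evidence rule", {
  keep <- aff_record(measure_value = 500)                     # IC50 500 nM
  expect_equal(nrow(filter_affinity_records(keep)), 1L)
  expect_equal(nrow(filter_affinity_records(
    aff_record(measure_value = 2000, confidence = 9))), 0L)   # >= 1 uM
  expect_equal(nrow(filter_affinity_records(
    aff_record(measure_type = "KI", measure_value = 100, confidence = 3))), 0L)
  expect_equal(nrow(filter_affinity_records(
    aff_record(reference = ""))), 0L)                         # no reference
  expect_equal(nrow(filter_affinity_records(aff_record(gene = ""))), 0L)
  expect_equal(nrow(filter_affinity_records(
    aff_record(measure_unit = "mg/ml"))), 0L)                 # unknown unit
  expect_equal(nrow(filter_affinity_records(
    aff_record(organism = "Rattus norvegicus"))), 0L)
  expect_equal(nrow(filter_affinity_records(
    aff_record(measure_type = "EC50"))), 0L)
  # boundary: exactly 1 uM is excluded (strict <)
  expect_equal(nrow(filter_affinity_records(
    aff_record(measure_value = 1, measure_unit = "uM"))), 0L)
  # unit conversion: 0.5 uM = 500 nM survives and is normalized to nM
  conv <- filter_affinity_records(aff_record(measure_value = 0.5,
                                             measure_unit = "uM"))
  expect_equal(conv$measure_value, 500)
  expect_equal(conv$measure_unit, "nM")
})

test_that("interaction filtering keeps the right channels at >= 0.8", {
  expect_equal(nrow(filter_interaction_records(
    inter_record(channel = "experimental", score = 0.85))), 1L)
  expect_equal(nrow(filter_interaction_records(
    inter_record(channel = "textmining", score = 0.95))), 0L)
  expect_equal(nrow(filter_interaction_records(
    inter_record(channel = "databases", score = 0.8))), 1L)   # inclusive
  expect_equal(nrow(filter_interaction_records(
    inter_record(channel = "experimental", score = 0.79))), 0L)
})

test_that("filters are idempotent and every survivor satisfies its predicate", {
  cfg <- simulation_config(n_compounds = 60, corruption_frac = 0.4, seed = 8)
  tr <- generate_screen(cfg)$truth
  tt <- generate_target_table(tr, cfg)
  a1 <- filter_affinity_records(tt$affinity)
  expect_identical(filter_affinity_records(a1), a1)
  i1 <- filter_interaction_records(tt$interaction)
  expect_identical(filter_interaction_records(i1), i1)
  expect_true(all(a1$reference != "" & a1$measure_value < 1000 &
                    a1$confidence >= 4 & a1$organism == "Homo sapiens"))
  expect_true(all(i1$channel %in% c("experimental", "databases") &
                    i1$score >= 0.8))
})

test_that("target sets merge as unions keyed by compound", {
  aff <- aff_record(compound_id = c("C1", "C1"), gene = c("A", "B"))
  inter <- inter_record(compound_id = c("C1", "C2"), gene = c("B", "C"))
  m <- merge_target_sets(filter_affinity_records(aff),
                         filter_interaction_records(inter))
  expect_equal(m$C1, c("A", "B"))
  expect_equal(m$C2, "C")
  # compound with only corrupted records is absent, not empty
  aff2 <- rbind(aff, aff_record(compound_id = "C3", reference = ""))
  m2 <- merge_target_sets(filter_affinity_records(aff2),
                          filter_interaction_records(inter))
  expect_false("C3" %in% names(m2))
  expect_equal(length(m2), 2L)
  # curated entries bypass filtering
  m3 <- merge_target_sets(filter_affinity_records(aff),
                          filter_interaction_records(inter),
                          curated = data.frame(compound_id = "C3", gene = "D"))
  expect_equal(m3$C3, "D")
  tab <- target_map_table(filter_affinity_records(aff),
                          filter_interaction_records(inter))
  expect_equal(tab$provenance[tab$compound_id == "C1" & tab$gene == "B"],
               "affinity,interaction")
})

test_that("promiscuity medians match a sort-based oracle", {
  m <- list(H1 = c("A", "B"), H2 = c("A", "B", "C", "D"),
            H3 = letters[1:6], N1 = letters[1:5], N2 = "A", N3 = letters[1:7])
  ps <- promiscuity_summary(m, hit_set = c("H1", "H2", "H3", "H9"))
  expect_equal(ps$median_hits, 4)               # {2, 4, 6} -> 4
  expect_equal(ps$median_nonhits, 5)            # {5, 1, 7} -> 5
  # compounds absent from the map are excluded ("with at least one known
  # target"): H9 has no target info and does not shift the median
  expect_equal(length(ps$counts_hits), 3L)
  set.seed(55)
  big <- lapply(seq_len(80), function(i)
    sample(sprintf("G%03d", 1:50), sample(1:12, 1)))
  names(big) <- sprintf("C%03d", seq_len(80))
  hits <- sample(names(big), 25)
  ps2 <- promiscuity_summary(big, hits)
  expect_equal(unname(ps2$median_hits),
               unname(oracle_median(lengths(big)[names(big) %in% hits])))
  expect_equal(unname(ps2$median_nonhits),
               unname(oracle_median(lengths(big)[!names(big) %in% hits])))
  expect_warning(promiscuity_summary(m["N1"], "H1"), "undefined")
})
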