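test_that("unscaled MAD matches hand values and the sort-based oracle", {
  expect_equal(mad_unscaled(c(1, 1, 1)), 0)
  expect_equal(mad_unscaled(c(1, 2, 3, 4, 100)), 1)
  expect_error(mad_unscaled(numeric(0)), "empty")
  set.seed(19)
  for (i in 1:25) {
    x <- rnorm(sample(1:40, 1))
    expect_equal(mad_unscaled(x), oracle_mad(x))
    k <- runif(1, -3, 3); c0 <- runif(1, -5, 5)
    expect_equal(mad_unscaled(x + c0), mad_unscaled(x))
    expect_equal(mad_unscaled(k * x), abs(k) * mad_unscaled(x))
  }
})

test_that("hit threshold and hit set match the hand-computed example", {
  # log2 viabilities {-5, 0.1, -0.1, 0.2, -0.2, 0}: median -0.05, MAD 0.15,
  # threshold -0.5. Duplicating the set leaves median and MAD unchanged
  # while satisfying the >= 10 compound-well precondition.
  l2 <- rep(c(-5, 0.1, -0.1, 0.2, -0.2, 0), 2)
  nw <- make_norm_wells(l2, sprintf("C%02d", 1:12))
  h <- call_hits(nw, "HIGH", k = 3)
  expect_equal(unname(attr(h, "threshold")["S1"]), -0.5)
  expect_setequal(hit_compounds(h), c("C01", "C07"))
})

test_that("degenerate dispersion is an error and hits are monotone in k", {
  nw <- make_norm_wells(rep(0, 12), sprintf("C%02d", 1:12))
  expect_error(call_hits(nw, "HIGH"), "degenerate dispersion")
  set.seed(23)
  nw <- make_norm_wells(rnorm(40, 0, 0.5), sprintf("C%02d", 1:40))
  hits_by_k <- lapply(c(1, 2, 3), function(k)
    hit_compounds(call_hits(nw, "HIGH", k = k)))
  expect_true(all(hits_by_k[[2]] %in% hits_by_k[[1]]))
  expect_true(all(hits_by_k[[3]] %in% hits_by_k[[2]]))
})

test_that("threshold arithmetic classifies the three worked cases", {
  smry <- data.frame(
    screen_id = "S1",
    compound_id = rep(c("A", "B", "C"), each = 2),
    condition = rep(c("HIGH", "LOW"), 3),
    concentration = 1,
    viability = c(0.3, 0.7, 0.4, 0.4, 0.8, 0.2),
    n_wells = 1L)
  smry$log2_viability <- log2(smry$viability)
  fake_hits <- function(ids) data.frame(compound_id = ids,
                                        hit = rep(TRUE, length(ids)))
  calls <- classify_differential(fake_hits("A"), fake_hits(c("B", "C")), smry)
  expect_equal(calls$group[calls$compound_id == "A"], "HIGH_SELECTIVE")
  expect_equal(calls$best_fold_ratio[calls$compound_id == "A"], 0.7 / 0.3)
  expect_equal(calls$group[calls$compound_id == "B"], "NONSELECTIVE_ACTIVE")
  expect_equal(calls$group[calls$compound_id == "C"], "LOW_SELECTIVE")
  # not hit anywhere -> INACTIVE even with a large ratio
  calls2 <- classify_differential(fake_hits(character(0)),
                                  fake_hits(character(0)), smry)
  expect_true(all(calls2$group == "INACTIVE"))
  # fold_only relaxes the hit requirement
  calls3 <- classify_differential(fake_hits(character(0)),
                                  fake_hits(character(0)), smry,
                                  fold_only = TRUE)
  expect_equal(calls3$group[calls3$compound_id == "A"], "HIGH_SELECTIVE")
})

test_that("no shared concentration is a comparability error", {
  smry <- data.frame(screen_id = "S1", compound_id = "A",
                     condition = c("HIGH", "LOW"), concentration = c(1, 2),
                     viability = c(0.5, 0.5), n_wells = 1L,
                     log2_viability = log2(0.5))
  fh <- data.frame(compound_id = character(), hit = logical())
  expect_error(classify_differential(fh, fh, smry), "shared")
})

test_that("swapping condition labels swaps the selective classes", {
  # 40 compounds x 2 doses exactly fill one 96-well plate per condition
  cfg <- simulation_config(n_compounds = 40, plate_format = 96,
                           concentrations = c(2.5, 0.25),
                           control_wells_per_plate = 16, seed = 41)
  sc <- generate_screen(cfg)
  w <- sc$wells[, setdiff(names(sc$wells), "true_viability")]
  nw <- normalize_screen(w)
  smry <- summarize_viability(nw)
  hh <- call_hits(nw, "HIGH"); hl <- call_hits(nw, "LOW")
  calls <- classify_differential(hh, hl, smry)
  # swap labels
  nw2 <- nw
  nw2$condition <- ifelse(nw$condition == "HIGH", "LOW", "HIGH")
  smry2 <- summarize_viability(nw2)
  calls2 <- classify_differential(call_hits(nw2, "HIGH"),
                                  call_hits(nw2, "LOW"), smry2)
  m <- merge(calls, calls2, by = "compound_id")
  swap <- c(HIGH_SELECTIVE = "LOW_SELECTIVE", LOW_SELECTIVE = "HIGH_SELECTIVE",
            NONSELECTIVE_ACTIVE = "NONSELECTIVE_ACTIVE", INACTIVE = "INACTIVE")
  expect_equal(unname(swap[m$group.x]), m$group.y)
})
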