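# synthetic_data: complete synthetic screens plus matched drug-target,
# expression, ChIP and PPI tables with a ground-truth manifest.
#
# The generative model: raw_signal = plate_scale * S(row, col) * v * eps,
# where S is a smooth strictly positive spatial surface (bilinear gradient +
# one Gaussian bump + edge attenuation), v is four-parameter logistic
# viability in [0, 1] with a condition-specific IC50 shift for selective
# compounds, and eps is lognormal measurement noise.

#' Simulation configuration for a synthetic two-condition screen
#'
#' Defaults describe a mid-sized screen: 200 compounds on 384-well plates at
#' the six-point dose grid 25, 8.3, 2.8 uM / 926, 308, 103 nM, with 5% of
#' compounds selectively potent in each condition, 5% active in both, and
#' the rest inactive. Negative-control (DMSO) wells occupy the first and
#' last plate columns, deliberately overlapping the edge-effect region so
#' that normalization is stressed where artifacts are worst.
#'
#' @param n_compounds number of distinct test compounds.
#' @param plate_format 384 or 96.
#' @param concentrations micromolar dose grid (strictly positive, distinct);
#'   every compound is tested once at every concentration.
#' @param frac_high_selective,frac_low_selective,frac_nonselective_active
#'   fractions of compounds in each active class; the remainder is inactive.
#' @param control_wells_per_plate number of DMSO wells per plate (placed in
#'   the first column top-down, then the last column).
#' @param spatial_amplitude strength of the multiplicative plate-position
#'   artifact (0 = perfectly flat plates).
#' @param noise_sigma sigma of the lognormal measurement noise (log scale).
#' @param promiscuity_mean mean number of annotated targets per compound
#'   (shifted geometric distribution, minimum 1).
#' @param n_genes size of the background gene universe.
#' @param n_planted_genes number of planted selective-target genes; these
#'   are targeted only by HIGH-selective compounds and are the ground truth
#'   for candidate-gene recovery.
#' @param corruption_frac fraction of drug-target records corrupted with a
#'   random defect (missing reference, missing/unknown units, non-human
#'   organism, low confidence, weak affinity) to exercise the filters.
#' @param selectivity_shift multiplicative IC50 shift between conditions
#'   for selective compounds (>= 4; default 8, about one log unit).
#' @param plate_scale baseline luminescence signal of an untreated well.
#' @param n_plates number of plates per condition; derived from capacity if
#'   `NULL`, an error if too small.
#' @param screen_id batch label for the screen.
#' @param seed integer seed; a fixed seed makes every generated artifact
#'   bit-identical across runs.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_compounds = 200,
                              plate_format = 384,
                              concentrations = c(25, 8.3, 2.8, 0.926, 0.308, 0.103),
                              frac_high_selective = 0.05,
                              frac_low_selective = 0.05,
                              frac_nonselective_active = 0.05,
                              control_wells_per_plate = NULL,
                              spatial_amplitude = 0.3,
                              noise_sigma = 0.05,
                              promiscuity_mean = 4,
                              n_genes = 300,
                              n_planted_genes = 10,
                              corruption_frac = 0.15,
                              selectivity_shift = 8,
                              plate_scale = 1e5,
                              n_plates = NULL,
                              screen_id = "S1",
                              seed = 1L) {
  dims <- plate_dims(plate_format)
  if (is.null(control_wells_per_plate))
    control_wells_per_plate <- 2L * dims[["rows"]]
  fr <- c(frac_high_selective, frac_low_selective, frac_nonselective_active)
  if (any(fr < 0) || sum(fr) > 1)
    stop_schema("class fractions must be nonnegative and sum to at most 1")
  if (any(concentrations <= 0) || anyDuplicated(concentrations))
    stop_schema("concentrations must be strictly positive and distinct")
  if (control_wells_per_plate < 1L ||
      control_wells_per_plate > 2L * dims[["rows"]])
    stop_schema("control_wells_per_plate must be between 1 and %d",
                2L * dims[["rows"]])
  if (selectivity_shift < 4)
    stop_schema("selectivity_shift must be at least 4")
  if (noise_sigma < 0 || spatial_amplitude < 0)
    stop_schema("noise_sigma and spatial_amplitude must be nonnegative")
  cfg <- list(n_compounds = as.integer(n_compounds),
              plate_format = as.integer(plate_format),
              concentrations = sort(as.numeric(concentrations), decreasing = TRUE),
              frac_high_selective = frac_high_selective,
              frac_low_selective = frac_low_selective,
              frac_nonselective_active = frac_nonselective_active,
              control_wells_per_plate = as.integer(control_wells_per_plate),
              spatial_amplitude = spatial_amplitude,
              noise_sigma = noise_sigma,
              promiscuity_mean = promiscuity_mean,
              n_genes = as.integer(n_genes),
              n_planted_genes = as.integer(n_planted_genes),
              corruption_frac = corruption_frac,
              selectivity_shift = selectivity_shift,
              plate_scale = plate_scale,
              n_plates = if (is.null(n_plates)) NULL else as.integer(n_plates),
              screen_id = as.character(screen_id),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Strictly positive multiplicative spatial surface for one plate:
# 1 + amplitude * (bilinear gradient + Gaussian bump), times an edge
# attenuation on the outermost rows/columns. Coefficients are drawn from
# the current RNG stream.
make_surface <- function(nrow, ncol, amplitude) {
  r <- (seq_len(nrow) - 1) / max(nrow - 1, 1) - 0.5
  c_ <- (seq_len(ncol) - 1) / max(ncol - 1, 1) - 0.5
  a <- stats::runif(2, -1, 1)                    # gradient direction
  grad <- outer(r, c_, function(x, y) a[1] * x + a[2] * y)
  ctr <- c(stats::runif(1, 0.2, 0.8) * (nrow - 1),
           stats::runif(1, 0.2, 0.8) * (ncol - 1))
  sig <- stats::runif(1, 2.5, 4.5)
  bump_sign <- sample(c(-1, 1), 1)
  bump <- bump_sign * outer(seq_len(nrow) - 1, seq_len(ncol) - 1,
                            function(x, y) exp(-((x - ctr[1])^2 + (y - ctr[2])^2) /
                                                 (2 * sig^2)))
  s <- 1 + amplitude * (0.6 * grad + 0.5 * bump)
  # smooth edge attenuation: exponential decay of signal loss with distance
  # from the nearest plate border (evaporation-style edge effect)
  dist_edge <- outer(seq_len(nrow) - 1, seq_len(ncol) - 1, function(x, y)
    pmin(x, nrow - 1 - x, y, ncol - 1 - y))
  s <- s * (1 - 0.4 * amplitude * exp(-dist_edge / 2))
  stopifnot(all(s > 0))
  s
}

# Four-parameter logistic viability, bottom 0 / top 1.
logistic_viability <- function(conc, ic50, hill) {
  1 / (1 + (conc / ic50)^hill)
}

#' Generate a synthetic two-condition viability screen
#'
#' Produces raw well measurements for both conditions (identical compound
#' layouts, independent plate surfaces and noise) together with the
#' ground-truth manifest: per-compound class labels and true dose-response
#' parameters, planted selective-target genes, and the exact spatial surface
#' of every plate. Selective compounds have their IC50 in the resistant
#' condition shifted up by `selectivity_shift`; the IC50 in the sensitive
#' condition is drawn so that the compound inhibits at least 75% of
#' viability at the middle of the dose grid.
#'
#' @param config a [simulation_config()] object.
#' @return list with elements `wells` (data.frame of well measurements for
#'   both conditions) and `truth` (list: `compounds`, `genes`, `surfaces`,
#'   `config`).
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dims <- plate_dims(config$plate_format)
  nr <- dims[["rows"]]; nc <- dims[["cols"]]
  set.seed(derive_seed(config$seed, config$screen_id))

  n <- config$n_compounds
  n_hs <- round(config$frac_high_selective * n)
  n_ls <- round(config$frac_low_selective * n)
  n_na <- round(config$frac_nonselective_active * n)
  classes <- rep("INACTIVE", n)
  lab <- sample.int(n)    # random assignment, deterministic counts
  classes[lab[seq_len(n_hs)]] <- "HIGH_SELECTIVE"
  if (n_ls > 0) classes[lab[n_hs + seq_len(n_ls)]] <- "LOW_SELECTIVE"
  if (n_na > 0) classes[lab[n_hs + n_ls + seq_len(n_na)]] <- "NONSELECTIVE_ACTIVE"
  compound_ids <- sprintf("CID%04d", seq_len(n))

  conc <- config$concentrations
  c_mid <- conc[ceiling(length(conc) / 2)]
  hill <- stats::runif(n, 1, 2)
  # sensitive-condition IC50: log-uniform below the dose giving >= 75%
  # inhibition at the mid concentration
  upper <- c_mid / 3^(1 / hill)
  lower <- pmin(min(conc), upper / 2)
  ic50_sens <- exp(stats::runif(n, log(lower), log(upper)))
  shift <- config$selectivity_shift
  ic50_high <- rep(Inf, n); ic50_low <- rep(Inf, n)
  act <- classes != "INACTIVE"
  ic50_high[act] <- ic50_sens[act]; ic50_low[act] <- ic50_sens[act]
  hs <- classes == "HIGH_SELECTIVE"; ls <- classes == "LOW_SELECTIVE"
  ic50_low[hs] <- ic50_sens[hs] * shift
  ic50_high[ls] <- ic50_sens[ls] * shift

  # plate layout: control wells in first/last columns, compound x dose wells
  # filling the remaining positions row-major; identical in both conditions
  ctrl_pos <- rbind(
    data.frame(row = seq_len(nr) - 1L, col = 0L),
    data.frame(row = seq_len(nr) - 1L, col = nc - 1L)
  )[seq_len(config$control_wells_per_plate), , drop = FALSE]
  all_pos <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)
  all_pos <- all_pos[, c("row", "col")]
  is_ctrl_pos <- paste(all_pos$row, all_pos$col) %in%
    paste(ctrl_pos$row, ctrl_pos$col)
  cmpd_pos <- all_pos[!is_ctrl_pos, , drop = FALSE]
  capacity <- nrow(cmpd_pos)
  jobs <- expand.grid(conc_i = seq_along(conc), cmpd_i = seq_len(n))
  jobs <- jobs[, c("cmpd_i", "conc_i")]
  n_plates <- ceiling(nrow(jobs) / capacity)
  if (!is.null(config$n_plates)) {
    if (config$n_plates < n_plates)
      stop_schema("capacity error: %d compound wells need %d plates, config allows %d",
                  nrow(jobs), n_plates, config$n_plates)
    n_plates <- config$n_plates
  }
  plate_ids <- sprintf("P%02d", seq_len(n_plates))
  jobs$plate_i <- rep(seq_len(n_plates), each = capacity)[seq_len(nrow(jobs))]
  # spread the wells of a partially filled plate uniformly over the plate
  # so the spatial fit never faces a large empty region
  pos_i <- unlist(lapply(seq_len(n_plates), function(p) {
    k <- sum(jobs$plate_i == p)
    floor((seq_len(k) - 1) * capacity / k) + 1L
  }))
  jobs$row <- cmpd_pos$row[pos_i]
  jobs$col <- cmpd_pos$col[pos_i]

  surfaces <- list()
  wells <- vector("list", 2L * n_plates)
  wi <- 0L
  for (cond in c("HIGH", "LOW")) {
    ic50 <- if (cond == "HIGH") ic50_high else ic50_low
    for (p in seq_len(n_plates)) {
      s <- make_surface(nr, nc, config$spatial_amplitude)
      surfaces[[paste(cond, plate_ids[p], sep = ":")]] <- s
      pj <- jobs[jobs$plate_i == p, , drop = FALSE]
      pdf <- data.frame(
        screen_id = config$screen_id, plate_id = plate_ids[p],
        row = c(pj$row, ctrl_pos$row), col = c(pj$col, ctrl_pos$col),
        compound_id = c(compound_ids[pj$cmpd_i],
                        rep(CONTROL_TOKEN, nrow(ctrl_pos))),
        concentration = c(conc[pj$conc_i], rep(0, nrow(ctrl_pos))),
        condition = cond, stringsAsFactors = FALSE)
      v <- c(logistic_viability(conc[pj$conc_i], ic50[pj$cmpd_i],
                                hill[pj$cmpd_i]),
             rep(1, nrow(ctrl_pos)))
      v[!is.finite(v)] <- 1     # Inf IC50 (inactive) -> full viability
      sfit <- s[cbind(pdf$row + 1L, pdf$col + 1L)]
      eps <- if (config$noise_sigma > 0)
        exp(stats::rnorm(nrow(pdf), 0, config$noise_sigma)) else 1
      pdf$raw_signal <- config$plate_scale * sfit * v * eps
      pdf$true_viability <- v
      wi <- wi + 1L
      wells[[wi]] <- pdf
    }
  }
  wells <- do.call(rbind, wells)
  rownames(wells) <- NULL

  genes <- sprintf("G%04d", seq_len(config$n_genes))
  planted <- genes[seq_len(min(config$n_planted_genes, config$n_genes))]
  truth <- list(
    compounds = data.frame(compound_id = compound_ids, class = classes,
                           ic50_high = ic50_high, ic50_low = ic50_low,
                           hill = hill, stringsAsFactors = FALSE),
    genes = data.frame(gene = genes, planted_selective = genes %in% planted,
                       stringsAsFactors = FALSE),
    surfaces = surfaces,
    config = config)
  validate_wells(wells[, setdiff(names(wells), "true_viability")],
                 config$plate_format)
  list(wells = wells, truth = truth)
}

# One clean affinity-style record per (compound, gene) pair.
clean_affinity_record <- function(compound_id, gene) {
  k <- length(gene)
  data.frame(compound_id = compound_id, gene = gene,
             organism = "Homo sapiens",
             measure_type = sample(c("IC50", "KI"), k, replace = TRUE),
             measure_value = signif(exp(stats::runif(k, log(1), log(900))), 4),
             measure_unit = "nM",
             confidence = sample(4:9, k, replace = TRUE),
             reference = sprintf("PMID:%07d", sample.int(9999999L, k, replace = TRUE)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic drug-target evidence table
#'
#' Emulates merged ChEMBL/STITCH-style exports. Per compound the number of
#' annotated targets follows a shifted geometric distribution with mean
#' `promiscuity_mean`; HIGH-selective compounds additionally target planted
#' selective genes (three each, assigned round-robin so every planted gene
#' is covered), while all other compounds draw from the background gene
#' pool. A `corruption_frac` fraction of records receives one random defect
#' so the evidence filters have something to reject.
#'
#' @param truth ground-truth manifest from [generate_screen()].
#' @param config the same [simulation_config()].
#' @return list with data.frames `affinity` (ChEMBL-like schema) and
#'   `interaction` (STITCH-like schema).
#' @export
generate_target_table <- function(truth, config) {
  set.seed(derive_seed(config$seed, paste0(config$screen_id, ":targets")))
  comp <- truth$compounds
  genes <- truth$genes$gene
  planted <- genes[truth$genes$planted_selective]
  background <- setdiff(genes, planted)
  p <- 1 / max(config$promiscuity_mean, 1)

  aff <- list(); inter <- list()
  hs_idx <- 0L
  for (i in seq_len(nrow(comp))) {
    cid <- comp$compound_id[i]
    n_t <- 1L + stats::rgeom(1, p)
    tg <- character(0)
    if (comp$class[i] == "HIGH_SELECTIVE" && length(planted) > 0) {
      k <- min(3L, length(planted))
      sel <- ((hs_idx * k + seq_len(k) - 1L) %% length(planted)) + 1L
      hs_idx <- hs_idx + 1L
      tg <- planted[sel]
    }
    n_bg <- max(n_t - length(tg), 0L)
    tg <- c(tg, sample(background, min(n_bg, length(background))))
    if (length(tg) == 0L) next
    src <- stats::runif(length(tg)) < 0.7     # 70% affinity, 30% interaction
    if (any(src)) aff[[length(aff) + 1L]] <- clean_affinity_record(cid, tg[src])
    if (any(!src)) {
      k <- sum(!src)
      inter[[length(inter) + 1L]] <- data.frame(
        compound_id = cid, gene = tg[!src],
        channel = sample(c("experimental", "databases"), k, replace = TRUE),
        score = round(stats::runif(k, 0.8, 1), 3), stringsAsFactors = FALSE)
    }
  }
  aff <- do.call(rbind, aff); inter <- do.call(rbind, inter)

  # corruption: one defect per selected record
  if (config$corruption_frac > 0 && !is.null(aff) && nrow(aff) > 0) {
    bad <- which(stats::runif(nrow(aff)) < config$corruption_frac)
    defect <- sample(c("no_ref", "no_unit", "organism", "low_conf", "weak"),
                     length(bad), replace = TRUE)
    aff$reference[bad[defect == "no_ref"]] <- ""
    aff$measure_unit[bad[defect == "no_unit"]] <- ""
    aff$organism[bad[defect == "organism"]] <- "Rattus norvegicus"
    aff$confidence[bad[defect == "low_conf"]] <-
      sample(0:3, sum(defect == "low_conf"), replace = TRUE)
    aff$measure_value[bad[defect == "weak"]] <-
      signif(exp(stats::runif(sum(defect == "weak"), log(1000), log(50000))), 4)
  }
  if (config$corruption_frac > 0 && !is.null(inter) && nrow(inter) > 0) {
    bad <- which(stats::runif(nrow(inter)) < config$corruption_frac)
    defect <- sample(c("channel", "low_score"), length(bad), replace = TRUE)
    inter$channel[bad[defect == "channel"]] <- "textmining"
    inter$score[bad[defect == "low_score"]] <-
      round(stats::runif(sum(defect == "low_score"), 0.15, 0.79), 3)
  }
  if (config$corruption_frac >= 1) {
    # total corruption: also break records whose defect draw left them valid
    if (!is.null(aff)) aff$reference <- ""
    if (!is.null(inter)) inter$channel <- "textmining"
  }
  list(affinity = aff %||% clean_affinity_record(character(0), character(0)),
       interaction = inter %||% data.frame(compound_id = character(),
                                           gene = character(),
                                           channel = character(),
                                           score = numeric()))
}

#' Generate matched expression and direct-binding (ChIP-like) tables
#'
#' Planted selective genes receive |log2fc| >= 1 at fdr <= 0.01 (the
#' regulation-filter thresholds) and enter the direct-target set with
#' probability 0.8; background genes get centred Gaussian log2fc and
#' uniform fdr, so they pass the filter only at the expected false-positive
#' rate.
#'
#' @param truth ground-truth manifest from [generate_screen()].
#' @param config the same [simulation_config()].
#' @return list with `expression` (data.frame gene/log2fc/fdr) and `chip`
#'   (character vector of direct-target genes).
#' @export
generate_expression_and_chip <- function(truth, config) {
  set.seed(derive_seed(config$seed, paste0(config$screen_id, ":expr")))
  genes <- truth$genes$gene
  planted <- truth$genes$planted_selective
  n <- length(genes)
  log2fc <- stats::rnorm(n, 0, 0.3)
  fdr <- stats::runif(n)
  k <- sum(planted)
  if (k > 0) {
    log2fc[planted] <- sample(c(-1, 1), k, replace = TRUE) *
      (1 + stats::rexp(k, 1))
    fdr[planted] <- stats::runif(k, 0, 0.01)
  }
  chip <- c(genes[planted][stats::runif(k) < 0.8],
            sample(genes[!planted], max(1L, round(0.02 * sum(!planted))))
  )
  list(expression = data.frame(gene = genes, log2fc = round(log2fc, 4),
                               fdr = signif(fdr, 4), stringsAsFactors = FALSE),
       chip = sort(unique(chip)))
}

#' Generate a synthetic protein-protein interaction table
#'
#' Random background edges over the gene universe plus guaranteed
#' high-confidence experimental edges among the planted genes, so a built
#' network has PPI structure to show.
#'
#' @param truth ground-truth manifest from [generate_screen()].
#' @param config the same [simulation_config()].
#' @param n_edges number of random background edges.
#' @return data.frame with columns `gene_a, gene_b, channel, score`.
#' @export
generate_ppi_table <- function(truth, config, n_edges = 400) {
  set.seed(derive_seed(config$seed, paste0(config$screen_id, ":ppi")))
  genes <- truth$genes$gene
  a <- sample(genes, n_edges, replace = TRUE)
  b <- sample(genes, n_edges, replace = TRUE)
  keep <- a != b
  df <- data.frame(gene_a = pmin(a[keep], b[keep]),
                   gene_b = pmax(a[keep], b[keep]),
                   channel = sample(c("experimental", "databases", "textmining"),
                                    sum(keep), replace = TRUE),
                   score = round(stats::runif(sum(keep), 0.1, 1), 3),
                   stringsAsFactors = FALSE)
  planted <- genes[truth$genes$planted_selective]
  if (length(planted) >= 2) {
    pa <- planted[-length(planted)]; pb <- planted[-1]
    df <- rbind(df, data.frame(gene_a = pmin(pa, pb), gene_b = pmax(pa, pb),
                               channel = "experimental",
                               score = round(stats::runif(length(pa), 0.85, 0.99), 3),
                               stringsAsFactors = FALSE))
  }
  df <- df[!duplicated(paste(df$gene_a, df$gene_b, df$channel)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write all synthetic pipeline inputs to a directory
#'
#' Convenience wrapper producing the full input set for [run_pipeline()]:
#' per-condition well tables, affinity and interaction drug-target tables,
#' expression, ChIP gene list, PPI table, and the ground-truth manifest
#' (`ground_truth_compounds.tsv`, `ground_truth_genes.tsv`).
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the ground-truth manifest.
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- generate_screen(config)
  wells <- sc$wells[, setdiff(names(sc$wells), "true_viability")]
  write_well_table(wells[wells$condition == "HIGH", ],
                   file.path(dir, "wells_high.tsv"), config$plate_format)
  write_well_table(wells[wells$condition == "LOW", ],
                   file.path(dir, "wells_low.tsv"), config$plate_format)
  tt <- generate_target_table(sc$truth, config)
  write_delim_table(tt$affinity, file.path(dir, "targets_affinity.tsv"))
  write_delim_table(tt$interaction, file.path(dir, "targets_interaction.tsv"))
  ec <- generate_expression_and_chip(sc$truth, config)
  write_delim_table(ec$expression, file.path(dir, "expression.tsv"))
  writeLines(ec$chip, file.path(dir, "chip_genes.txt"))
  write_delim_table(generate_ppi_table(sc$truth, config),
                    file.path(dir, "ppi.tsv"))
  write_delim_table(sc$truth$compounds, file.path(dir, "ground_truth_compounds.tsv"))
  write_delim_table(sc$truth$genes, file.path(dir, "ground_truth_genes.tsv"))
  invisible(sc$truth)
}
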