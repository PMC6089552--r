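# hit_calling: screen-level hit calling by the median - k*MAD rule on
# normalized log2 viability, and classification of compounds into
# condition-selective groups by the two-fold viability criterion.

#' Unscaled median absolute deviation
#'
#' `median(|x - median(x)|)` without the 1.4826 Gaussian consistency factor:
#' the hit threshold is stated in raw MAD units. The scaled variant is
#' available through `scaled = TRUE`.
#'
#' @param x numeric vector, at least one value.
#' @param scaled multiply by the 1.4826 consistency factor?
#' @return nonnegative scalar.
#' @export
#' @examples
#' mad_unscaled(c(1, 2, 3, 4, 100)) # 1
mad_unscaled <- function(x, scaled = FALSE) {
  if (length(x) == 0L) stop_schema("mad of an empty vector")
  stats::mad(x, constant = if (scaled) 1.4826 else 1)
}

#' Call screen hits by the median - k*MAD rule
#'
#' For each screen and the given condition, the location and dispersion of
#' `log2_viability` are computed over all compound wells (controls excluded
#' by default), and a (compound, concentration) pair is a hit when its
#' summarized (median-over-replicates) log2 viability falls at or below
#' `median - k * MAD`. A compound is a hit when it is a hit at one or more
#' concentrations.
#'
#' @param norm_wells normalized wells from [normalize_screen()].
#' @param condition `"HIGH"` or `"LOW"`.
#' @param k MAD multiplier (default 3).
#' @param scaled_mad use the 1.4826-scaled MAD instead of the raw MAD.
#' @param include_controls include control wells in the median/MAD
#'   statistics (off by default: the screen statistics are taken over
#'   screened compound wells).
#' @return data.frame with one row per (screen_id, compound_id,
#'   concentration): `log2_viability`, `hit`, plus attributes `threshold`
#'   (named per screen) and `condition`.
#' @export
call_hits <- function(norm_wells, condition, k = 3, scaled_mad = FALSE,
                      include_controls = FALSE) {
  w <- norm_wells[norm_wells$condition == condition, , drop = FALSE]
  if (nrow(w) == 0L) stop_schema("no wells in condition %s", condition)
  stat_w <- if (include_controls) w else w[!is_control(w$compound_id), , drop = FALSE]
  smry <- summarize_viability(w)
  thresholds <- c()
  out <- list()
  for (sid in unique(w$screen_id)) {
    sw <- stat_w[stat_w$screen_id == sid, , drop = FALSE]
    if (sum(!is_control(sw$compound_id)) < 10L)
      stop_schema("screen %s: fewer than 10 compound wells", sid)
    med <- stats::median(sw$log2_viability)
    disp <- mad_unscaled(sw$log2_viability, scaled = scaled_mad)
    if (disp == 0)
      stop_schema("screen %s/%s: zero MAD of log2 viability (degenerate dispersion)",
                  sid, condition)
    thr <- med - k * disp
    thresholds[sid] <- thr
    ss <- smry[smry$screen_id == sid, , drop = FALSE]
    ss$hit <- ss$log2_viability <= thr
    out[[sid]] <- ss
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- thresholds
  attr(res, "condition") <- condition
  res
}

#' Compound-level hit set from per-concentration calls
#'
#' @param hit_table output of [call_hits()].
#' @return character vector of compounds hit at >= 1 concentration.
#' @export
hit_compounds <- function(hit_table) {
  sort(unique(hit_table$compound_id[hit_table$hit]))
}

# Merge per-(compound, concentration, condition) summaries across screens /
# library entries: the minimum viability (most sensitive evidence) wins.
merge_across_screens <- function(smry) {
  key <- paste(smry$compound_id, smry$condition, smry$concentration, sep = "\r")
  o <- order(key, smry$viability)
  m <- smry[o, , drop = FALSE]
  m <- m[!duplicated(key[o]), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Classify compounds into condition-selective groups
#'
#' A compound is `HIGH_SELECTIVE` when it is a hit in the HIGH-condition
#' screen and at some concentration tested in both conditions its viability
#' in LOW is at least `fold` times its viability in HIGH (i.e. at least a
#' two-fold stronger viability decrease in HIGH, on the linear scale);
#' `LOW_SELECTIVE` is symmetric. Compounds hit in at least one condition
#' but meeting neither ratio criterion are `NONSELECTIVE_ACTIVE`; the rest
#' are `INACTIVE`. Compounds appearing in several screens are merged by
#' compound id first, keeping the minimum viability per concentration.
#'
#' In the rare event that a compound satisfies both selectivity criteria it
#' is assigned to the side with the larger best fold ratio.
#'
#' @param hits_high,hits_low outputs of [call_hits()] for the two
#'   conditions.
#' @param smry summarized viabilities from [summarize_viability()] (both
#'   conditions).
#' @param fold linear fold-change threshold (default 2).
#' @param fold_only ignore hit status and classify on the fold criterion
#'   alone.
#' @return data.frame with one row per compound: `compound_id, hit_high,
#'   hit_low, group, best_fold_ratio, supporting_concentration`.
#' @export
classify_differential <- function(hits_high, hits_low, smry, fold = 2,
                                  fold_only = FALSE) {
  m <- merge_across_screens(smry)
  hi <- hit_compounds(hits_high)
  lo <- hit_compounds(hits_low)
  compounds <- sort(unique(m$compound_id))
  res <- lapply(compounds, function(cid) {
    mh <- m[m$compound_id == cid & m$condition == "HIGH", , drop = FALSE]
    ml <- m[m$compound_id == cid & m$condition == "LOW", , drop = FALSE]
    shared <- intersect(mh$concentration, ml$concentration)
    if (length(shared) == 0L)
      stop_schema("compound %s has no concentration shared between conditions", cid)
    vh <- mh$viability[match(shared, mh$concentration)]
    vl <- ml$viability[match(shared, ml$concentration)]
    r_high <- vl / vh     # large when the compound kills HIGH cells harder
    r_low <- vh / vl
    i_h <- which.max(r_high); i_l <- which.max(r_low)
    hit_h <- cid %in% hi; hit_l <- cid %in% lo
    qual_h <- (fold_only || hit_h) && r_high[i_h] >= fold
    qual_l <- (fold_only || hit_l) && r_low[i_l] >= fold
    if (qual_h && qual_l) {
      if (r_high[i_h] >= r_low[i_l]) qual_l <- FALSE else qual_h <- FALSE
    }
    if (qual_h) {
      grp <- "HIGH_SELECTIVE"; best <- r_high[i_h]; conc <- shared[i_h]
    } else if (qual_l) {
      grp <- "LOW_SELECTIVE"; best <- r_low[i_l]; conc <- shared[i_l]
    } else if (hit_h || hit_l) {
      grp <- "NONSELECTIVE_ACTIVE"
      best <- max(r_high[i_h], r_low[i_l])
      conc <- if (r_high[i_h] >= r_low[i_l]) shared[i_h] else shared[i_l]
    } else {
      grp <- "INACTIVE"
      best <- max(r_high[i_h], r_low[i_l])
      conc <- if (r_high[i_h] >= r_low[i_l]) shared[i_h] else shared[i_l]
    }
    data.frame(compound_id = cid, hit_high = hit_h, hit_low = hit_l,
               group = grp, best_fold_ratio = best,
               supporting_concentration = conc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
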