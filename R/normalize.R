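# plate_normalization: LOESS-log normalization. A robust locally weighted
# quadratic surface is fitted to log2 signal over (row, col) per plate;
# signals are divided by the surface (rescaled so the correction is
# mean-neutral on the log scale), scaled by the plate's negative-control
# median, and log2-transformed.

#' Fit a robust LOESS spatial surface to one plate
#'
#' Locally weighted quadratic regression of `log2(raw_signal)` on
#' (row, col) with tricube neighbourhood weights over the nearest
#' `ceiling(span * n)` wells, followed by `robust_iters` reweighting passes
#' with bisquare weights on the residuals (Cleveland's robust LOESS, as in
#' [stats::loess()] with `family = "symmetric"`). Outlying wells -- strong
#' actives, liquid-handling spikes -- are therefore down-weighted before
#' the spatial trend is estimated.
#'
#' @param plate_wells data.frame of well measurements from a single plate
#'   and condition; at least 20 wells, all signals positive.
#' @param span LOESS span in (0, 1].
#' @param robust_iters number of bisquare reweighting passes (0 = plain
#'   least-squares LOESS).
#' @return numeric vector of fitted surface values (signal units, strictly
#'   positive), aligned with the rows of `plate_wells`.
#' @export
fit_plate_surface <- function(plate_wells, span = 0.5, robust_iters = 6) {
  if (nrow(plate_wells) < 20L)
    stop_schema("plate has %d wells; at least 20 required for surface fitting",
                nrow(plate_wells))
  if (any(plate_wells$raw_signal <= 0))
    stop_schema("surface fitting requires strictly positive signals")
  if (span <= 0 || span > 1) stop_schema("span must lie in (0, 1]")
  df <- data.frame(l2 = log2(plate_wells$raw_signal),
                   row = plate_wells$row, col = plate_wells$col)
  fam <- if (robust_iters > 0) "symmetric" else "gaussian"
  fit <- stats::loess(l2 ~ row + col, data = df, span = span, degree = 2,
                      normalize = FALSE, family = fam,
                      control = stats::loess.control(
                        surface = "direct",
                        iterations = as.integer(robust_iters) + 1L))
  2^stats::fitted(fit)
}

#' LOESS-log normalize one plate
#'
#' Applies the spatial correction from [fit_plate_surface()], then scales by
#' the plate's negative-control (DMSO) median and log2-transforms:
#' \deqn{corrected = raw \cdot GM(surface) / surface}
#' \deqn{viability = corrected / median(corrected_{controls})}
#' where GM is the geometric mean over the plate, which makes the
#' correction mean-neutral (the plate's geometric-mean signal is exactly
#' preserved). Wells driven to zero viability are floored at the smallest
#' positive double and flagged, keeping downstream medians finite.
#'
#' @param plate_wells wells of one plate and condition.
#' @param span,robust_iters passed to [fit_plate_surface()].
#' @return the input data.frame with added columns `surface_fit`,
#'   `corrected_signal`, `viability`, `log2_viability`, `floored`.
#' @export
normalize_plate <- function(plate_wells, span = 0.5, robust_iters = 6) {
  ctrl <- is_control(plate_wells$compound_id)
  if (!any(ctrl))
    stop_schema("plate %s has no control (%s) wells",
                plate_wells$plate_id[1], CONTROL_TOKEN)
  if (stats::median(plate_wells$raw_signal[ctrl]) <= 0)
    stop_schema("plate %s: degenerate control median (zero/negative control signal)",
                plate_wells$plate_id[1])
  sfit <- fit_plate_surface(plate_wells, span, robust_iters)
  corrected <- plate_wells$raw_signal * geomean(sfit) / sfit
  ctrl_med <- stats::median(corrected[ctrl])
  if (!is.finite(ctrl_med) || ctrl_med <= 0)
    stop_schema("plate %s: degenerate control median (%s)",
                plate_wells$plate_id[1], format(ctrl_med))
  viability <- corrected / ctrl_med
  floored <- viability <= 0
  viability[floored] <- .Machine$double.xmin
  out <- plate_wells
  out$surface_fit <- sfit
  out$corrected_signal <- corrected
  out$viability <- viability
  out$log2_viability <- log2(viability)
  out$floored <- floored
  out
}

#' LOESS-log normalize a whole screen
#'
#' Splits the well collection by (screen, condition, plate) and applies
#' [normalize_plate()] to each plate independently -- the correction and
#' the control median are strictly per plate.
#'
#' @param wells well measurements for one or more plates/conditions.
#' @param span,robust_iters passed to [fit_plate_surface()].
#' @return data.frame of normalized wells.
#' @export
normalize_screen <- function(wells, span = 0.5, robust_iters = 6) {
  key <- paste(wells$screen_id, wells$condition, wells$plate_id, sep = "\r")
  parts <- lapply(split(seq_len(nrow(wells)), key), function(i) {
    normalize_plate(wells[i, , drop = FALSE], span, robust_iters)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Summarize normalized viability per compound, concentration and condition
#'
#' Median viability across replicate wells, with the replicate count
#' carried along. Control wells are excluded. When the same compound and
#' concentration appear in several screens (a compound present in more than
#' one library), entries are kept per screen here and merged later by
#' [classify_differential()].
#'
#' @param norm_wells normalized wells from [normalize_screen()].
#' @return data.frame with columns `screen_id, compound_id, condition,
#'   concentration, viability, log2_viability, n_wells`.
#' @export
summarize_viability <- function(norm_wells) {
  cw <- norm_wells[!is_control(norm_wells$compound_id), , drop = FALSE]
  key <- interaction(cw$screen_id, cw$compound_id, cw$condition,
                     cw$concentration, drop = TRUE, sep = "\r")
  med <- tapply(cw$viability, key, stats::median)
  n <- tapply(cw$viability, key, length)
  parts <- strsplit(names(med), "\r", fixed = TRUE)
  out <- data.frame(screen_id = vapply(parts, `[`, "", 1),
                    compound_id = vapply(parts, `[`, "", 2),
                    condition = vapply(parts, `[`, "", 3),
                    concentration = as.numeric(vapply(parts, `[`, "", 4)),
                    viability = as.numeric(med),
                    n_wells = as.integer(n),
                    stringsAsFactors = FALSE)
  out$log2_viability <- log2(out$viability)
  out <- out[order(out$screen_id, out$compound_id, out$condition,
                   -out$concentration), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarized viability of one compound in one condition
#'
#' @param norm_wells normalized wells from [normalize_screen()].
#' @param compound compound identifier.
#' @param condition `"HIGH"` or `"LOW"`.
#' @return data.frame of per-concentration median viability.
#' @export
summarize_compound <- function(norm_wells, compound, condition) {
  s <- summarize_viability(norm_wells)
  s <- s[s$compound_id == compound & s$condition == condition, , drop = FALSE]
  if (nrow(s) == 0L)
    stop_schema("compound %s not measured in condition %s", compound, condition)
  rownames(s) <- NULL
  s
}
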