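# dose_response: four-parameter logistic (4PL) curve fitting for IC50
# estimation from dilution-series viability data.
#
# Model: v(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill),
# fitted by bounded Levenberg-Marquardt least squares on log concentration
# (log parameterization of ic50 for conditioning).

#' Fit a four-parameter logistic dose-response curve
#'
#' Initialization: `top = max(v)`, `bottom = min(v)`, `ic50` at the tested
#' concentration nearest the half-range crossing, `hill = 1`. The IC50 is
#' constrained to `[min(conc)/100, max(conc)*100]`; flat or non-crossing
#' data converge to a bound with `converged = FALSE`.
#'
#' @param conc micromolar concentrations (>= 4 distinct positive values).
#' @param viability viability fractions (same length as `conc`).
#' @param fix_bottom,fix_top optionally pin the lower/upper asymptote
#'   (e.g. `fix_bottom = 0`, `fix_top = 1`).
#' @return object of class `dose_response_fit`: list with `bottom`, `top`,
#'   `hill`, `ic50` (uM), `rss`, `converged`, `fitted`.
#' @export
#' @examples
#' conc <- c(20, 6.7, 2.2, 0.74, 0.25, 0.082, 0.027, 0.009)
#' v <- 1 / (1 + conc / 1)      # ic50 = 1 uM, hill = 1
#' fit_4pl(conc, v)$ic50
fit_4pl <- function(conc, viability, fix_bottom = NULL, fix_top = NULL) {
  if (length(conc) != length(viability))
    stop_schema("conc and viability must have equal length")
  ok <- is.finite(conc) & is.finite(viability) & conc > 0
  conc <- conc[ok]; viability <- viability[ok]
  if (length(unique(conc)) < 4L)
    stop_schema("at least 4 distinct positive concentrations required")
  lc <- log(conc)
  lo_ic <- log(min(conc) / 100); hi_ic <- log(max(conc) * 100)

  top0 <- if (is.null(fix_top)) max(viability) else fix_top
  bot0 <- if (is.null(fix_bottom)) min(viability) else fix_bottom
  half <- (top0 + bot0) / 2
  i0 <- which.min(abs(viability - half))
  start <- list(lic50 = min(max(lc[i0], lo_ic), hi_ic), hill = 1)
  lower <- c(lic50 = lo_ic, hill = 0.1)
  upper <- c(lic50 = hi_ic, hill = 10)
  if (is.null(fix_bottom)) {
    start$bottom <- bot0; lower <- c(lower, bottom = -0.5); upper <- c(upper, bottom = 1.5)
  }
  if (is.null(fix_top)) {
    start$top <- top0; lower <- c(lower, top = -0.5); upper <- c(upper, top = 2)
  }
  model <- function(p) {
    bottom <- if (is.null(fix_bottom)) p[["bottom"]] else fix_bottom
    top <- if (is.null(fix_top)) p[["top"]] else fix_top
    bottom + (top - bottom) / (1 + exp(p[["hill"]] * (lc - p[["lic50"]])))
  }
  # note: 1 + (c/ic50)^h = 1 + exp(h*(log c - log ic50)); viability DECREASES
  # with c, so the logistic above must place high viability at low c:
  # v = bottom + (top-bottom)/(1 + exp(h*(lc - lic50))) does exactly that.
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       lower = lower[names(start)], upper = upper[names(start)],
                       fn = function(p) viability - model(p),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res <- list(bottom = bot0, top = top0, hill = NA_real_, ic50 = NA_real_,
                rss = NA_real_, converged = FALSE,
                fitted = rep(NA_real_, length(conc)))
    class(res) <- "dose_response_fit"
    return(res)
  }
  p <- fit$par
  bottom <- if (is.null(fix_bottom)) p[["bottom"]] else fix_bottom
  top <- if (is.null(fix_top)) p[["top"]] else fix_top
  if (bottom > top) {   # degenerate inversion: swap to honor bottom <= top
    tmp <- bottom; bottom <- top; top <- tmp
  }
  ic50 <- exp(p[["lic50"]])
  at_bound <- p[["lic50"]] <= lo_ic + 1e-8 || p[["lic50"]] >= hi_ic - 1e-8
  flat <- (top - bottom) < 0.05
  res <- list(bottom = bottom, top = top, hill = p[["hill"]], ic50 = ic50,
              rss = sum(fit$fvec^2),
              converged = fit$info %in% 1:4 && !at_bound && !flat,
              fitted = model(p))
  if (at_bound || flat)
    warning("dose-response fit did not identify an interior IC50 (flat or non-crossing data)",
            call. = FALSE)
  class(res) <- "dose_response_fit"
  res
}

#' Predicted viability from a 4PL fit
#'
#' @param object a `dose_response_fit`.
#' @param conc concentrations (uM) at which to predict; defaults to the
#'   fitted values' concentrations being unavailable, so `conc` is
#'   required.
#' @param ... unused.
#' @return numeric vector of predicted viabilities.
#' @export
predict.dose_response_fit <- function(object, conc, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + (conc / object$ic50)^object$hill)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit: ic50 = %.4g uM, hill = %.3g, bottom = %.3g, top = %.3g, rss = %.3g%s\n",
              x$ic50, x$hill, x$bottom, x$top, x$rss,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fit dose-response curves for a table of compounds
#'
#' @param curves data.frame with columns `compound_id, condition,
#'   concentration_um, viability`.
#' @param ... passed to [fit_4pl()].
#' @return data.frame with one row per (compound, condition):
#'   `compound_id, condition, bottom, top, hill, ic50, rss, converged`.
#' @export
fit_dose_response_table <- function(curves, ...) {
  key <- paste(curves$compound_id, curves$condition, sep = "\r")
  rows <- lapply(split(seq_len(nrow(curves)), key), function(i) {
    f <- fit_4pl(curves$concentration_um[i], curves$viability[i], ...)
    data.frame(compound_id = curves$compound_id[i[1]],
               condition = curves$condition[i[1]],
               bottom = f$bottom, top = f$top, hill = f$hill, ic50 = f$ic50,
               rss = f$rss, converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound_id, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
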