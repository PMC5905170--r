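#' Match a sample's peptides to the reference run
#'
#' Pairs retention times of peptides identified in both a sample and the
#' reference run. The matching key is the exact sequence text (including
#' modification tags); sequences occurring more than once in either run are
#' excluded so that every pair is unambiguous. Pairs are returned sorted by
#' the sample's retention time.
#'
#' @param sample,reference peptide-record data frames.
#' @param min_pairs minimum number of matched pairs required (default 10).
#' @return data frame with columns `sequence`, `rt_sample`, `rt_reference`.
#' @export
match_to_reference <- function(sample, reference, min_pairs = 10L) {
  stopifnot(nrow(sample) > 0L, nrow(reference) > 0L)
  uniq <- function(df) {
    tab <- table(df$sequence)
    df[df$sequence %in% names(tab)[tab == 1L], c("sequence", "rt")]
  }
  s <- uniq(sample)
  r <- uniq(reference)
  m <- merge(s, r, by = "sequence", suffixes = c("_sample", "_reference"))
  m <- m[order(m$rt_sample, m$sequence), , drop = FALSE]
  rownames(m) <- NULL
  if (nrow(m) < min_pairs) {
    stop(sprintf(
      "calibration error: only %d matched peptide pair(s) with the reference (minimum %d)",
      nrow(m), min_pairs), call. = FALSE)
  }
  m
}

#' Fit a LOWESS retention-time calibration
#'
#' Fits a robust LOWESS regression of the reference run's retention times on
#' the sample's, then makes the fitted curve non-decreasing by isotonic
#' post-adjustment. Inside the observed range the model interpolates the
#' fitted curve linearly; outside it extrapolates by a constant offset from
#' the nearest endpoint, keeping the mapping total and monotone.
#'
#' @param pairs matched pairs from [match_to_reference()].
#' @param fraction LOWESS smoother span in (0, 1] (default 0.3).
#' @param iterations robustifying reweighting iterations (default 3).
#' @param sample_id optional label stored in the model.
#' @param min_pairs minimum pair count.
#' @return an object of class `rt_calibration` with the fitted knots, the
#'   pair count, the span used and the median absolute residual (minutes).
#' @export
fit_lowess <- function(pairs, fraction = 0.3, iterations = 3L,
                       sample_id = NULL, min_pairs = 10L) {
  stopifnot(fraction > 0, fraction <= 1, iterations >= 0L)
  if (nrow(pairs) < min_pairs) {
    stop("calibration error: fewer than ", min_pairs, " pairs", call. = FALSE)
  }
  x <- pairs$rt_sample
  y <- pairs$rt_reference
  if (any(x <= 0) || any(y <= 0)) {
    stop("retention times must be positive", call. = FALSE)
  }
  if (diff(range(x)) <= 0) {
    stop("calibration error: degenerate pairs (all identical rt_sample)",
         call. = FALSE)
  }
  # the bisquare reweighting of the robustifying iterations is undefined
  # when the initial fit is (near-)interpolating: residual MAD of ~0 sends
  # every weight to zero and the smoother collapses. Fall back to the plain
  # fit in that case.
  fit0 <- stats::lowess(x, y, f = fraction, iter = 0)
  resid0 <- y[order(x)] - fit0$y
  if (iterations > 0L && stats::mad(resid0) > 1e-8 * max(diff(range(y)), 1)) {
    fit <- stats::lowess(x, y, f = fraction, iter = iterations)
  } else {
    fit <- fit0
  }
  # collapse duplicate x knots, then enforce monotonicity
  ux <- unique(fit$x)
  uy <- vapply(split(fit$y, factor(match(fit$x, ux), levels = seq_along(ux))),
               mean, numeric(1))
  uy <- stats::isoreg(seq_along(ux), uy)$yf
  resid <- stats::approx(ux, uy, xout = x, rule = 2)$y - y
  model <- list(
    sample_id = sample_id,
    knots_x = ux,
    knots_y = uy,
    n_pairs = nrow(pairs),
    fraction = fraction,
    iterations = iterations,
    median_abs_residual = stats::median(abs(resid)),
    identity = FALSE
  )
  class(model) <- "rt_calibration"
  model
}

#' Identity calibration model
#'
#' Used for the reference sample, which maps onto itself.
#'
#' @param sample_id optional label.
#' @return an `rt_calibration` object implementing the identity map.
#' @export
identity_calibration <- function(sample_id = NULL) {
  model <- list(sample_id = sample_id, knots_x = NULL, knots_y = NULL,
                n_pairs = NA_integer_, fraction = NA_real_,
                iterations = NA_integer_, median_abs_residual = 0,
                identity = TRUE)
  class(model) <- "rt_calibration"
  model
}

#' Evaluate a retention-time calibration model
#'
#' @param object an `rt_calibration` model.
#' @param rt retention times (minutes) on the sample's scale.
#' @param ... unused.
#' @return retention times mapped onto the reference scale.
#' @export
predict.rt_calibration <- function(object, rt, ...) {
  if (object$identity) return(rt)
  x <- object$knots_x
  y <- object$knots_y
  out <- stats::approx(x, y, xout = rt, rule = 1)$y
  lo <- rt < x[1L]
  hi <- rt > x[length(x)]
  # constant-offset extrapolation from the nearest endpoint
  out[lo] <- rt[lo] + (y[1L] - x[1L])
  out[hi] <- rt[hi] + (y[length(y)] - x[length(x)])
  out
}

#' @export
print.rt_calibration <- function(x, ...) {
  if (x$identity) {
    cat("rt calibration: identity (reference sample",
        if (!is.null(x$sample_id)) paste0("'", x$sample_id, "'") else "",
        ")\n")
  } else {
    cat(sprintf(
      "rt calibration%s: %d pairs, span %.2f, median |residual| %.3f min\n",
      if (!is.null(x$sample_id)) paste0(" '", x$sample_id, "'") else "",
      x$n_pairs, x$fraction, x$median_abs_residual))
  }
  invisible(x)
}

#' Apply a calibration model to peptide records
#'
#' Replaces every record's retention time by the model's mapping onto the
#' reference scale; all other fields are unchanged.
#'
#' @param records peptide-record data frame.
#' @param model an `rt_calibration` model.
#' @return the records with calibrated `rt`.
#' @export
apply_calibration <- function(records, model) {
  records$rt <- predict(model, records$rt)
  records
}

#' Calibrate every sample of a study to the reference
#'
#' Convenience driver over [match_to_reference()], [fit_lowess()] and
#' [apply_calibration()]: the sample flagged `is_reference` in the design is
#' mapped by identity, all others through their fitted LOWESS model.
#'
#' @param peptides named list of per-sample peptide-record data frames.
#' @param design study design (one `is_reference` sample).
#' @param fraction,iterations,min_pairs passed to [fit_lowess()].
#' @return list with `peptides` (calibrated records, same structure) and
#'   `models` (named list of `rt_calibration` objects).
#' @export
calibrate_study <- function(peptides, design, fraction = 0.3,
                            iterations = 3L, min_pairs = 10L) {
  validate_study_design(design)
  ref_id <- design$sample_id[design$is_reference]
  if (!ref_id %in% names(peptides)) {
    stop("reference sample '", ref_id, "' not present in peptide lists",
         call. = FALSE)
  }
  reference <- peptides[[ref_id]]
  models <- list()
  out <- peptides
  for (sid in names(peptides)) {
    if (sid == ref_id) {
      models[[sid]] <- identity_calibration(sid)
    } else {
      pairs <- match_to_reference(peptides[[sid]], reference,
                                  min_pairs = min_pairs)
      models[[sid]] <- fit_lowess(pairs, fraction = fraction,
                                  iterations = iterations,
                                  sample_id = sid, min_pairs = min_pairs)
    }
    out[[sid]] <- apply_calibration(peptides[[sid]], models[[sid]])
  }
  list(peptides = out, models = models)
}

#' Suggest a reference sample
#'
#' When no sample is flagged as reference, the natural choice is the run
#' whose identifications cover the widest mass and retention-time range with
#' the most peptides. Coverage is scored as the product of the run's mass
#' range, rt range and unique-sequence count, each relative to the study
#' maximum.
#'
#' @param peptides named list of per-sample peptide-record data frames.
#' @return the suggested sample id.
#' @export
suggest_reference <- function(peptides) {
  score <- vapply(peptides, function(df) {
    if (nrow(df) == 0L) return(0)
    diff(range(df$measured_mass)) * diff(range(df$rt)) *
      length(unique(df$sequence))
  }, numeric(1))
  names(score)[which.max(score)]
}
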