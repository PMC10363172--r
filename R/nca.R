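#' NCA options
#'
#' Tunables of the noncompartmental analysis.
#'
#' @param lambda_z_min_points Minimum number of points in a terminal fit
#'   window (>= 3).
#' @param adj_r2_tol Adjusted-R2 tie tolerance for window selection: among
#'   candidate windows whose adjusted R2 is within this tolerance of the best,
#'   the one with more points is preferred.
#' @param clast_mode `"observed"` uses the observed last quantifiable
#'   concentration for extrapolation; `"predicted"` uses the terminal
#'   regression's fitted value at `tlast`.
#' @param extrapolation_warn_pct Flag results whose extrapolated AUC fraction
#'   exceeds this percentage (quality warning, never a failure).
#' @param threshold Therapeutic threshold concentration, ng/mL, or `NA` to
#'   skip threshold computations.
#' @return A list of class `nca_options`.
#' @export
nca_options <- function(lambda_z_min_points = 3L, adj_r2_tol = 1e-4,
                        clast_mode = c("observed", "predicted"),
                        extrapolation_warn_pct = 20, threshold = 0.1) {
  clast_mode <- match.arg(clast_mode)
  stopifnot(lambda_z_min_points >= 3L, adj_r2_tol >= 0,
            extrapolation_warn_pct > 0)
  if (!is.na(threshold) && threshold <= 0) stop("threshold must be > 0 (or NA)")
  structure(list(lambda_z_min_points = as.integer(lambda_z_min_points),
                 adj_r2_tol = adj_r2_tol, clast_mode = clast_mode,
                 extrapolation_warn_pct = extrapolation_warn_pct,
                 threshold = threshold),
            class = "nca_options")
}

#' Assemble one analysis profile
#'
#' @param time_h Sampling times, hours. Re-sorted internally; duplicates are
#'   an error.
#' @param conc_ng_per_ml Concentrations; `NA` allowed only where `blq` is set.
#' @param blq Logical/0-1 below-quantitation flags (default all quantifiable).
#' @param dose Dose in mg/kg.
#' @param subject_id,group_label,formulation,analyte Metadata carried through.
#' @return A list of class `pk_profile`.
#' @export
pk_profile <- function(time_h, conc_ng_per_ml, blq = NULL, dose = NA_real_,
                       subject_id = NA_character_, group_label = NA_character_,
                       formulation = NA_character_, analyte = "parent") {
  stopifnot(length(time_h) == length(conc_ng_per_ml), all(time_h >= 0))
  if (is.null(blq)) blq <- rep(FALSE, length(time_h))
  blq <- as.logical(blq)
  if (anyDuplicated(time_h)) stop("duplicate sampling times in profile")
  ord <- order(time_h)
  time_h <- time_h[ord]; conc <- conc_ng_per_ml[ord]; blq <- blq[ord]
  if (any(!blq & is.na(conc))) stop("missing concentration on a quantifiable row")
  if (any(!is.na(conc) & conc < 0)) stop("negative concentration")
  structure(list(subject_id = subject_id, group_label = group_label,
                 formulation = formulation, analyte = analyte, dose = dose,
                 time_h = time_h, conc_ng_per_ml = conc, blq = blq),
            class = "pk_profile")
}

quantifiable <- function(profile) {
  keep <- !profile$blq & !is.na(profile$conc_ng_per_ml)
  list(time = profile$time_h[keep], conc = profile$conc_ng_per_ml[keep])
}

#' Observed extrema of a profile
#'
#' @param profile A [pk_profile()].
#' @return A list `cmax`, `tmax` (earliest time attaining the maximum),
#'   `tlast` (last quantifiable time), `clast`.
#' @export
observed_extrema <- function(profile) {
  q <- quantifiable(profile)
  if (!length(q$time)) {
    stop(no_quantifiable_error(profile))
  }
  imax <- which.max(q$conc)  # which.max returns the first maximum: earliest tmax
  n <- length(q$time)
  list(cmax = q$conc[imax], tmax = q$time[imax],
       tlast = q$time[n], clast = q$conc[n])
}

no_quantifiable_error <- function(profile) {
  structure(class = c("depotnca_no_quantifiable_data", "error", "condition"),
            list(message = sprintf("no quantifiable data in profile %s/%s",
                                   profile$subject_id, profile$analyte),
                 call = NULL))
}

# AUC/AUMC integration points under the BLQ policy: BLQ values before the
# first quantifiable sample count as zero; embedded or trailing BLQ values
# are dropped; a (0, 0) anchor is prepended for extravascular dosing when
# the series does not already start at t = 0.
auc_points <- function(profile) {
  t <- profile$time_h; c <- profile$conc_ng_per_ml; blq <- profile$blq
  qidx <- which(!blq & !is.na(c))
  if (!length(qidx)) stop(no_quantifiable_error(profile))
  first_q <- qidx[1L]; last_q <- qidx[length(qidx)]
  keep <- logical(length(t))
  keep[seq_len(last_q)] <- TRUE
  keep[setdiff(which(blq), seq_len(first_q - 1L))] <- FALSE  # drop embedded BLQ
  c[blq] <- 0  # leading BLQ -> zero
  t <- t[keep]; c <- c[keep]
  if (t[1L] > 0) { t <- c(0, t); c <- c(0, c) }
  list(time = t, conc = c)
}

#' Cumulative AUC and AUMC to the last quantifiable sample
#'
#' Sums [auc_segment()] / [aumc_segment()] over consecutive integration
#' points (leading-zero anchor and BLQ policy applied).
#'
#' @param profile A [pk_profile()].
#' @return A list `auc_last`, `aumc_last` (ng.h/mL, ng.h^2/mL).
#' @export
auc_last <- function(profile) {
  pts <- auc_points(profile)
  n <- length(pts$time)
  if (n < 2L) return(list(auc_last = 0, aumc_last = 0))
  i <- seq_len(n - 1L)
  list(auc_last = sum(auc_segment(pts$time[i], pts$conc[i],
                                  pts$time[i + 1L], pts$conc[i + 1L])),
       aumc_last = sum(aumc_segment(pts$time[i], pts$conc[i],
                                    pts$time[i + 1L], pts$conc[i + 1L])))
}

#' Terminal elimination rate constant by best-adjusted-R2 window search
#'
#' Candidate windows are the suffixes of the quantifiable points strictly
#' after Tmax (the Cmax point itself is excluded) with at least
#' `lambda_z_min_points` points. Each window gets an ordinary least-squares
#' fit of `log(conc)` on time; the window with the highest adjusted R2 wins,
#' and among windows within `adj_r2_tol` of the best the one with more points
#' is preferred. A window only qualifies if its slope is negative
#' (`lambda_z = -slope > 0`).
#'
#' @param profile A [pk_profile()].
#' @param options An [nca_options()].
#' @return A list of class `lambda_z_fit` with `lambda_z` (1/h), `intercept`
#'   (log ng/mL), `n_points`, `adj_r2`, `t_lower`, `t_upper`; or `NULL` when
#'   no qualifying window exists (insufficient points or no declining phase).
#' @export
fit_lambda_z <- function(profile, options = nca_options()) {
  q <- quantifiable(profile)
  if (!length(q$time)) stop(no_quantifiable_error(profile))
  ext <- observed_extrema(profile)
  sel <- q$time > ext$tmax & q$conc > 0
  x <- q$time[sel]; y <- log(q$conc[sel])
  n <- length(x)
  minp <- options$lambda_z_min_points
  if (n < minp) return(NULL)
  # All suffix regressions at once via reverse cumulative sums.
  rcs <- function(v) rev(cumsum(rev(v)))
  m <- n - seq_len(n) + 1
  sx <- rcs(x); sy <- rcs(y); sxx <- rcs(x^2); sxy <- rcs(x * y); syy <- rcs(y^2)
  vx <- m * sxx - sx^2
  vy <- m * syy - sy^2
  cxy <- m * sxy - sx * sy
  slope <- cxy / vx
  r2 <- ifelse(vy > 0, cxy^2 / (vx * vy), NA_real_)
  adj_r2 <- 1 - (1 - r2) * (m - 1) / (m - 2)
  ok <- m >= minp & is.finite(slope) & slope < 0 & is.finite(adj_r2)
  if (!any(ok)) return(NULL)
  best <- max(adj_r2[ok])
  tied <- which(ok & adj_r2 >= best - options$adj_r2_tol)
  start <- tied[which.max(m[tied])]   # suffixes: larger m == earlier start
  mm <- m[start]
  b1 <- slope[start]
  b0 <- (sy[start] - b1 * sx[start]) / mm
  structure(list(lambda_z = -b1, intercept = b0, n_points = as.integer(mm),
                 adj_r2 = adj_r2[start], t_lower = x[start], t_upper = x[n]),
            class = "lambda_z_fit")
}

#' Terminal half-life
#'
#' `t_half = log(2) / lambda_z`.
#'
#' @param fit A `lambda_z_fit` (from [fit_lambda_z()]) or a bare rate (1/h).
#' @return Half-life in hours.
#' @export
half_life <- function(fit) {
  lz <- if (inherits(fit, "lambda_z_fit")) fit$lambda_z else fit
  stopifnot(is.numeric(lz), lz > 0)
  log(2) / lz
}

#' AUC extrapolated to infinity
#'
#' `auc_inf = auc_last + clast / lambda_z`, where `clast` is observed or
#' regression-predicted per `options$clast_mode`.
#'
#' @param auc_last_value AUC to the last quantifiable sample.
#' @param clast Last quantifiable concentration (observed), ng/mL.
#' @param tlast Time of the last quantifiable sample, h.
#' @param fit A `lambda_z_fit`.
#' @param options An [nca_options()].
#' @return List `auc_inf`, `pct_extrapolated`, `clast_used`,
#'   `extrapolation_flag` (TRUE when the extrapolated fraction exceeds
#'   `options$extrapolation_warn_pct`).
#' @export
auc_inf <- function(auc_last_value, clast, tlast, fit, options = nca_options()) {
  stopifnot(inherits(fit, "lambda_z_fit"))
  clast_used <- if (options$clast_mode == "predicted") {
    exp(fit$intercept - fit$lambda_z * tlast)
  } else {
    clast
  }
  total <- auc_last_value + clast_used / fit$lambda_z
  pct <- 100 * (total - auc_last_value) / total
  list(auc_inf = total, pct_extrapolated = pct, clast_used = clast_used,
       extrapolation_flag = pct > options$extrapolation_warn_pct)
}

#' Apparent clearance for extravascular dosing
#'
#' `CL/F = dose (mg/kg -> ug/kg) / AUC0-inf (ng.h/mL == ug.h/L)`, in L/h/kg.
#'
#' @param dose Dose in mg/kg.
#' @param auc_inf_value AUC0-inf in ng.h/mL.
#' @return Clearance in L/h/kg.
#' @export
clearance_over_F <- function(dose, auc_inf_value) {
  stopifnot(dose > 0, auc_inf_value > 0)
  dose * 1e3 / auc_inf_value
}

#' Mean residence times
#'
#' `mrt_last = aumc_last / auc_last`; with a terminal fit,
#' `aumc_inf = aumc_last + clast * tlast / lambda_z + clast / lambda_z^2` and
#' `mrt_inf = aumc_inf / auc_inf`. `mrt_inf` is `NA` when no fit exists.
#'
#' @param auc A list from [auc_last()].
#' @param clast,tlast Observed last quantifiable concentration and its time.
#' @param fit A `lambda_z_fit` or `NULL`.
#' @param auc_inf_value AUC0-inf (required when `fit` is given).
#' @return List `mrt_last`, `mrt_inf`.
#' @export
mean_residence_time <- function(auc, clast, tlast, fit = NULL,
                                auc_inf_value = NULL) {
  mrt_last <- if (auc$auc_last > 0) auc$aumc_last / auc$auc_last else NA_real_
  mrt_inf <- NA_real_
  if (!is.null(fit)) {
    stopifnot(!is.null(auc_inf_value))
    aumc_inf <- auc$aumc_last + clast * tlast / fit$lambda_z +
      clast / fit$lambda_z^2
    mrt_inf <- aumc_inf / auc_inf_value
  }
  list(mrt_last = mrt_last, mrt_inf = mrt_inf)
}

#' Time above a therapeutic threshold
#'
#' Onset is the first sampled time whose concentration is at or above the
#' threshold (never interpolated before the first sample). If the curve is
#' still above threshold at the last quantifiable time and a terminal fit is
#' available, the downward crossing is extrapolated as
#' `tlast + log(clast/threshold) / lambda_z` and flagged `extrapolated`;
#' without a fit the duration is censored at the observation end
#' (`duration = tlast - onset`, `censored = TRUE`). A crossing between
#' samples is located by log-linear interpolation on the declining segment
#' (linear when the lower bound is zero). Transient dips below threshold
#' between onset and the final crossing are not subtracted.
#'
#' @param time_h,conc Quantifiable concentration-time series (e.g. one
#'   subject's quantifiable points, or a group mean curve).
#' @param threshold Threshold concentration, ng/mL, > 0.
#' @param fit Optional `lambda_z_fit` used for extrapolation beyond `tlast`.
#' @return List `onset`, `crossing`, `duration`, `censored`, `extrapolated`.
#'   When the curve never reaches the threshold: `onset = NA`, `duration = 0`.
#' @export
time_above_threshold <- function(time_h, conc, threshold, fit = NULL) {
  stopifnot(length(time_h) == length(conc), all(diff(time_h) > 0))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  above <- conc >= threshold
  if (!any(above)) {
    return(list(onset = NA_real_, crossing = NA_real_, duration = 0,
                censored = FALSE, extrapolated = FALSE))
  }
  onset <- time_h[which(above)[1L]]
  n <- length(time_h)
  last_above <- max(which(above))
  if (last_above == n) {
    tlast <- time_h[n]; clast <- conc[n]
    if (!is.null(fit)) {
      crossing <- tlast + log(clast / threshold) / fit$lambda_z
      return(list(onset = onset, crossing = crossing,
                  duration = crossing - onset,
                  censored = FALSE, extrapolated = TRUE))
    }
    return(list(onset = onset, crossing = NA_real_,
                duration = tlast - onset, censored = TRUE,
                extrapolated = FALSE))
  }
  t1 <- time_h[last_above]; c1 <- conc[last_above]
  t2 <- time_h[last_above + 1L]; c2 <- conc[last_above + 1L]
  crossing <- if (c1 == threshold) {
    t1
  } else if (c2 > 0) {
    t1 + (t2 - t1) * log(c1 / threshold) / log(c1 / c2)
  } else {
    t1 + (t2 - t1) * (c1 - threshold) / (c1 - c2)
  }
  list(onset = onset, crossing = crossing, duration = crossing - onset,
       censored = FALSE, extrapolated = FALSE)
}

#' Run the full noncompartmental analysis on one profile
#'
#' Orchestrates [observed_extrema()], [auc_last()], [fit_lambda_z()],
#' [half_life()], [auc_inf()], [clearance_over_F()], [mean_residence_time()]
#' and [time_above_threshold()]. Parameters that depend on a terminal fit are
#' `NA`, with a `lambda_z_not_estimable` flag, when no qualifying window
#' exists. Input row order does not matter (profiles sort by time).
#'
#' @param profile A [pk_profile()].
#' @param options An [nca_options()].
#' @return An object of class `nca_result`: a list with every parameter of
#'   the standard extravascular set (`cmax`, `tmax`, `tlast`, `clast`,
#'   `lambda_z` and fit diagnostics, `t_half`, `auc_last`, `auc_inf`,
#'   `pct_extrapolated`, `clearance_over_F`, `mrt_last`, `mrt_inf`),
#'   threshold onset/duration, and a character vector `flags`.
#' @export
run_nca <- function(profile, options = nca_options()) {
  stopifnot(inherits(profile, "pk_profile"), inherits(options, "nca_options"))
  ext <- observed_extrema(profile)
  auc <- auc_last(profile)
  fit <- fit_lambda_z(profile, options)
  flags <- character()
  res <- list(
    subject_id = profile$subject_id, group_label = profile$group_label,
    formulation = profile$formulation, analyte = profile$analyte,
    dose_mg_per_kg = profile$dose,
    n_quantifiable = length(quantifiable(profile)$time),
    cmax = ext$cmax, tmax = ext$tmax, tlast = ext$tlast, clast = ext$clast,
    lambda_z = NA_real_, lambda_z_intercept = NA_real_,
    lambda_z_n_points = NA_integer_, lambda_z_adj_r2 = NA_real_,
    lambda_z_t_lower = NA_real_, lambda_z_t_upper = NA_real_,
    t_half = NA_real_,
    auc_last = auc$auc_last, aumc_last = auc$aumc_last,
    auc_inf = NA_real_, pct_extrapolated = NA_real_,
    clearance_over_F = NA_real_,
    mrt_last = NA_real_, mrt_inf = NA_real_,
    threshold = options$threshold,
    threshold_onset = NA_real_, threshold_crossing = NA_real_,
    threshold_duration = NA_real_,
    threshold_censored = FALSE, threshold_extrapolated = FALSE
  )
  if (is.null(fit)) {
    flags <- c(flags, "lambda_z_not_estimable")
  } else {
    res$lambda_z <- fit$lambda_z
    res$lambda_z_intercept <- fit$intercept
    res$lambda_z_n_points <- fit$n_points
    res$lambda_z_adj_r2 <- fit$adj_r2
    res$lambda_z_t_lower <- fit$t_lower
    res$lambda_z_t_upper <- fit$t_upper
    res$t_half <- half_life(fit)
    ainf <- auc_inf(auc$auc_last, ext$clast, ext$tlast, fit, options)
    res$auc_inf <- ainf$auc_inf
    res$pct_extrapolated <- ainf$pct_extrapolated
    if (ainf$extrapolation_flag) flags <- c(flags, "extrapolation_gt_warn_pct")
    if (!is.na(profile$dose)) {
      res$clearance_over_F <- clearance_over_F(profile$dose, ainf$auc_inf)
    }
    mrt <- mean_residence_time(auc, ext$clast, ext$tlast, fit, ainf$auc_inf)
    res$mrt_last <- mrt$mrt_last
    res$mrt_inf <- mrt$mrt_inf
  }
  if (is.null(fit)) {
    mrt <- mean_residence_time(auc, ext$clast, ext$tlast)
    res$mrt_last <- mrt$mrt_last
  }
  if (!is.na(options$threshold)) {
    q <- quantifiable(profile)
    thr <- time_above_threshold(q$time, q$conc, options$threshold, fit)
    res$threshold_onset <- thr$onset
    res$threshold_crossing <- thr$crossing
    res$threshold_duration <- thr$duration
    res$threshold_censored <- thr$censored
    res$threshold_extrapolated <- thr$extrapolated
    if (thr$censored) flags <- c(flags, "threshold_duration_censored")
  }
  res$flags <- flags
  structure(res, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA result: subject %s, analyte %s, dose %s mg/kg\n",
              x$subject_id, x$analyte, format(x$dose_mg_per_kg)))
  show <- c("cmax", "tmax", "tlast", "t_half", "auc_last", "auc_inf",
            "clearance_over_F", "lambda_z", "mrt_last", "mrt_inf",
            "pct_extrapolated", "threshold_duration")
  for (p in show) cat(sprintf("  %-20s %s\n", p, format(x[[p]], digits = 5)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  x$flags <- paste(x$flags, collapse = ";")
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Run NCA on every subject x analyte profile of a concentration table
#'
#' Profiles with no quantifiable data yield a row of `NA` parameters with the
#' `no_quantifiable_data` flag rather than aborting the batch.
#'
#' @param table A concentration table (the dialect of
#'   [read_concentration_table()]).
#' @param options An [nca_options()].
#' @return A data.frame with one row per subject x analyte.
#' @export
run_nca_table <- function(table, options = nca_options()) {
  stopifnot(is.data.frame(table))
  key <- interaction(table$subject_id, table$analyte, drop = TRUE)
  rows <- lapply(split(table, key), function(d) {
    d <- d[order(d$time_h), ]
    prof <- pk_profile(d$time_h, d$conc_ng_per_ml, blq = d$blq,
                       dose = d$dose_mg_per_kg[1L],
                       subject_id = as.character(d$subject_id[1L]),
                       group_label = as.character(d$group_label[1L]),
                       formulation = as.character(d$formulation[1L]),
                       analyte = as.character(d$analyte[1L]))
    tryCatch(as.data.frame(run_nca(prof, options)),
             depotnca_no_quantifiable_data = function(e) {
               empty <- as.data.frame(run_nca(
                 pk_profile(c(1, 2), c(1, 1), dose = 1,
                            subject_id = prof$subject_id,
                            group_label = prof$group_label,
                            formulation = prof$formulation,
                            analyte = prof$analyte),
                 options))
               empty[1L, setdiff(names(empty),
                                 c("subject_id", "group_label", "formulation",
                                   "analyte"))] <- NA
               empty$dose_mg_per_kg <- prof$dose
               empty$flags <- "no_quantifiable_data"
               empty
             })
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group_label, out$subject_id, out$analyte), ]
  rownames(out) <- NULL
  out
}
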