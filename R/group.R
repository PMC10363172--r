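#' Mean +/- SD concentration curve for one group and analyte
#'
#' Per scheduled time point, the arithmetic mean and n-1 sample standard
#' deviation over quantifiable values. By default BLQ values are excluded
#' from the average (with the per-point n reporting how many values entered);
#' `blq = "zero"` imputes zero instead.
#'
#' @param table A concentration table.
#' @param group Group label.
#' @param analyte `"parent"` or `"metabolite"`.
#' @param blq `"exclude"` (default) or `"zero"`.
#' @return A data.frame `group_label`, `analyte`, `time_h`, `mean_conc`,
#'   `sd_conc` (`NA` when n < 2), `n`.
#' @export
mean_sd_curve <- function(table, group, analyte = "parent",
                          blq = c("exclude", "zero")) {
  blq_policy <- match.arg(blq)
  d <- table[table$group_label == group & table$analyte == analyte, ]
  if (!nrow(d)) stop("no rows for group ", group, ", analyte ", analyte)
  if (blq_policy == "zero") d$conc_ng_per_ml[d$blq == 1] <- 0
  sp <- split(d$conc_ng_per_ml, d$time_h)
  times <- as.numeric(names(sp))
  stats_at <- function(v) {
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
      n = length(v))
  }
  m <- t(vapply(sp, stats_at, numeric(3)))
  out <- data.frame(group_label = group, analyte = analyte, time_h = times,
                    mean_conc = m[, "mean"], sd_conc = m[, "sd"],
                    n = as.integer(m[, "n"]))
  out <- out[order(out$time_h), ]
  rownames(out) <- NULL
  out
}

# The standard extravascular NCA report parameters, in report order.
table1_parameters <- function() {
  c("cmax", "tmax", "tlast", "t_half", "auc_last", "auc_inf",
    "clearance_over_F", "lambda_z", "mrt_last", "mrt_inf")
}

#' Group summaries of NCA parameters
#'
#' One row per parameter per group with mean, n-1 sample SD and the number of
#' subjects for which the parameter was estimable (SD is `NA` when n < 2).
#' Covers the ten standard report parameters: Cmax, Tmax, Tlast, t1/2,
#' AUC0-Tlast, AUC0-inf, CL/F, lambda_z, MRT and MRT0-inf.
#'
#' @param results A data.frame from [run_nca_table()] (parent analyte rows
#'   are selected with `analyte`).
#' @param analyte Analyte to summarise (default `"parent"`).
#' @param parameters Character vector of result columns to summarise.
#' @return A data.frame `group_label`, `parameter`, `mean`, `sd`, `n`,
#'   `n_missing`.
#' @export
summarize_parameters <- function(results, analyte = "parent",
                                 parameters = table1_parameters()) {
  stopifnot(is.data.frame(results), all(parameters %in% names(results)))
  d <- results[results$analyte == analyte, ]
  groups <- sort(unique(d$group_label))
  out <- list()
  for (g in groups) {
    dg <- d[d$group_label == g, ]
    for (p in parameters) {
      v <- dg[[p]]
      ok <- !is.na(v)
      out[[length(out) + 1L]] <- data.frame(
        group_label = g, parameter = p,
        mean = if (any(ok)) mean(v[ok]) else NA_real_,
        sd = if (sum(ok) >= 2L) stats::sd(v[ok]) else NA_real_,
        n = sum(ok), n_missing = sum(!ok))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Render a group summary as a mean +/- SD text table
#'
#' @param summary A data.frame from [summarize_parameters()].
#' @param digits Significant digits.
#' @return A character matrix (parameters x groups) of `"mean +/- sd"` cells,
#'   with `(n)` appended when a group has missing subjects for a parameter.
#' @export
format_group_summary <- function(summary, digits = 3) {
  groups <- unique(summary$group_label)
  params <- unique(summary$parameter)
  fmt <- function(row) {
    if (row$n == 0L) return("NE")
    cell <- if (is.na(row$sd)) {
      format(signif(row$mean, digits))
    } else {
      paste0(format(signif(row$mean, digits)), " ± ",
             format(signif(row$sd, digits)))
    }
    if (row$n_missing > 0L) cell <- paste0(cell, " (n=", row$n, ")")
    cell
  }
  m <- matrix("", nrow = length(params), ncol = length(groups),
              dimnames = list(params, groups))
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    m[r$parameter, r$group_label] <- fmt(r)
  }
  m
}

# Enumerated group assignments choose(n, nx), cached: the same index matrix
# is reused across the many small tests a simulation study runs.
.mw_cache <- new.env(parent = emptyenv())

mw_assignments <- function(n, nx) {
  key <- paste0(n, ".", nx)
  if (is.null(.mw_cache[[key]])) .mw_cache[[key]] <- utils::combn(n, nx)
  .mw_cache[[key]]
}

# Mann-Whitney U of x against y using mid-ranks for ties.
mw_u_statistic <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
}

#' Exact Mann-Whitney test (two-sided, tie-aware)
#'
#' The U statistic uses mid-ranks. For combined sample sizes up to
#' `exact_max_n` the two-sided p-value is exact: all
#' `choose(n_x + n_y, n_x)` assignments of the observed values to the first
#' group are enumerated (conditioning on the observed ties), and
#' `p = P(|U - n_x n_y / 2| >= |U_obs - n_x n_y / 2|)` under that permutation
#' distribution. Larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max_n Largest combined sample size for exact enumeration.
#' @return List `U`, `p`, `method` (`"exact"` or `"normal-approx"`).
#' @examples
#' mann_whitney_exact(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_exact <- function(x, y, exact_max_n = 20L) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  stopifnot(is.numeric(x), is.numeric(y), !anyNA(x), !anyNA(y))
  nx <- length(x); ny <- length(y); n <- nx + ny
  u_obs <- mw_u_statistic(x, y)
  mu <- nx * ny / 2
  if (n <= exact_max_n) {
    r <- rank(c(x, y))
    idx <- mw_assignments(n, nx)
    # column sums of ranks for every assignment of nx values to group x
    u_all <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    return(list(U = u_obs, p = p, method = "exact"))
  }
  r <- rank(c(x, y))
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  list(U = u_obs, p = p, method = "normal-approx")
}

#' Bonferroni adjustment with explicit family size
#'
#' `p_adj = min(1, family_size * p)`. The family size is a study-design fact
#' and must be supplied; it is never inferred from the length of `p`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param family_size Number of tests in the family, >= 1.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p, family_size) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1), family_size >= 1)
  pmin(1, family_size * p)
}

#' Pairwise between-group comparisons of NCA parameters
#'
#' For each requested parameter and group pair, a two-sided Mann-Whitney test
#' (exact at these sample sizes) on per-subject values, Bonferroni-adjusted
#' with the caller's declared family size.
#'
#' @param results A data.frame from [run_nca_table()].
#' @param pairs A list of length-2 character vectors of group labels.
#' @param parameters Result columns to compare.
#' @param family_size Explicit Bonferroni family size (1 = no adjustment).
#' @param alpha Significance level applied to the adjusted p-value.
#' @param analyte Analyte whose results are compared.
#' @return A data.frame `parameter`, `group_a`, `group_b`, `n_a`, `n_b`, `U`,
#'   `p_exact`, `p_adjusted`, `method`, `significant`.
#' @export
compare_groups <- function(results, pairs, parameters = table1_parameters(),
                           family_size = 1, alpha = 0.05, analyte = "parent") {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  d <- results[results$analyte == analyte, ]
  out <- list()
  for (p in parameters) {
    for (pr in pairs) {
      stopifnot(length(pr) == 2L)
      va <- d[[p]][d$group_label == pr[1L]]
      vb <- d[[p]][d$group_label == pr[2L]]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      tst <- mann_whitney_exact(va, vb)
      out[[length(out) + 1L]] <- data.frame(
        parameter = p, group_a = pr[1L], group_b = pr[2L],
        n_a = length(va), n_b = length(vb),
        U = tst$U, p_exact = tst$p,
        p_adjusted = bonferroni_adjust(tst$p, family_size),
        method = tst$method, significant = NA)
    }
  }
  out <- do.call(rbind, out)
  out$significant <- out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}

#' Dose-trend description across extended-release dose groups
#'
#' Descriptive only: reports whether group-mean Cmax and AUC0-Tlast increase
#' strictly with dose, plus the log-log slope (slope 1 = dose-proportional
#' exposure).
#'
#' @param summaries A data.frame from [summarize_parameters()].
#' @param design A [study_design()] (supplies each group's dose).
#' @param formulation Formulation tag whose dose groups are examined.
#' @return List `formulation`, `doses`, `cmax_means`, `auc_means`,
#'   `cmax_strictly_increasing`, `auc_strictly_increasing`,
#'   `cmax_loglog_slope`, `auc_loglog_slope`.
#' @export
dose_trend <- function(summaries, design, formulation = "EXR") {
  g <- design$groups[design$groups$formulation == formulation, ]
  if (nrow(g) < 2L) stop("need at least two dose groups for a trend")
  g <- g[order(g$dose_mg_per_kg), ]
  pick <- function(param) {
    vapply(g$label, function(lb) {
      v <- summaries$mean[summaries$group_label == lb &
                            summaries$parameter == param]
      if (length(v) != 1L) NA_real_ else v
    }, numeric(1))
  }
  cmax <- pick("cmax"); auc <- pick("auc_last")
  loglog <- function(v) {
    if (anyNA(v) || any(v <= 0)) return(NA_real_)
    unname(stats::coef(stats::lm(log(v) ~ log(g$dose_mg_per_kg)))[2L])
  }
  list(formulation = formulation, doses = g$dose_mg_per_kg,
       cmax_means = unname(cmax), auc_means = unname(auc),
       cmax_strictly_increasing = !anyNA(cmax) && all(diff(cmax) > 0),
       auc_strictly_increasing = !anyNA(auc) && all(diff(auc) > 0),
       cmax_loglog_slope = loglog(cmax), auc_loglog_slope = loglog(auc))
}

#' Threshold onset/duration from group mean curves
#'
#' Applies [time_above_threshold()] to each group's mean parent curve, both
#' without a terminal fit (censored, observation-limited coverage) and, where
#' estimable, with the mean curve's own terminal log-linear fit
#' (extrapolated crossing). The `fit_source` column records which was used
#' for the extrapolated figures.
#'
#' @param table A concentration table.
#' @param design A [study_design()].
#' @param options An [nca_options()].
#' @return A data.frame, one row per group: onset, observed coverage end and
#'   censored duration, extrapolated crossing and duration (NA when the mean
#'   curve has no estimable terminal phase).
#' @export
threshold_report <- function(table, design, options = nca_options()) {
  thr <- if (!is.na(options$threshold)) options$threshold else design$threshold_ng_per_ml
  out <- list()
  for (g in design$groups$label) {
    mc <- mean_sd_curve(table, g, "parent")
    mc <- mc[!is.na(mc$mean_conc), ]
    prof <- pk_profile(mc$time_h, mc$mean_conc, dose = NA_real_,
                       subject_id = g, group_label = g, analyte = "parent")
    fit <- fit_lambda_z(prof, options)
    obs <- time_above_threshold(mc$time_h, mc$mean_conc, thr, fit = NULL)
    ext <- time_above_threshold(mc$time_h, mc$mean_conc, thr, fit = fit)
    out[[length(out) + 1L]] <- data.frame(
      group_label = g, threshold = thr,
      onset = obs$onset,
      observed_end = max(mc$time_h),
      observed_duration = obs$duration,
      observed_censored = obs$censored,
      extrapolated_crossing = ext$crossing,
      extrapolated_duration = if (is.null(fit) && obs$censored) NA_real_ else ext$duration,
      fit_source = if (is.null(fit)) "none" else "mean-curve",
      mean_curve_lambda_z = if (is.null(fit)) NA_real_ else fit$lambda_z)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
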