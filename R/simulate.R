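#' Dual-depot Bateman concentration
#'
#' Concentration of the parent analyte at time `t` after a single
#' extravascular dose split between two first-order depots:
#' \deqn{C(t) = \frac{D \cdot 10^3}{V/F}\left[
#'   f\frac{k_{a1}}{k_{a1}-k_e}(e^{-k_e t}-e^{-k_{a1} t}) +
#'   (1-f)\frac{k_{a2}}{k_{a2}-k_e}(e^{-k_e t}-e^{-k_{a2} t})\right]}
#' with the dose converted mg/kg to ug/kg so concentrations come out in
#' ug/L, numerically identical to ng/mL.
#'
#' @param t Time(s) post-dose in hours, >= 0. Vectorised.
#' @param dose Dose in mg/kg, > 0.
#' @param p A [pk_parameters()] object.
#' @return Concentration(s) in ng/mL; `C(0) = 0`, always >= 0.
#' @examples
#' p <- pk_parameters(1.8, 55, 0.9, 0.12, 0.5)
#' dual_bateman_concentration(c(0, 8, 72), 0.15, p)
#' @export
dual_bateman_concentration <- function(t, dose, p) {
  stopifnot(inherits(p, "pk_parameters"), is.numeric(t), all(t >= 0),
            is.numeric(dose), length(dose) == 1L, dose > 0)
  ke <- p$ke
  for (ka in c(p$ka_fast, p$ka_slow)) {
    if (abs(ka - ke) / ke < .rate_epsilon) {
      stop("degenerate rates: |ka - ke|/ke below ", .rate_epsilon,
           " (construct parameters via pk_parameters() to nudge)")
    }
  }
  amt <- dose * 1e3 / p$volume_over_F   # ug/kg over L/kg -> ug/L == ng/mL
  term <- function(ka, f) {
    if (f == 0) return(0)
    f * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
  }
  c_t <- amt * (term(p$ka_fast, p$frac_fast) + term(p$ka_slow, 1 - p$frac_fast))
  pmax(c_t, 0)  # guard vanishing negative round-off at t = 0
}

#' Metabolite concentration from the depot -> parent -> metabolite cascade
#'
#' A fraction `m$fm` of first-order parent elimination forms the metabolite,
#' which is cleared at `m$ke_m`. The linear cascade has a closed form: each
#' depot contributes a three-exponential term (rates `ka`, `ke`, `ke_m`).
#' The closed form agrees with numerical integration of the cascade ODEs to
#' relative error well below 1e-6 (verified in the test suite against an
#' independent ODE solver).
#'
#' @param t Time(s) post-dose in hours, >= 0. Vectorised.
#' @param dose Dose in mg/kg, > 0.
#' @param p A [pk_parameters()] object (parent kinetics).
#' @param m A [metabolite_params()] object.
#' @return Metabolite concentration(s) in ng/mL; 0 at `t = 0`.
#' @export
simulate_metabolite <- function(t, dose, p, m) {
  stopifnot(inherits(p, "pk_parameters"), inherits(m, "metabolite_params"),
            is.numeric(t), all(t >= 0), dose > 0)
  if (m$fm == 0) return(rep(0, length(t)))
  ke <- p$ke
  kem <- m$ke_m
  if (abs(kem - ke) / ke < .rate_epsilon) kem <- ke * (1 + 2 * .rate_epsilon)
  amt <- dose * 1e3  # ug/kg
  one_depot <- function(ka, f) {
    if (f == 0) return(0)
    if (abs(kem - ka) / ka < .rate_epsilon) ka <- ka * (1 + 2 * .rate_epsilon)
    b <- f * amt * ka / (ka - ke)
    m$fm * ke * b * ((exp(-ke * t) - exp(-kem * t)) / (kem - ke) -
                     (exp(-ka * t) - exp(-kem * t)) / (kem - ka))
  }
  c_m <- (one_depot(p$ka_fast, p$frac_fast) +
          one_depot(p$ka_slow, 1 - p$frac_fast)) / m$volume_m_over_F
  pmax(c_m, 0)
}

#' Simulate one subject's sampled profile
#'
#' Evaluates the noise-free model at the schedule times and multiplies each
#' value by log-normal proportional error with median 1 and coefficient of
#' variation `residual_cv` (`sdlog = sqrt(log(1 + cv^2))`), so
#' `residual_cv = 0` reproduces the noise-free curve exactly. Randomness is
#' drawn from R's current RNG stream; seed it (or use [simulate_study()],
#' which derives per-subject seeds) for reproducibility.
#'
#' @param p A [pk_parameters()] object.
#' @param dose Dose in mg/kg.
#' @param schedule_h Sampling times in hours, strictly increasing, > 0.
#' @param residual_cv Proportional residual error CV, >= 0.
#' @param m Optional [metabolite_params()]; when supplied the metabolite is
#'   simulated with its own independent residual draws.
#' @return A data.frame with columns `analyte`, `time_h`, `conc_ng_per_ml`.
#' @export
simulate_subject <- function(p, dose, schedule_h, residual_cv = 0, m = NULL) {
  stopifnot(all(schedule_h > 0), all(diff(schedule_h) > 0), residual_cv >= 0)
  noisy <- function(x) {
    if (residual_cv == 0) return(x)
    sdlog <- sqrt(log(1 + residual_cv^2))
    x * exp(stats::rnorm(length(x), 0, sdlog))
  }
  out <- data.frame(analyte = "parent", time_h = schedule_h,
                    conc_ng_per_ml = noisy(dual_bateman_concentration(schedule_h, dose, p)))
  if (!is.null(m)) {
    out <- rbind(out, data.frame(
      analyte = "metabolite", time_h = schedule_h,
      conc_ng_per_ml = noisy(simulate_metabolite(schedule_h, dose, p, m))))
  }
  out
}

#' Censor a concentration table at the quantitation limit
#'
#' Rows with concentration strictly below `lloq` are flagged `blq = 1` and
#' their numeric value removed (`NA`), so downstream analysis must own the
#' imputation policy. A value exactly at the LLOQ is quantifiable. Row count
#' and quantifiable values are unchanged.
#'
#' @param table A concentration table (see [read_concentration_table()] for
#'   the column dialect) with `conc_ng_per_ml` present for every row.
#' @param lloq Lower limit of quantitation, ng/mL, > 0.
#' @return The table with `blq` set and BLQ concentrations replaced by `NA`.
#' @export
censor_lloq <- function(table, lloq) {
  stopifnot(is.data.frame(table), "conc_ng_per_ml" %in% names(table), lloq > 0)
  blq <- !is.na(table$conc_ng_per_ml) & table$conc_ng_per_ml < lloq
  table$blq <- as.integer(blq)
  table$conc_ng_per_ml[blq] <- NA_real_
  table
}

# Deterministic per-subject seed: independent of other groups' sizes so that
# changing one group's n never perturbs another subject's draws.
subject_seed <- function(root_seed, group_index, subject_index) {
  key <- 1000L * group_index + subject_index
  as.integer((as.double(root_seed) + 7919 * key) %% 2147483647)
}

#' Simulate a full sparse-sampling study
#'
#' Draws each subject's parameters log-normally around the population typical
#' values (typical = median; `sdlog = sqrt(log(1 + cv^2))`), simulates the
#' sampled profiles with proportional residual error, and censors at the
#' design LLOQ. Each subject consumes an RNG substream seeded from
#' `(seed, group index, subject index)`, so results are reproducible from the
#' root seed and unchanged for a subject when other groups are edited.
#'
#' @param design A [study_design()] object.
#' @param pop A [population_params()] object.
#' @param seed Integer root seed.
#' @return A list of class `study_simulation`:
#' \describe{
#'   \item{concentrations}{data.frame in the concentration-table dialect
#'     (`subject_id`, `group_label`, `formulation`, `dose_mg_per_kg`,
#'     `analyte`, `time_h`, `conc_ng_per_ml`, `blq`).}
#'   \item{truth}{data.frame of per-subject simulated parameters, including
#'     the derived `ke` and the true terminal rate `min(ke, ka_slow)`.}
#' }
#' @export
simulate_study <- function(design, pop, seed) {
  stopifnot(inherits(design, "study_design"), inherits(pop, "population_params"),
            is.numeric(seed), length(seed) == 1L)
  typ <- pop$typical
  cvs <- pop$bsv_cv
  conc <- list()
  truth <- list()
  for (g in seq_len(nrow(design$groups))) {
    grp <- design$groups[g, ]
    for (i in seq_len(grp$n)) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      }
      set.seed(subject_seed(seed, g, i))
      draw <- function(typical, cv) {
        if (cv == 0) return(typical)
        typical * exp(stats::rnorm(1, 0, sqrt(log(1 + cv^2))))
      }
      p_i <- pk_parameters(
        clearance_over_F = draw(typ$clearance_over_F, cvs[["clearance_over_F"]]),
        volume_over_F = draw(typ$volume_over_F, cvs[["volume_over_F"]]),
        ka_fast = draw(typ$ka_fast, cvs[["ka_fast"]]),
        ka_slow = draw(typ$ka_slow, cvs[["ka_slow"]]),
        frac_fast = typ$frac_fast
      )
      prof <- simulate_subject(p_i, grp$dose_mg_per_kg, design$schedule_h,
                               residual_cv = pop$residual_cv, m = pop$metabolite)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      sid <- sprintf("%s-%02d", gsub("[^A-Za-z0-9.]+", "_", grp$label), i)
      prof <- cbind(data.frame(subject_id = sid, group_label = grp$label,
                               formulation = grp$formulation,
                               dose_mg_per_kg = grp$dose_mg_per_kg),
                    prof)
      conc[[length(conc) + 1L]] <- prof
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = sid, group_label = grp$label,
        dose_mg_per_kg = grp$dose_mg_per_kg,
        clearance_over_F = p_i$clearance_over_F,
        volume_over_F = p_i$volume_over_F,
        ka_fast = p_i$ka_fast, ka_slow = p_i$ka_slow,
        frac_fast = p_i$frac_fast, ke = p_i$ke,
        lambda_z_true = min(p_i$ke, p_i$ka_slow),
        t_half_true = log(2) / min(p_i$ke, p_i$ka_slow)
      )
    }
  }
  conc <- do.call(rbind, conc)
  conc$blq <- 0L
  conc <- censor_lloq(conc, design$lloq_ng_per_ml)
  # canonical row order (the reader's sort), so write/read round-trips exactly
  conc <- conc[order(conc$subject_id, conc$analyte, conc$time_h), ]
  rownames(conc) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(concentrations = conc, truth = truth), class = "study_simulation")
}

#' In-vitro microsome time course
#'
#' Closed-form two-step first-order kinetics:
#' parent `c0 * exp(-k_dep t)`; metabolite
#' `c0 * k_form/(k_out - k_dep) * (exp(-k_dep t) - exp(-k_out t))`,
#' with the limiting form `c0 * k_form * t * exp(-k_dep t)` when
#' `k_out == k_dep`.
#'
#' @param preset A [microsome_preset()] object.
#' @param t_grid_min Sampling times in minutes, >= 0 (default: the standard
#'   0, 5, 10, 15, 30, 45, 60 min assay draws).
#' @return A data.frame `species`, `time_min`, `parent_uM`, `metabolite_uM`.
#' @export
simulate_microsome_timecourse <- function(preset,
                                          t_grid_min = c(0, 5, 10, 15, 30, 45, 60)) {
  stopifnot(inherits(preset, "microsome_preset"), all(t_grid_min >= 0))
  t <- as.numeric(t_grid_min)
  parent <- preset$c0 * exp(-preset$k_dep * t)
  if (preset$k_form == 0) {
    met <- rep(0, length(t))
  } else if (abs(preset$k_out - preset$k_dep) < 1e-12) {
    met <- preset$c0 * preset$k_form * t * exp(-preset$k_dep * t)
  } else {
    met <- preset$c0 * preset$k_form / (preset$k_out - preset$k_dep) *
      (exp(-preset$k_dep * t) - exp(-preset$k_out * t))
  }
  data.frame(species = preset$species, time_min = t,
             parent_uM = parent, metabolite_uM = pmax(met, 0))
}
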