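# Shared fixtures: typical parameters, designs with variability switched off,
# and independent numerical oracles used across test files.

typical_params <- function() {
  pk_parameters(clearance_over_F = 1.8, volume_over_F = 55,
                ka_fast = 0.9, ka_slow = 0.12, frac_fast = 0.5)
}

single_depot_params <- function(ka = 0.5, CL = 1.8, V = 55) {
  pk_parameters(clearance_over_F = CL, volume_over_F = V,
                ka_fast = ka, ka_slow = ka * 2, frac_fast = 1)
}

reference_design <- function() default_study_design()

noise_free_population <- function(metabolite = NULL) {
  population_params(typical = typical_params(), bsv_cv = numeric(0),
                    residual_cv = 0, metabolite = metabolite)
}

# Dense two-resolution grid: fine where the curve bends (absorption phase),
# and spanning ~45 terminal half-lives so the best-window search is dominated
# by the pure terminal phase.
dense_schedule <- function() c(seq(0.02, 24, by = 0.02), seq(24.5, 960, by = 0.5))

make_profile <- function(time, conc, blq = NULL, dose = 0.15, ...) {
  pk_profile(time, conc, blq = blq, dose = dose, subject_id = "S1", ...)
}

# Adaptive-quadrature oracle for one linear-up/log-down segment of the
# concentration curve or its first-moment curve. Integrates the declared
# interpolant: exponential between positive declining endpoints, otherwise
# linear (for the moment curve, linear in t*C).
segment_quadrature <- function(t1, c1, t2, c2, moment = FALSE) {
  logdown <- c2 < c1 && c2 > 0
  f <- if (logdown) {
    k <- log(c1 / c2) / (t2 - t1)
    if (moment) function(t) t * c1 * exp(-k * (t - t1))
    else function(t) c1 * exp(-k * (t - t1))
  } else {
    if (moment) function(t) (t1 * c1 + (t - t1) / (t2 - t1) * (t2 * c2 - t1 * c1))
    else function(t) c1 + (t - t1) / (t2 - t1) * (c2 - c1)
  }
  stats::integrate(f, t1, t2, rel.tol = 1e-12, abs.tol = 0)$value
}

# Fine-grid ODE integration of depot -> parent -> metabolite with deSolve;
# the independent oracle for the closed-form cascade.
cascade_ode_oracle <- function(t_out, dose, p, m) {
  rhs <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      dD1 <- -ka1 * D1
      dD2 <- -ka2 * D2
      dP <- ka1 * D1 + ka2 * D2 - ke * P
      dM <- fm * ke * P - kem * M
      list(c(dD1, dD2, dP, dM))
    })
  }
  amt <- dose * 1e3
  y0 <- c(D1 = p$frac_fast * amt, D2 = (1 - p$frac_fast) * amt, P = 0, M = 0)
  parms <- c(ka1 = p$ka_fast, ka2 = p$ka_slow, ke = p$ke, fm = m$fm,
             kem = m$ke_m)
  out <- deSolve::lsoda(y0, c(0, t_out), rhs, parms, rtol = 1e-11, atol = 1e-12)
  out[-1L, "M"] / m$volume_m_over_F
}

# Brute-force Mann-Whitney oracle: enumerate every assignment and compute U
# by direct pairwise counting (independent of the rank-sum implementation).
mw_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x); n <- length(pooled)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- nx * length(y) / 2
  u_obs <- u_of(x, y)
  sets <- utils::combn(n, nx)
  u_all <- apply(sets, 2L, function(idx) u_of(pooled[idx], pooled[-idx]))
  list(U = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}
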