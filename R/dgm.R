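# Synthetic data-generating mechanisms with known truth.

#' Coefficients of the cardiovascular simulation mechanism
#'
#' Returns the full set of coefficients used by [generate_dataset()] and
#' [true_psi()]. The mechanism emulates a statin-initiation / cardiovascular
#' outcome setting: five covariates (age in years, natural-log LDL
#' cholesterol, a diabetes indicator, a frailty indicator and a unitless
#' risk score), a binary treatment assigned with confounding by indication
#' (sicker, higher-risk people are more likely to be treated), and a binary
#' outcome whose risk is lowered by treatment with effect modification by
#' LDL. Covariate effects enter through nonlinear and interaction terms, so
#' main-effects nuisance models are deliberately misspecified.
#'
#' Keeping every coefficient in one record makes the mechanism auditable and
#' lets tests switch off the treatment effect (`outcome$treat`,
#' `outcome$treat_ldl`) to verify the null-effect limit.
#'
#' @return A named list of coefficient lists, one per structural equation:
#'   `age`, `ldl`, `diabetes`, `frailty`, `risk_score`, `treatment`,
#'   `outcome`.
#' @export
dgm_coefficients <- function() {
  list(
    # age ~ Uniform(min, max), rounded to whole years
    age = list(min = 40, max = 75),
    # ln(LDL) ~ Normal(intercept + age * age_slope, sd)
    ldl = list(intercept = 4.70, age_slope = 0.005, sd = 0.20),
    # diabetes ~ Bernoulli(expit(b0 + b1*ldl_log + b2*age + b3*age^2))
    diabetes = list(intercept = -4.23, ldl_log = 0.03, age = -0.02,
                    age_sq = 0.0009),
    # frailty ~ Bernoulli(expit(b0 + b1*(age-20) + b2*exp(ldl_log) + b3*diabetes))
    frailty = list(intercept = -5.5, age20 = 0.05, ldl = 0.001,
                   diabetes = 0.5),
    # risk_score = expit(b0 + b1*age + b2*ldl_log + b3*diabetes + b4*frailty
    #                    + b5*(age-55)*(ldl_log-5))
    risk_score = list(intercept = -7.0, age = 0.06, ldl_log = 0.60,
                      diabetes = 0.90, frailty = 1.20, age_ldl = -0.01),
    # P(A=1|L) = expit(b0 + b1*diabetes + b2*(ldl_log-5) + b3*(risk-0.35)
    #                  + b4*(age-55) + b5*frailty)
    treatment = list(intercept = -1.2, diabetes = 0.95, ldl_c = 0.35,
                     risk_c = 2.5, age_c = 0.02, frailty = 0.3),
    # P(Y=1|A=a,L) = expit(b0 + treat*a + treat_ldl*a*(ldl_log-5)
    #                      + b1*(age-55) + b2*(ldl_log-5) + b3*diabetes
    #                      + b4*frailty + b5*(risk-0.35)
    #                      + b6*(age-55)*(ldl_log-5))
    outcome = list(intercept = -2.2, treat = -0.8, treat_ldl = -0.3,
                   age_c = 0.05, ldl_c = 0.60, diabetes = 0.70,
                   frailty = 0.90, risk_c = 1.80, age_ldl = 0.015)
  )
}

# Draw the five covariates; returns a data.frame. Consumes RNG.
draw_covariates <- function(n, coef) {
  age <- round(stats::runif(n, coef$age$min, coef$age$max))
  ldl_log <- stats::rnorm(n, coef$ldl$intercept + coef$ldl$age_slope * age,
                          coef$ldl$sd)
  cd <- coef$diabetes
  diabetes <- stats::rbinom(n, 1L, stats::plogis(
    cd$intercept + cd$ldl_log * ldl_log + cd$age * age + cd$age_sq * age^2))
  cf <- coef$frailty
  frailty <- stats::rbinom(n, 1L, stats::plogis(
    cf$intercept + cf$age20 * (age - 20) + cf$ldl * exp(ldl_log) +
      cf$diabetes * diabetes))
  cr <- coef$risk_score
  risk_score <- stats::plogis(
    cr$intercept + cr$age * age + cr$ldl_log * ldl_log +
      cr$diabetes * diabetes + cr$frailty * frailty +
      cr$age_ldl * (age - 55) * (ldl_log - 5))
  data.frame(age = age, ldl_log = ldl_log, diabetes = diabetes,
             frailty = frailty, risk_score = risk_score)
}

# True propensity P(A=1|L) under the mechanism.
dgm_propensity <- function(L, coef) {
  ct <- coef$treatment
  stats::plogis(ct$intercept + ct$diabetes * L$diabetes +
                  ct$ldl_c * (L$ldl_log - 5) +
                  ct$risk_c * (L$risk_score - 0.35) +
                  ct$age_c * (L$age - 55) + ct$frailty * L$frailty)
}

# True outcome risk P(Y=1|A=a,L) under the mechanism.
dgm_outcome_risk <- function(a, L, coef) {
  co <- coef$outcome
  stats::plogis(co$intercept + co$treat * a +
                  co$treat_ldl * a * (L$ldl_log - 5) +
                  co$age_c * (L$age - 55) + co$ldl_c * (L$ldl_log - 5) +
                  co$diabetes * L$diabetes + co$frailty * L$frailty +
                  co$risk_c * (L$risk_score - 0.35) +
                  co$age_ldl * (L$age - 55) * (L$ldl_log - 5))
}

#' Generate one synthetic observational dataset
#'
#' Draws `n` records from the cardiovascular simulation mechanism (see
#' [dgm_coefficients()]): covariates, a confounded binary treatment `A`, and
#' a binary outcome `Y` equal to the potential outcome under the received
#' treatment.
#'
#' @param n Number of records (positive integer).
#' @param seed Integer seed; the same `(n, seed)` pair always reproduces
#'   the same table element-wise.
#' @param coef Coefficient record, by default [dgm_coefficients()].
#' @return A `data.frame` with columns `Y`, `A`, `age`, `ldl_log`,
#'   `diabetes`, `frailty`, `risk_score` and attribute `"seed"`.
#' @seealso [true_psi()] for the marginal risk difference of this
#'   mechanism; [generate_simple_dataset()] for a closed-form test
#'   mechanism.
#' @examples
#' d <- generate_dataset(500, seed = 1)
#' colMeans(d[, c("Y", "A")])
#' @export
generate_dataset <- function(n, seed, coef = dgm_coefficients()) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  L <- draw_covariates(n, coef)
  A <- stats::rbinom(n, 1L, dgm_propensity(L, coef))
  y1 <- stats::rbinom(n, 1L, dgm_outcome_risk(1L, L, coef))
  y0 <- stats::rbinom(n, 1L, dgm_outcome_risk(0L, L, coef))
  d <- cbind(data.frame(Y = ifelse(A == 1L, y1, y0), A = A), L)
  attr(d, "seed") <- as.integer(seed)
  d
}

#' True marginal risk difference of the simulation mechanism
#'
#' Computes the causal estimand psi = E[Y1 - Y0] by large-sample
#' potential-outcome simulation: `n_truth` covariate vectors are drawn, both
#' potential outcomes are realised for each (independent Bernoulli draws
#' under treatment and control), and psi is the mean difference.
#'
#' @param n_truth Number of potential-outcome draws; at least 1e5 is
#'   recommended for a Monte Carlo SE below about 0.002.
#' @param seed Integer seed.
#' @param coef Coefficient record, by default [dgm_coefficients()].
#' @return A list with `psi` (true risk difference), `n_truth`, and
#'   `mc_se_truth` (the Monte Carlo standard error of `psi`).
#' @examples
#' true_psi(1e5, seed = 42)$psi
#' @export
true_psi <- function(n_truth, seed, coef = dgm_coefficients()) {
  if (length(n_truth) != 1L || !is.finite(n_truth) || n_truth < 1)
    stop("`n_truth` must be a positive integer", call. = FALSE)
  n_truth <- as.integer(n_truth)
  set.seed(as.integer(seed))
  L <- draw_covariates(n_truth, coef)
  y1 <- stats::rbinom(n_truth, 1L, dgm_outcome_risk(1L, L, coef))
  y0 <- stats::rbinom(n_truth, 1L, dgm_outcome_risk(0L, L, coef))
  diff <- y1 - y0
  list(psi = mean(diff), n_truth = n_truth,
       mc_se_truth = stats::sd(diff) / sqrt(n_truth))
}

# --- Simple single-covariate mechanism with an exactly computable truth ----

simple_dgm_pars <- function() {
  # W ~ Uniform(0,1); A ~ Bern(expit(a0 + a1 W)); Y ~ Bern(expit(b0 + b1 W + theta A))
  list(a0 = -0.4, a1 = 0.8, b0 = -1.2, b1 = 0.8)
}

# Marginal risk difference of the simple mechanism for a given theta,
# by numerical integration over W.
simple_dgm_rd <- function(theta, pars = simple_dgm_pars()) {
  f <- function(w) stats::plogis(pars$b0 + pars$b1 * w + theta) -
    stats::plogis(pars$b0 + pars$b1 * w)
  stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
}

# Solve for the treatment coefficient giving a requested marginal risk
# difference. Root-finding against the integral above.
simple_dgm_theta <- function(effect, pars = simple_dgm_pars()) {
  if (effect == 0) return(0)
  stats::uniroot(function(th) simple_dgm_rd(th, pars) - effect,
                 lower = -40, upper = 40, tol = 1e-12)$root
}

#' Generate data from a simple mechanism with known risk difference
#'
#' A single uniform covariate, logistic treatment and outcome models. The
#' treatment coefficient is solved (by numerical integration and
#' root-finding) so that the marginal risk difference E[Y1 - Y0] equals
#' `effect` exactly. Used for parameter-recovery checks where the truth
#' must be known independently of any simulation.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param effect Target marginal risk difference, strictly inside (-1, 1)
#'   and attainable under the fixed baseline model (roughly (-0.31, 0.69)).
#' @return A `data.frame` with columns `Y`, `A`, `W` and attributes
#'   `"seed"`, `"effect"`, `"theta"` (the solved treatment coefficient).
#' @examples
#' d <- generate_simple_dataset(1000, seed = 3, effect = 0.10)
#' mean(d$Y[d$A == 1]) - mean(d$Y[d$A == 0])  # crude, confounded
#' @export
generate_simple_dataset <- function(n, seed, effect = 0.10) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  if (!is.finite(effect) || effect <= -1 || effect >= 1)
    stop("`effect` must lie strictly inside (-1, 1)", call. = FALSE)
  pars <- simple_dgm_pars()
  theta <- simple_dgm_theta(effect, pars)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  W <- stats::runif(n)
  A <- stats::rbinom(n, 1L, stats::plogis(pars$a0 + pars$a1 * W))
  Y <- stats::rbinom(n, 1L, stats::plogis(pars$b0 + pars$b1 * W + theta * A))
  d <- data.frame(Y = Y, A = A, W = W)
  attr(d, "seed") <- as.integer(seed)
  attr(d, "effect") <- effect
  attr(d, "theta") <- theta
  d
}

#' Write or read a simulated dataset as CSV
#'
#' Plain CSV with a header row (`Y,A,` then the covariate columns); no row
#' names. `read_sim_csv()` checks that the outcome and treatment columns
#' are present and binary.
#'
#' @param data A data frame as produced by [generate_dataset()].
#' @param path File path.
#' @return `write_sim_csv()` returns `path` invisibly; `read_sim_csv()`
#'   returns the data frame.
#' @export
write_sim_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sim_csv
#' @param outcome,treatment Column names to validate on reading.
#' @export
read_sim_csv <- function(path, outcome = "Y", treatment = "A") {
  d <- utils::read.csv(path)
  missing_cols <- setdiff(c(outcome, treatment), names(d))
  if (length(missing_cols))
    stop("columns missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cl in c(outcome, treatment))
    if (!all(d[[cl]] %in% c(0, 1)))
      stop("column ", cl, " must be binary 0/1", call. = FALSE)
  d
}

# Deterministic child-seed stream: repetition/dataset i (and sub-role j) of
# root seed S. Arithmetic kept in doubles below 2^53; result in [0, 2^31-2].
child_seed <- function(seed, i, j = 0) {
  m <- 2147483647
  x <- (as.double(seed) %% m) * 69069 + as.double(i) * 1013904223 +
    as.double(j) * 97561
  as.integer(x %% m)
}
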