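# Targeting step: logistic fluctuation of initial outcome predictions and
# influence-function variance; plus the non-cross-fit comparator.

split_failure <- function(msg) {
  stop(structure(class = c("dcftmle_split_failure", "dcftmle_failure",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Default truncation bounds: propensity scores and outcome predictions are
# kept strictly inside (0,1) before any logit transform.
G_BOUNDS <- c(0.01, 0.99)
Q_BOUNDS <- c(0.0005, 0.9995)

#' TMLE targeting step on one estimation split
#'
#' Given initial nuisance predictions, fits the logistic fluctuation
#' `logit(q_eps) = logit(q) + eps * H` with clever covariate
#' `H = A/g - (1-A)/(1-g)` by offset maximum likelihood (no intercept),
#' and returns the targeted risk difference together with its
#' influence-function variance.
#'
#' The returned variance is `var(IC)/n` where
#' `IC_i = H_i (y_i - q*_{A_i,i}) + (q*_{1,i} - q*_{0,i}) - ATE`, evaluated
#' on the estimation records only.
#'
#' @param y Binary outcome vector on the estimation split.
#' @param a Binary treatment vector on the estimation split.
#' @param g Propensity predictions P(A=1|L); truncated to `g_bounds`.
#' @param q0,q1 Outcome predictions P(Y=1|A=0,L) and P(Y=1|A=1,L);
#'   truncated to `q_bounds`.
#' @param g_bounds,q_bounds Truncation intervals (defaults `[0.01, 0.99]`
#'   and `[0.0005, 0.9995]`).
#' @return A list of class `"split_estimate"`: `ate` (targeted risk
#'   difference), `var` (influence-function variance of `ate`), `n`,
#'   `eps` (fluctuation coefficient) and `score` (the post-targeting mean
#'   of `H (y - q*)`, which should be numerically zero).
#' @examples
#' d <- generate_simple_dataset(500, seed = 1, effect = 0.1)
#' g <- rep(0.5, 500)
#' q <- rep(mean(d$Y), 500)
#' tmle_target(d$Y, d$A, g = g, q0 = q, q1 = q)$ate
#' @export
tmle_target <- function(y, a, g, q0, q1,
                        g_bounds = G_BOUNDS, q_bounds = Q_BOUNDS) {
  n <- length(y)
  stopifnot(length(a) == n, length(g) == n, length(q0) == n,
            length(q1) == n)
  if (!all(y %in% c(0, 1)) || !all(a %in% c(0, 1)))
    stop("`y` and `a` must be binary 0/1", call. = FALSE)
  g <- pmin(pmax(g, g_bounds[1]), g_bounds[2])
  q0 <- pmin(pmax(q0, q_bounds[1]), q_bounds[2])
  q1 <- pmin(pmax(q1, q_bounds[1]), q_bounds[2])

  H <- a / g - (1 - a) / (1 - g)
  qa <- ifelse(a == 1, q1, q0)
  off <- stats::qlogis(qa)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      x = matrix(H, ncol = 1L), y = y, offset = off,
      family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-12, maxit = 100L))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || !is.finite(fit$coefficients[1]))
    split_failure("fluctuation fit did not converge")
  eps <- unname(fit$coefficients[1])

  q1s <- stats::plogis(stats::qlogis(q1) + eps / g)
  q0s <- stats::plogis(stats::qlogis(q0) - eps / (1 - g))
  qas <- ifelse(a == 1, q1s, q0s)
  ate <- mean(q1s - q0s)
  ic <- H * (y - qas) + (q1s - q0s) - ate
  structure(list(ate = ate, var = stats::var(ic) / n, n = n, eps = eps,
                 score = mean(H * (y - qas))),
            class = "split_estimate")
}

# Fit both nuisance models by super learner and produce predictions on an
# estimation set. `train_g` / `train_q` / `est` are row indices into `data`.
fit_nuisances <- function(data, outcome, treatment, covariates,
                          train_g, train_q, est, learners, folds,
                          seed_g, seed_q) {
  Xg <- data[train_g, covariates, drop = FALSE]
  gfit <- fit_super_learner(Xg, data[[treatment]][train_g],
                            library = learners, folds = folds,
                            seed = seed_g)
  Xq <- data[train_q, c(treatment, covariates), drop = FALSE]
  qfit <- fit_super_learner(Xq, data[[outcome]][train_q],
                            library = learners, folds = folds,
                            seed = seed_q)
  Xe <- data[est, covariates, drop = FALSE]
  g <- predict(gfit, Xe, trunc = G_BOUNDS)
  Xe1 <- cbind(stats::setNames(data.frame(1), treatment), Xe)
  Xe0 <- cbind(stats::setNames(data.frame(0), treatment), Xe)
  list(g = g,
       q1 = predict(qfit, Xe1, trunc = Q_BOUNDS),
       q0 = predict(qfit, Xe0, trunc = Q_BOUNDS))
}

#' Non-cross-fit TMLE comparator
#'
#' Fits both nuisance models by super learner on the full sample, targets on
#' the full sample, and returns the estimate in the same shape as
#' [dcf_tmle()] (a single repetition with a single split). This is the
#' "worst-case" comparator: with adaptive learners its influence-function
#' variance is typically anti-conservative.
#'
#' @inheritParams dcf_tmle
#' @return An object of class `"dcf_tmle"` with `method = "tmle"`.
#' @examples
#' d <- generate_simple_dataset(400, seed = 1, effect = 0.1)
#' fit <- tmle_no_crossfit(d, covariates = "W",
#'                         learners = "logit_main_effects", seed = 2)
#' coef(fit)
#' @export
tmle_no_crossfit <- function(data, outcome = "Y", treatment = "A",
                             covariates = NULL,
                             learners = default_learners(),
                             folds = 10L, seed = 1L) {
  covariates <- check_columns(data, outcome, treatment, covariates)
  idx <- seq_len(nrow(data))
  nuis <- fit_nuisances(data, outcome, treatment, covariates,
                        train_g = idx, train_q = idx, est = idx,
                        learners = learners, folds = folds,
                        seed_g = child_seed(seed, 1, 1),
                        seed_q = child_seed(seed, 1, 2))
  est <- tmle_target(data[[outcome]], data[[treatment]],
                     g = nuis$g, q0 = nuis$q0, q1 = nuis$q1)
  reps <- data.frame(rep = 1L, seed = as.integer(seed), status = "success",
                     reason = "", ate_r = est$ate, var_r = est$var,
                     stringsAsFactors = FALSE)
  new_dcf_result(ate = est$ate, var = est$var, reps = reps,
                 method = "tmle", generalization = NA_integer_,
                 p = 1L, r = 1L, n = nrow(data), seed = seed,
                 outcome = outcome, treatment = treatment,
                 covariates = covariates, learners = learners,
                 call = match.call())
}

check_columns <- function(data, outcome, treatment, covariates) {
  if (is.null(covariates))
    covariates <- setdiff(names(data), c(outcome, treatment))
  missing_cols <- setdiff(c(outcome, treatment, covariates), names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!length(covariates)) stop("no covariate columns", call. = FALSE)
  for (cl in c(outcome, treatment))
    if (!all(data[[cl]] %in% c(0, 1)))
      stop("column ", cl, " must be binary 0/1", call. = FALSE)
  covariates
}
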