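# Generalized double cross-fitting: split planning, role assignment,
# the repetition loop and the three-layer aggregation.

#' Partition records into p near-equal random splits
#'
#' A uniformly random permutation of the record indices is cut into `p`
#' non-overlapping blocks whose sizes differ by at most one.
#'
#' @param n Number of records.
#' @param p Number of splits, `3 <= p <= n`.
#' @param seed Integer seed.
#' @return Integer vector of length `n` giving each record's split label in
#'   `1..p`.
#' @examples
#' table(make_splits(10, 3, seed = 1))
#' @export
make_splits <- function(n, p, seed) {
  if (p < 3) stop("double cross-fitting needs p >= 3 splits", call. = FALSE)
  if (p > n) stop("more splits than records (p > n)", call. = FALSE)
  set.seed(as.integer(seed))
  sizes <- rep(n %/% p, p)
  extra <- n %% p
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- integer(n)
  labels[sample.int(n)] <- rep.int(seq_len(p), sizes)
  labels
}

#' Split-role assignment under Generalization 1 (equal splits)
#'
#' Each estimation split `s` borrows exactly one other split for each
#' nuisance model, cyclically: the propensity model is trained on split
#' `s-2` and the outcome model on split `s-1` (labels mod `p`). This is the
#' three-split rotation (propensity from split 1, outcome from split 2,
#' estimation in split 3) extended to arbitrary `p`; for `p > 3` the other
#' `p-3` splits are unused within a single split-estimate. Every split
#' serves each role exactly once per repetition. The orientation (which
#' neighbour trains which model) is a documented convention; the roles are
#' statistically exchangeable.
#'
#' @param p Number of splits (>= 3).
#' @return List of `p` role triples, each a list with `est` (estimation
#'   split label), `P` (propensity-training split labels) and `Q`
#'   (outcome-training split labels).
#' @export
roles_gen1 <- function(p) {
  if (p < 3) stop("double cross-fitting needs p >= 3 splits", call. = FALSE)
  lapply(seq_len(p), function(s) {
    list(est = s,
         P = 1L + (s - 3L) %% p,
         Q = 1L + (s - 2L) %% p)
  })
}

#' Split-role assignment under Generalization 2 (full data use)
#'
#' One split is reserved for effect estimation; the remaining `p-1` splits
#' are divided equally between the two nuisance models by alternating in
#' cyclic order after the estimation split: odd offsets train the
#' propensity model, even offsets the outcome model (so for `p = 5`,
#' estimation in split 1 uses splits {2,4} for the propensity and {3,5}
#' for the outcome model). Requires an odd `p` so the division is equal;
#' at `p = 3` the triples coincide with [roles_gen1()], which is why the
#' two generalizations agree exactly there.
#'
#' @param p Odd number of splits (>= 3).
#' @return As [roles_gen1()]; here `P` and `Q` each contain `(p-1)/2`
#'   labels.
#' @export
roles_gen2 <- function(p) {
  if (p < 3) stop("double cross-fitting needs p >= 3 splits", call. = FALSE)
  if (p %% 2 == 0)
    stop("Generalization 2 requires an odd number of splits; ",
         "use `allow_even_p = TRUE` in dcf_tmle() for the pooled fallback",
         call. = FALSE)
  lapply(seq_len(p), function(s) {
    offs <- seq_len(p - 1L)
    lab <- 1L + (s - 1L + offs) %% p
    list(est = s, P = lab[offs %% 2L == 1L], Q = lab[offs %% 2L == 0L])
  })
}

#' Run one double cross-fitting repetition
#'
#' Randomly partitions the data into `p` splits, assigns nuisance-training
#' roles under the chosen generalization, fits both nuisance models by
#' super learner for every role triple, targets each estimation split with
#' [tmle_target()], and averages: the repetition estimate is the mean of
#' the `p` split estimates, and the repetition variance is that of a mean
#' of independent split estimates — the split-level influence-function
#' variances referred to the full sample size and averaged,
#' `var_r = (1/p) * sum_s Var_s(IC) / n`.
#'
#' Statistical failures (a constant outcome in a training pool, a candidate
#' library that cannot fit, a non-convergent fluctuation) never raise an
#' error; the repetition is returned with `status = "failed"` and the
#' reason recorded.
#'
#' @inheritParams dcf_tmle
#' @param seed Integer seed for this repetition (drives the split
#'   permutation and, deterministically, each nuisance fit).
#' @return A list of class `"repetition_estimate"`: `ate_r`, `var_r`,
#'   `status` (`"success"` or `"failed"`), `reason`, `seed`, and on
#'   success a `splits` data frame with the per-split estimates.
#' @export
run_repetition <- function(data, p = 3L, generalization = 1L,
                           outcome = "Y", treatment = "A",
                           covariates = NULL,
                           learners = default_learners(), folds = 10L,
                           seed = 1L, allow_even_p = FALSE) {
  covariates <- check_columns(data, outcome, treatment, covariates)
  n <- nrow(data)
  even_pooled <- generalization == 2L && p %% 2L == 0L
  if (even_pooled && !allow_even_p)
    stop("Generalization 2 requires an odd number of splits; ",
         "use `allow_even_p = TRUE` for the pooled fallback", call. = FALSE)
  labels <- make_splits(n, p, seed)
  roles <- if (generalization == 1L) roles_gen1(p)
           else if (!even_pooled) roles_gen2(p)
           else NULL

  out <- tryCatch({
    ests <- vector("list", p)
    for (s in seq_len(p)) {
      if (!even_pooled) {
        tri <- roles[[s]]
        train_g <- which(labels %in% tri$P)
        train_q <- which(labels %in% tri$Q)
        est_idx <- which(labels == tri$est)
      } else {
        # even-p fallback: pool the other p-1 splits and re-split the
        # pooled records into two equal halves (seeded deterministically)
        est_idx <- which(labels == s)
        pool <- which(labels != s)
        set.seed(child_seed(seed, s, 9))
        pool <- sample(pool)
        half <- length(pool) %/% 2L
        train_g <- pool[seq_len(half)]
        train_q <- pool[(half + 1L):length(pool)]
      }
      nuis <- fit_nuisances(data, outcome, treatment, covariates,
                            train_g = train_g, train_q = train_q,
                            est = est_idx, learners = learners,
                            folds = folds,
                            seed_g = child_seed(seed, s, 1),
                            seed_q = child_seed(seed, s, 2))
      ests[[s]] <- tmle_target(data[[outcome]][est_idx],
                               data[[treatment]][est_idx],
                               g = nuis$g, q0 = nuis$q0, q1 = nuis$q1)
    }
    ates <- vapply(ests, `[[`, numeric(1), "ate")
    vars <- vapply(ests, `[[`, numeric(1), "var")
    ns <- vapply(ests, `[[`, numeric(1), "n")
    # variance of the mean of p (independent, disjoint-data) split
    # estimates: average the split-level IC variances evaluated over the
    # full sample size, (1/p) * sum_s Var_s(IC)/n
    var_r <- sum(vars * ns) / (n * p)
    list(ate_r = mean(ates), var_r = var_r, status = "success",
         reason = "",
         splits = data.frame(split = seq_len(p), ate_p = ates,
                             var_p = vars,
                             n_p = vapply(ests, `[[`, numeric(1), "n")))
  }, error = function(e) {
    list(ate_r = NA_real_, var_r = NA_real_, status = "failed",
         reason = conditionMessage(e), splits = NULL)
  })
  out$seed <- as.integer(seed)
  class(out) <- "repetition_estimate"
  out
}

#' Aggregate repetition estimates into the overall DCF estimate
#'
#' The overall estimate is the median of the successful repetitions'
#' estimates; the overall variance is the median, over the same
#' repetitions, of the within-repetition variance plus the squared
#' deviation of the repetition estimate from the overall estimate:
#' `var = median( var_r + (ate_r - ate)^2 )`. Failed repetitions are
#' excluded. With an even number of successes the median is the mean of
#' the two central order statistics.
#'
#' @param reps List of `"repetition_estimate"` objects (or a data frame
#'   with columns `ate_r`, `var_r`, `status`).
#' @return A list with `ate`, `var`, `se`, `ci95` (using the normal 1.96
#'   quantile), `n_success`, `n_failed`.
#' @examples
#' reps <- data.frame(ate_r = c(0.10, 0.12, 0.20),
#'                    var_r = c(0.01, 0.01, 0.01), status = "success")
#' aggregate_repetitions(reps)[c("ate", "var")]
#' @export
aggregate_repetitions <- function(reps) {
  if (is.data.frame(reps)) {
    df <- reps
  } else {
    df <- data.frame(
      ate_r = vapply(reps, `[[`, numeric(1), "ate_r"),
      var_r = vapply(reps, `[[`, numeric(1), "var_r"),
      status = vapply(reps, `[[`, character(1), "status"))
  }
  okr <- df[df$status == "success", , drop = FALSE]
  if (!nrow(okr))
    stop(structure(class = c("dcftmle_all_failed", "error", "condition"),
                   list(message = "all repetitions failed", call = NULL)))
  ate <- stats::median(okr$ate_r)
  v <- stats::median(okr$var_r + (okr$ate_r - ate)^2)
  se <- sqrt(v)
  list(ate = ate, var = v, se = se,
       ci95 = c(ate - 1.96 * se, ate + 1.96 * se),
       n_success = nrow(okr), n_failed = sum(df$status != "success"))
}

new_dcf_result <- function(ate, var, reps, method, generalization, p, r, n,
                           seed, outcome, treatment, covariates, learners,
                           call) {
  se <- sqrt(var)
  structure(list(
    ate = ate, var = var, se = se,
    ci95 = c(ate - 1.96 * se, ate + 1.96 * se),
    n_success = sum(reps$status == "success"),
    n_failed = sum(reps$status != "success"),
    method = method, generalization = generalization, p = p, r = r, n = n,
    seed = seed, outcome = outcome, treatment = treatment,
    covariates = covariates, learners = learners, reps = reps,
    call = call), class = "dcf_tmle")
}

#' Double cross-fitted TMLE for the average treatment effect
#'
#' Estimates the risk difference `E[Y1 - Y0]` of a binary treatment on a
#' binary outcome by targeted maximum likelihood with generalized double
#' cross-fitting. Within each of `r` repetitions the data are randomly
#' partitioned into `p` splits; the propensity model, the outcome model and
#' the effect estimate for each split use three mutually disjoint index
#' sets, so neither nuisance model ever sees the records it is evaluated
#' on (removing the Donsker-class restriction on the learners). Each
#' repetition averages its `p` split estimates and variances; the overall
#' estimate is the median over repetitions, and the overall variance the
#' median of the within-repetition variance plus the squared
#' between-repetition deviation (see [aggregate_repetitions()]).
#'
#' @param data Data frame with binary outcome and treatment columns and
#'   one or more covariate columns.
#' @param outcome,treatment Column names of the binary outcome and
#'   treatment.
#' @param covariates Covariate column names; default all other columns.
#' @param p Number of splits (>= 3).
#' @param r Number of repetitions; the default 100 follows standard
#'   practice for stable median aggregation (smaller values are much
#'   cheaper; r = 25 is usually close).
#' @param generalization `1` (each nuisance model trains on a single
#'   split) or `2` (the `p-1` non-estimation splits are divided equally
#'   between the two nuisance models, using the full sample; requires odd
#'   `p` unless `allow_even_p`).
#' @param learners Candidate learner names for both nuisance super
#'   learners; see [default_learners()].
#' @param folds Cross-validation folds inside the super learner.
#' @param seed Integer root seed. Repetition `j` runs on a child seed
#'   derived deterministically from `(seed, j)`, so results do not depend
#'   on execution order and the first repetitions of a longer run
#'   reproduce a shorter run exactly.
#' @param allow_even_p Enable the even-`p` fallback for Generalization 2:
#'   the non-estimation records are pooled and re-split into two equal
#'   halves. Off by default.
#' @param retry_failed Retry a failed repetition with a fresh child seed
#'   (up to `max_retries` times) instead of dropping it. Off by default:
#'   failed repetitions are excluded from the medians and counted.
#' @param max_retries Maximum retries per repetition when `retry_failed`.
#' @return An object of class `"dcf_tmle"`: the point estimate (`ate`),
#'   variance (`var`), standard error (`se`), 95% confidence interval
#'   (`ci95`), success/failure counts, configuration, and a per-repetition
#'   data frame `reps` (columns `rep`, `seed`, `status`, `reason`,
#'   `ate_r`, `var_r`). Methods: `print`, `summary`, `coef`, `confint`,
#'   `plot`.
#' @examples
#' d <- generate_simple_dataset(600, seed = 7, effect = 0.10)
#' fit <- dcf_tmle(d, covariates = "W", p = 3, r = 3,
#'                 learners = "logit_main_effects", seed = 11)
#' fit
#' @export
dcf_tmle <- function(data, outcome = "Y", treatment = "A",
                     covariates = NULL, p = 3L, r = 100L,
                     generalization = 1L,
                     learners = default_learners(), folds = 10L,
                     seed = 1L, allow_even_p = FALSE,
                     retry_failed = FALSE, max_retries = 3L) {
  covariates <- check_columns(data, outcome, treatment, covariates)
  if (!generalization %in% c(1L, 2L))
    stop("`generalization` must be 1 or 2", call. = FALSE)
  if (r < 1) stop("`r` must be a positive integer", call. = FALSE)
  rows <- vector("list", r)
  for (j in seq_len(r)) {
    rep_seed <- child_seed(seed, j)
    rep_out <- run_repetition(data, p = p, generalization = generalization,
                              outcome = outcome, treatment = treatment,
                              covariates = covariates, learners = learners,
                              folds = folds, seed = rep_seed,
                              allow_even_p = allow_even_p)
    attempt <- 0L
    while (retry_failed && rep_out$status == "failed" &&
           attempt < max_retries) {
      attempt <- attempt + 1L
      rep_out <- run_repetition(data, p = p,
                                generalization = generalization,
                                outcome = outcome, treatment = treatment,
                                covariates = covariates,
                                learners = learners, folds = folds,
                                seed = child_seed(seed, j, 7919L * attempt),
                                allow_even_p = allow_even_p)
    }
    rows[[j]] <- data.frame(rep = j, seed = rep_out$seed,
                            status = rep_out$status,
                            reason = rep_out$reason,
                            ate_r = rep_out$ate_r, var_r = rep_out$var_r,
                            stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rows)
  agg <- aggregate_repetitions(reps)
  new_dcf_result(ate = agg$ate, var = agg$var, reps = reps, method = "dcf",
                 generalization = as.integer(generalization),
                 p = as.integer(p), r = as.integer(r), n = nrow(data),
                 seed = as.integer(seed), outcome = outcome,
                 treatment = treatment, covariates = covariates,
                 learners = learners, call = match.call())
}

# ---- S3 methods ----------------------------------------------------------

#' @export
print.dcf_tmle <- function(x, digits = 4, ...) {
  lab <- if (identical(x$method, "tmle")) "TMLE (no cross-fitting)"
         else sprintf("Double cross-fitted TMLE (generalization %d, p = %d, r = %d)",
                      x$generalization, x$p, x$r)
  cat(lab, "\n", sep = "")
  cat(sprintf("  ATE (risk difference): %.*f  SE: %.*f\n",
              digits, x$ate, digits, x$se))
  cat(sprintf("  95%% CI: [%.*f, %.*f]\n",
              digits, x$ci95[1], digits, x$ci95[2]))
  if (x$n_failed > 0)
    cat(sprintf("  repetitions: %d successful, %d failed\n",
                x$n_success, x$n_failed))
  invisible(x)
}

#' @export
summary.dcf_tmle <- function(object, ...) {
  ok <- object$reps[object$reps$status == "success", , drop = FALSE]
  out <- list(fit = object,
              rep_quartiles = if (nrow(ok))
                stats::quantile(ok$ate_r, c(0.25, 0.5, 0.75)) else NULL)
  class(out) <- "summary.dcf_tmle"
  out
}

#' @export
print.summary.dcf_tmle <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$rep_quartiles) && x$fit$r > 1) {
    cat("  per-repetition estimate quartiles:\n")
    print(round(x$rep_quartiles, 4))
  }
  invisible(x)
}

#' @export
coef.dcf_tmle <- function(object, ...) c(ATE = object$ate)

#' @export
vcov.dcf_tmle <- function(object, ...) {
  matrix(object$var, 1, 1, dimnames = list("ATE", "ATE"))
}

#' @export
confint.dcf_tmle <- function(object, parm = "ATE", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$ate - z * object$se, object$ate + z * object$se),
              nrow = 1,
              dimnames = list("ATE", sprintf("%.1f %%",
                                             c((1 - level) / 2,
                                               1 - (1 - level) / 2) * 100)))
  m
}

#' Plot per-repetition estimates of a DCF TMLE fit
#'
#' Dot plot of the successful repetitions' estimates in repetition order,
#' with the overall median and its 95% confidence band.
#'
#' @param x A `"dcf_tmle"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dcf_tmle <- function(x, ...) {
  ok <- x$reps[x$reps$status == "success", , drop = FALSE]
  graphics::plot(ok$rep, ok$ate_r, pch = 19, cex = 0.6,
                 xlab = "repetition", ylab = "repetition estimate",
                 main = "Per-repetition DCF TMLE estimates", ...)
  graphics::abline(h = x$ate, lwd = 2)
  graphics::abline(h = x$ci95, lty = 2)
  invisible(x)
}
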