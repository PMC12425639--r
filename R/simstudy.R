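# Monte Carlo harness and simulation performance measures.

#' Define a simulation scenario
#'
#' Bundles and validates everything one Monte Carlo scenario needs: sample
#' size, split counts, generalization, repetitions, number of simulated
#' datasets, the learner roster and the estimators to run.
#'
#' @param n Sample size of each simulated dataset.
#' @param p Integer vector of split counts to run (each >= 3).
#' @param generalization 1 or 2.
#' @param r Repetitions per DCF fit.
#' @param n_sims Number of simulated datasets (the convention in this
#'   literature is 2000; desk-scale runs use far fewer).
#' @param seed Root seed; dataset `i` is generated and analysed under a
#'   child seed derived from `(seed, i)`.
#' @param learners Learner roster for the nuisance super learners.
#' @param estimators Subset of `c("dcf", "tmle")` (`"tmle"` is the
#'   non-cross-fit comparator).
#' @param folds Super-learner CV folds.
#' @return A validated list of class `"scenario_config"`.
#' @export
scenario_config <- function(n = 3000L, p = 3L, generalization = 1L,
                            r = 100L, n_sims = 2000L, seed = 1L,
                            learners = default_learners(),
                            estimators = "dcf", folds = 10L) {
  if (n_sims < 1) stop("`n_sims` must be a positive integer", call. = FALSE)
  if (any(p < 3)) stop("all split counts must be >= 3", call. = FALSE)
  if (!generalization %in% c(1, 2))
    stop("`generalization` must be 1 or 2", call. = FALSE)
  if (r < 1 || n < 1) stop("`r` and `n` must be positive", call. = FALSE)
  bad <- setdiff(estimators, c("dcf", "tmle"))
  if (length(bad))
    stop("unknown estimator(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(n = as.integer(n), p = as.integer(p),
                 generalization = as.integer(generalization),
                 r = as.integer(r), n_sims = as.integer(n_sims),
                 seed = as.integer(seed), learners = learners,
                 estimators = estimators, folds = as.integer(folds)),
            class = "scenario_config")
}

#' Read a scenario configuration from a YAML file
#'
#' Keys are the arguments of [scenario_config()].
#'
#' @param path Path to a YAML file.
#' @return A `"scenario_config"`.
#' @export
read_scenario <- function(path) {
  # keep boolean-looking scalars (notably the key "n") verbatim
  keep <- function(x) x
  cfg <- yaml::read_yaml(path, handlers = list("bool#no" = keep,
                                               "bool#yes" = keep))
  known <- names(formals(scenario_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(scenario_config, cfg)
}

scenario_method_label <- function(estimator, generalization, p) {
  if (estimator == "tmle") "tmle"
  else sprintf("dcf_g%d_p%d", generalization, p)
}

#' Run a Monte Carlo scenario
#'
#' Simulates `n_sims` datasets from the cardiovascular mechanism
#' ([generate_dataset()]) and runs every configured estimator on each,
#' collecting one row per dataset x estimator with the point estimate,
#' model SE, confidence limits and repetition failure counts. Datasets on
#' which every repetition fails yield a flagged row, not an error.
#'
#' If `output` is given, completed rows are appended to that CSV as the
#' run progresses and are skipped on re-runs, so an interrupted scenario
#' resumes where it stopped and a finished one is a no-op.
#'
#' @param cfg A `"scenario_config"`.
#' @param output Optional CSV path enabling incremental/resumable output.
#' @param verbose Print one line per dataset.
#' @return Data frame with columns `sim`, `method`, `status`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `n_success`, `n_failed`.
#' @export
run_scenario <- function(cfg, output = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  methods <- unlist(lapply(cfg$estimators, function(es) {
    if (es == "tmle") "tmle"
    else vapply(cfg$p, function(pp)
      scenario_method_label("dcf", cfg$generalization, pp), character(1))
  }))
  done <- NULL
  if (!is.null(output) && file.exists(output)) {
    done <- utils::read.csv(output, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(cfg$n_sims)) {
    data_seed <- child_seed(cfg$seed, i, 1)
    est_seed <- child_seed(cfg$seed, i, 2)
    d <- NULL
    for (m in methods) {
      if (!is.null(done) &&
          any(done$sim == i & done$method == m)) {
        rows[[length(rows) + 1L]] <-
          done[done$sim == i & done$method == m, , drop = FALSE]
        next
      }
      if (is.null(d)) d <- generate_dataset(cfg$n, data_seed)
      row <- tryCatch({
        fit <- if (m == "tmle") {
          tmle_no_crossfit(d, learners = cfg$learners, folds = cfg$folds,
                           seed = est_seed)
        } else {
          pp <- as.integer(sub(".*_p", "", m))
          dcf_tmle(d, p = pp, r = cfg$r,
                   generalization = cfg$generalization,
                   learners = cfg$learners, folds = cfg$folds,
                   seed = est_seed)
        }
        data.frame(sim = i, method = m, status = "ok",
                   estimate = fit$ate, se = fit$se,
                   ci_low = fit$ci95[1], ci_high = fit$ci95[2],
                   n_success = fit$n_success, n_failed = fit$n_failed,
                   stringsAsFactors = FALSE)
      }, dcftmle_all_failed = function(e) {
        data.frame(sim = i, method = m, status = "failed",
                   estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, n_success = 0L,
                   n_failed = if (m == "tmle") 1L else cfg$r,
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
      if (!is.null(output)) {
        new_file <- !file.exists(output)
        utils::write.table(row, output, sep = ",", row.names = FALSE,
                           col.names = new_file, append = !new_file,
                           qmethod = "double")
      }
    }
    if (verbose) message("dataset ", i, "/", cfg$n_sims, " done")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sim, match(out$method, methods)), , drop = FALSE]
}

#' Simulation performance measures
#'
#' Computes the standard simulation-study metrics for each estimator in a
#' raw estimates table: bias, empirical SE (SD of the estimates), average
#' model SE, relative % error in the model SE, MSE, coverage of the 95%
#' intervals, bias-eliminated coverage (coverage of the mean estimate
#' rather than the truth), and the Monte Carlo SE of each. The average
#' model SE is `sqrt(mean(se^2))`; the arithmetic mean of the SEs is
#' reported alongside as `avg_model_se_mean`. Rows flagged as failed are
#' excluded, with their count reported.
#'
#' @param raw Data frame from [run_scenario()] (columns `method`,
#'   `status`, `estimate`, `se`, `ci_low`, `ci_high`).
#' @param psi True value of the estimand.
#' @return Data frame with one row per estimator.
#' @examples
#' raw <- data.frame(method = "toy", status = "ok",
#'                   estimate = c(0.08, 0.10, 0.12, 0.14),
#'                   se = 0.02, ci_low = c(0.08, 0.10, 0.12, 0.14) - 0.0392,
#'                   ci_high = c(0.08, 0.10, 0.12, 0.14) + 0.0392)
#' performance(raw, psi = 0.10)
#' @export
performance <- function(raw, psi) {
  stopifnot(is.numeric(psi), length(psi) == 1L)
  out <- lapply(split(raw, raw$method), function(g) {
    ok <- g[g$status == "ok" & is.finite(g$estimate), , drop = FALSE]
    S <- nrow(ok)
    if (S < 2) stop("need at least 2 complete rows per estimator",
                    call. = FALSE)
    est <- ok$estimate
    se <- ok$se
    bias <- mean(est) - psi
    empse <- stats::sd(est)
    modse <- sqrt(mean(se^2))
    mcse_modse <- sqrt(stats::var(se^2) / (4 * S * modse^2))
    degen <- empse == 0
    relerr <- if (degen) NA_real_ else 100 * (modse / empse - 1)
    mcse_relerr <- if (degen) NA_real_ else
      100 * (modse / empse) *
        sqrt(mcse_modse^2 / modse^2 + 1 / (2 * (S - 1)))
    mse <- mean((est - psi)^2)
    cover <- mean(ok$ci_low <= psi & psi <= ok$ci_high)
    becover <- mean(ok$ci_low <= mean(est) & mean(est) <= ok$ci_high)
    data.frame(
      method = g$method[1], n_used = S,
      n_flagged = sum(g$status != "ok" | !is.finite(g$estimate)),
      bias = bias, mcse_bias = empse / sqrt(S),
      empirical_se = empse, mcse_empirical_se = empse / sqrt(2 * (S - 1)),
      avg_model_se = modse, mcse_avg_model_se = mcse_modse,
      avg_model_se_mean = mean(se),
      relative_se_error_pct = relerr,
      mcse_relative_se_error_pct = mcse_relerr,
      mse = mse, mcse_mse = sqrt(stats::var((est - psi)^2) / S),
      coverage = cover, mcse_coverage = sqrt(cover * (1 - cover) / S),
      bias_eliminated_coverage = becover,
      mcse_bias_eliminated_coverage = sqrt(becover * (1 - becover) / S),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Zip-plot data: confidence intervals ranked by |z|
#'
#' For each estimator, centers every dataset's interval on the truth,
#' computes the standardised deviate `z = (estimate - psi)/se`, and ranks
#' datasets by `|z|` (fractional rank in (0, 1]). Plotting the intervals
#' against the rank gives the usual zip plot; the data are returned rather
#' than drawn so the core stays headless.
#'
#' @inheritParams performance
#' @return Data frame with columns `method`, `sim`, `rank_pct`, `z`,
#'   `ci_low`, `ci_high`, `covers`.
#' @export
zip_data <- function(raw, psi) {
  out <- lapply(split(raw, raw$method), function(g) {
    ok <- g[g$status == "ok" & is.finite(g$estimate), , drop = FALSE]
    z <- (ok$estimate - psi) / ok$se
    ord <- order(abs(z))
    data.frame(method = ok$method[ord], sim = ok$sim[ord],
               rank_pct = seq_along(ord) / length(ord),
               z = z[ord], ci_low = ok$ci_low[ord],
               ci_high = ok$ci_high[ord],
               covers = ok$ci_low[ord] <= psi & psi <= ok$ci_high[ord],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
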