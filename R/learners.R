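# Candidate learners and the cross-validated super learner.

# Condition raised when an outcome vector is degenerate (or no candidate can
# be fitted); callers treat the enclosing repetition as failed.
degenerate_outcome <- function(msg) {
  stop(structure(class = c("dcftmle_degenerate_outcome", "dcftmle_failure",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' The default candidate learner roster
#'
#' Names the six candidate algorithms used for both nuisance models:
#' main-effects logistic regression, generalized additive models with
#' basis dimension 4 and 6 per continuous covariate, a single-hidden-layer
#' neural network with 2 units, a 500-tree random forest with minimum
#' terminal-node size 20, and the empirical mean.
#'
#' @return Character vector of learner names.
#' @export
default_learners <- function() {
  c("logit_main_effects", "gam_4_splines", "gam_6_splines",
    "nnet_2_hidden", "random_forest_500_minleaf20", "empirical_mean")
}

# Columns treated as continuous get smooth terms in the GAMs; binary or
# few-valued columns enter linearly.
is_continuous <- function(x) is.numeric(x) && length(unique(x)) > 10L

clip01 <- function(p, lo = 1e-6, hi = 1 - 1e-6) pmin(pmax(p, lo), hi)

# Each constructor returns list(fit = function(X, y, seed) model,
#                               predict = function(model, X) probabilities).
learner_spec <- function(name) {
  switch(name,
    logit_main_effects = list(
      fit = function(X, y, seed) {
        # separation warnings are routine in small training splits; the
        # resulting boundary predictions are truncated downstream
        suppressWarnings(
          stats::glm.fit(cbind(1, as.matrix(X)), y,
                         family = stats::binomial()))
      },
      predict = function(m, X) {
        # aliased (rank-deficient) columns contribute nothing
        b <- m$coefficients
        b[is.na(b)] <- 0
        as.vector(stats::plogis(cbind(1, as.matrix(X)) %*% b))
      }),
    gam_4_splines = gam_spec(k = 4L),
    gam_6_splines = gam_spec(k = 6L),
    nnet_2_hidden = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        nnet::nnet(x = as.matrix(X), y = y, size = 2L, decay = 1e-4,
                   maxit = 500L, entropy = TRUE, trace = FALSE)
      },
      predict = function(m, X) as.vector(stats::predict(m, as.matrix(X)))),
    random_forest_500_minleaf20 = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                   ntree = 500L, nodesize = 20L)
      },
      predict = function(m, X) {
        unname(stats::predict(m, X, type = "prob")[, "1"])
      }),
    empirical_mean = list(
      fit = function(X, y, seed) mean(y),
      predict = function(m, X) rep(m, nrow(X))),
    stop("unknown learner: ", name, call. = FALSE)
  )
}

gam_spec <- function(k) {
  list(
    fit = function(X, y, seed) {
      smooth <- vapply(X, is_continuous, logical(1))
      terms <- c(
        if (any(smooth)) sprintf("s(%s, k = %d)", names(X)[smooth], k),
        if (any(!smooth)) names(X)[!smooth])
      fm <- stats::reformulate(terms, response = "..y")
      dd <- cbind(X, ..y = y)
      mgcv::gam(fm, family = stats::binomial(), data = dd, method = "REML")
    },
    predict = function(m, X) {
      as.vector(stats::predict(m, newdata = X, type = "response"))
    })
}

# Stratified fold assignment: folds balanced within each outcome class.
# Consumes RNG.
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

cv_neg_loglik <- function(p, y) -mean(y * log(p) + (1 - y) * log(1 - p))

# Minimise CV negative Bernoulli log-likelihood over the weight simplex.
# Nonnegative parametrisation w = x / sum(x) solved by L-BFGS-B from the
# uniform start and from every vertex; vertices themselves are also
# candidates, so the optimum is never worse than any single learner.
solve_simplex_weights <- function(Z, y) {
  K <- ncol(Z)
  risk_w <- function(w) cv_neg_loglik(clip01(as.vector(Z %*% w)), y)
  if (K == 1L) return(list(weights = 1, risk = risk_w(1)))
  obj <- function(x) {
    s <- sum(x)
    if (s < 1e-10) return(cv_neg_loglik(clip01(rowMeans(Z)), y))
    risk_w(x / s)
  }
  starts <- c(list(rep(1, K)), lapply(seq_len(K), function(j) {
    x <- rep(1e-4, K); x[j] <- 1; x
  }))
  best <- NULL
  for (x0 in starts) {
    op <- tryCatch(
      stats::optim(x0, obj, method = "L-BFGS-B", lower = 0, upper = 1e3,
                   control = list(maxit = 200L, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  w <- best$par / sum(best$par)
  # a pure vertex may still beat the interior optimum numerically
  vrisk <- vapply(seq_len(K), function(j) {
    e <- numeric(K); e[j] <- 1; risk_w(e)
  }, numeric(1))
  if (min(vrisk) < best$value) {
    w <- numeric(K); w[which.min(vrisk)] <- 1
    return(list(weights = w, risk = min(vrisk)))
  }
  list(weights = w, risk = best$value)
}

#' Fit a cross-validated super learner for a binary outcome
#'
#' Stacks the candidate learners by V-fold cross-validation: each
#' candidate's out-of-fold predictions are combined with simplex-constrained
#' weights minimising the cross-validated negative Bernoulli log-likelihood,
#' then every candidate is refit on the full training set. Candidates that
#' fail to fit (on any fold or on the full data) are dropped with a warning;
#' if the outcome is constant, or every candidate fails, a degenerate-outcome
#' error is raised so the caller can mark the repetition as failed.
#'
#' @param X Covariate data frame (numeric or binary columns).
#' @param y Binary 0/1 outcome vector, `length(y) == nrow(X)`.
#' @param library Character vector of learner names (see
#'   [default_learners()]).
#' @param folds Number of cross-validation folds (default 10); folds are
#'   stratified on `y`.
#' @param seed Integer seed controlling fold assignment and the stochastic
#'   learners.
#' @return An object of class `"super_learner"` with elements `weights`
#'   (named, nonnegative, summing to 1), `fits` (full-data candidate fits),
#'   `cv_risk` (CV risk of the ensemble), `candidate_risks`,
#'   `cv_predictions` (matrix of out-of-fold candidate predictions),
#'   `fold_assignment` and `columns`.
#' @examples
#' d <- generate_simple_dataset(200, seed = 1, effect = 0.1)
#' sl <- fit_super_learner(d["W"], d$Y,
#'                         library = c("logit_main_effects", "empirical_mean"),
#'                         seed = 2)
#' sl$weights
#' @export
fit_super_learner <- function(X, y, library = default_learners(),
                              folds = 10L, seed = 1L) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  if (!all(y %in% c(0, 1)))
    stop("`y` must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    degenerate_outcome("outcome is constant in the training records")
  if (nrow(X) < folds)
    stop("fewer records than cross-validation folds", call. = FALSE)
  if (!length(library)) stop("empty learner library", call. = FALSE)

  specs <- lapply(library, learner_spec)
  names(specs) <- library
  K <- length(specs)

  if (K == 1L) {
    # trivial simplex: skip cross-validation entirely
    fit <- tryCatch(specs[[1]]$fit(X, y, child_seed(seed, 1, 1)),
                    error = function(e) degenerate_outcome(conditionMessage(e)))
    return(structure(list(
      weights = stats::setNames(1, library), library = library,
      fits = stats::setNames(list(fit), library), specs = specs,
      cv_risk = NA_real_, candidate_risks = stats::setNames(NA_real_, library),
      cv_predictions = NULL, fold_assignment = NULL,
      columns = names(X), folds = folds, seed = seed),
      class = "super_learner"))
  }

  set.seed(as.integer(seed))
  fold <- stratified_folds(y, folds)
  Z <- matrix(NA_real_, nrow(X), K, dimnames = list(NULL, library))
  ok <- rep(TRUE, K)
  for (j in seq_len(K)) {
    for (v in seq_len(folds)) {
      out <- tryCatch({
        m <- specs[[j]]$fit(X[fold != v, , drop = FALSE], y[fold != v],
                            child_seed(seed, j, v))
        specs[[j]]$predict(m, X[fold == v, , drop = FALSE])
      }, error = function(e) NULL)
      if (is.null(out) || anyNA(out)) { ok[j] <- FALSE; break }
      Z[fold == v, j] <- out
    }
  }
  full <- vector("list", K)
  for (j in seq_len(K)) {
    if (!ok[j]) next
    full[[j]] <- tryCatch(specs[[j]]$fit(X, y, child_seed(seed, j, 0)),
                          error = function(e) NULL)
    if (is.null(full[[j]])) ok[j] <- FALSE
  }
  if (!any(ok))
    degenerate_outcome("all candidate learners failed to fit")
  if (any(!ok))
    warning("dropped failed learner(s): ",
            paste(library[!ok], collapse = ", "), call. = FALSE)

  Zok <- clip01(Z[, ok, drop = FALSE])
  sol <- solve_simplex_weights(Zok, y)
  cand <- vapply(seq_len(ncol(Zok)),
                 function(j) cv_neg_loglik(Zok[, j], y), numeric(1))
  structure(list(
    weights = stats::setNames(sol$weights, library[ok]),
    library = library[ok],
    fits = stats::setNames(full[ok], library[ok]),
    specs = specs[ok],
    cv_risk = sol$risk,
    candidate_risks = stats::setNames(cand, library[ok]),
    cv_predictions = Zok,
    fold_assignment = fold,
    columns = names(X), folds = folds, seed = seed),
    class = "super_learner")
}

#' Predict event probabilities from a super learner fit
#'
#' The weighted average of the candidate predictions, truncated to
#' `trunc` to keep downstream logit transforms finite.
#'
#' @param object A `"super_learner"` fit.
#' @param newdata Data frame containing the training columns.
#' @param trunc Length-2 numeric bounds applied to the ensemble prediction.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.super_learner <- function(object, newdata,
                                  trunc = c(0.0005, 0.9995), ...) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$columns, names(newdata))
  if (length(missing_cols))
    stop("newdata lacks training column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  newdata <- newdata[object$columns]
  P <- vapply(object$library, function(nm) {
    clip01(object$specs[[nm]]$predict(object$fits[[nm]], newdata))
  }, numeric(nrow(newdata)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  p <- as.vector(P %*% object$weights)
  pmin(pmax(p, trunc[1]), trunc[2])
}

#' @export
print.super_learner <- function(x, ...) {
  cat("Super learner fit (", x$folds, "-fold CV, n = ",
      if (is.null(x$fold_assignment)) "?" else length(x$fold_assignment),
      ")\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}
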