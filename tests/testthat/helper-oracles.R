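# Shared fixtures and independent oracles.

# Single-candidate roster used wherever learner flexibility is not the
# property under test; the super learner then collapses to weight 1.
FAST <- "logit_main_effects"

# Independent one-parameter fluctuation oracle: direct Newton iterations on
# the offset logistic log-likelihood (kept independent of the package's
# glm-based targeting path).
newton_fluctuation <- function(y, a, g, q0, q1,
                               g_bounds = c(0.01, 0.99),
                               q_bounds = c(0.0005, 0.9995)) {
  g <- pmin(pmax(g, g_bounds[1]), g_bounds[2])
  q0 <- pmin(pmax(q0, q_bounds[1]), q_bounds[2])
  q1 <- pmin(pmax(q1, q_bounds[1]), q_bounds[2])
  H <- a / g - (1 - a) / (1 - g)
  off <- qlogis(ifelse(a == 1, q1, q0))
  eps <- 0
  for (it in 1:200) {
    p <- plogis(off + eps * H)
    step <- sum(H * (y - p)) / sum(H^2 * p * (1 - p))
    eps <- eps + step
    if (abs(step) < 1e-14) break
  }
  q1s <- plogis(qlogis(q1) + eps / g)
  q0s <- plogis(qlogis(q0) - eps / (1 - g))
  list(ate = mean(q1s - q0s), eps = eps)
}

# Random bounded nuisance fixtures for targeting tests.
random_tmle_fixture <- function(n, seed) {
  set.seed(seed)
  list(y = rbinom(n, 1, 0.4), a = rbinom(n, 1, 0.5),
       g = runif(n, 0.1, 0.9), q0 = runif(n, 0.05, 0.95),
       q1 = runif(n, 0.05, 0.95))
}

# True nuisance functions of the simple single-covariate mechanism.
simple_truth <- function(d, effect = 0.10) {
  pars <- dcftmle:::simple_dgm_pars()
  theta <- dcftmle:::simple_dgm_theta(effect)
  list(g = plogis(pars$a0 + pars$a1 * d$W),
       q0 = plogis(pars$b0 + pars$b1 * d$W),
       q1 = plogis(pars$b0 + pars$b1 * d$W + theta))
}
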