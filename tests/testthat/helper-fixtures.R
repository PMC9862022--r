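# Small shared fixtures for the test suite. Everything is generated in code;
# no binary data.

# a compact cohort config used by several integration-style tests
small_config <- function(seed = 1, ...) {
  cohort_config(n_normal = 30, n_gp = 50, n_pp = 30, n_genes = 300,
                seed = seed, ...)
}

empty_de_spec <- function() {
  tibble::tibble(gene = character(), set = character(), log2fc = numeric())
}

empty_hazard_spec <- function() {
  tibble::tibble(gene = character(), coef = numeric())
}

# independent Benjamini-Hochberg step-up oracle, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# independent bisection oracle for the intersection of two weighted normal
# densities on (mu1, mu2)
intersection_oracle <- function(w1, mu1, s1, w2, mu2, s2, tol = 1e-10) {
  f <- function(x) w1 * dnorm(x, mu1, s1) - w2 * dnorm(x, mu2, s2)
  lo <- mu1
  hi <- mu2
  if (sign(f(lo)) == sign(f(hi))) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force two-sided Fisher p: enumerate all tables with the observed
# margins and sum the probabilities not exceeding that of the observed table
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random right-censored survival dataset
random_survival_data <- function(n, seed) {
  withr::with_seed(seed, {
    t_death <- rexp(n, rate = runif(1, 0.05, 0.5))
    t_cens <- rexp(n, rate = runif(1, 0.05, 0.5))
    list(times = pmin(t_death, t_cens), events = t_death <= t_cens)
  })
}
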