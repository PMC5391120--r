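# Independent oracles used to cross-check the package implementations.

# Textbook Ledoit-Wolf estimator, written as plain loops over the 2004
# paper's quantities; deliberately naive and separate from the package path.
lw_oracle <- function(x) {
  n <- nrow(x)
  d <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  s <- matrix(0, d, d)
  for (i in seq_len(n)) s <- s + tcrossprod(xc[i, ])
  s <- s / n
  m <- sum(diag(s)) / d
  d2 <- sum((s - m * diag(d))^2) / d
  b2bar <- 0
  for (i in seq_len(n)) {
    b2bar <- b2bar + sum((tcrossprod(xc[i, ]) - s)^2) / d
  }
  b2bar <- b2bar / n^2
  b2 <- min(b2bar, d2)
  gamma <- if (d2 > 0) b2 / d2 else 0
  list(sigma = (1 - gamma) * s + gamma * m * diag(d), gamma = gamma)
}

# Brute-force pairwise AUC with the ties-count-half convention.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == "target"]
  neg <- scores[labels != "target"]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Gaussian feature epochs with explicit labels (no group structure needed).
labelled_gaussian_epochs <- function(n, mu_t, mu_n, sd = 1, seed = NULL,
                                     p_target = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(mu_t)
  lab <- ifelse(stats::runif(n) < p_target, "target", "nontarget")
  mu <- matrix(mu_n, n, d, byrow = TRUE)
  mu[lab == "target", ] <- matrix(mu_t, sum(lab == "target"), d, byrow = TRUE)
  epoch_set(mu + matrix(stats::rnorm(n * d, sd = sd), n, d),
    group = rep("g1", n), label = lab
  )
}

# Schedules + attended symbols for a short simulated spelling run.
make_study_run <- function(n_chars, grid = speller_grid(), seed = 1) {
  set.seed(seed)
  schedules <- lapply(seq_len(n_chars), function(t) {
    generate_trial(grid, trial_id = t)
  })
  attended <- sample(which(!grid$blank), n_chars, replace = TRUE)
  list(schedules = schedules, attended = attended)
}
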