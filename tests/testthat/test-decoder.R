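test_that("shrinkage covariance matches an independent Ledoit-Wolf oracle", {
  set.seed(41)
  x <- matrix(rnorm(18), 6, 3)
  fit <- shrinkage_covariance(x)
  ora <- lw_oracle(x)
  expect_equal(fit$sigma, ora$sigma, tolerance = 1e-8)
  expect_equal(fit$gamma, ora$gamma, tolerance = 1e-8)
})

test_that("shrinkage intensity adapts to the sampling regime", {
  set.seed(42)
  # N >> D, spherical truth: estimate close to the true identity
  x <- matrix(rnorm(50000 * 5), 50000, 5)
  fit <- shrinkage_covariance(x)
  expect_lt(max(abs(fit$sigma - diag(5))), 0.1)
  # N >> D, anisotropic truth far from the spherical target: intensity
  # vanishes and the sample covariance is kept
  a <- sqrt(c(5, 2, 1, 0.5, 0.1))
  xa <- sweep(matrix(rnorm(50000 * 5), 50000, 5), 2, a, `*`)
  fita <- shrinkage_covariance(xa)
  expect_lt(fita$gamma, 0.05)
  expect_lt(max(abs(fita$sigma - diag(a^2))), 0.15)
  # N = 2 << D = 100: degenerate dispersion forces full shrinkage,
  # output still positive-definite
  y <- matrix(rnorm(200), 2, 100)
  fit2 <- shrinkage_covariance(y)
  expect_gt(fit2$gamma, 0.9)
  expect_true(all(eigen(fit2$sigma, symmetric = TRUE,
    only.values = TRUE
  )$values > 0))
  expect_error(shrinkage_covariance(y[1, , drop = FALSE]), "at least 2")
  y[1, 1] <- NA
  expect_error(shrinkage_covariance(y), "non-finite")
})

test_that("LLP training recovers the supervised direction without labels", {
  mix <- study_mixing()
  # exact group means: weights proportional to Sigma^-1 (mu+ - mu-) = (1, -1)
  gm <- unclass(mix) %*% rbind(c(1, 0), c(0, 1))
  cm <- reconstruct_class_means(gm, mix)
  expect_equal(cm$target, c(1, 0), tolerance = 1e-10)

  set.seed(77)
  ep <- sample_feature_epochs(
    mix, c(10000, 10000),
    list(target = c(1, 0, 0.5), nontarget = c(0, 1, -0.5))
  )
  m_llp <- train_llp(ep, mix)
  m_sup <- train_supervised(ep)
  cosine <- sum(m_llp$weights * m_sup$weights) /
    sqrt(sum(m_llp$weights^2) * sum(m_sup$weights^2))
  expect_gt(cosine, 0.95)
  expect_false(m_llp$supervised)
  expect_true(m_sup$supervised)

  # Eq-12 self-consistency: Sigma w = mu+ - mu-
  for (m in list(m_llp, m_sup)) {
    delta <- m$class_means$target - m$class_means$nontarget
    expect_equal(drop(m$covariance %*% m$weights), delta,
      tolerance = 1e-8 * max(abs(delta))
    )
  }
})

test_that("LLP never reads labels and improves with more trials", {
  grid <- speller_grid()
  run <- make_study_run(12, grid, seed = 9)
  mu_t <- c(rep(2, 3), rep(0, 7))
  mu_n <- rep(0, 10)
  ep <- simulate_study_epochs(run$schedules, run$attended, grid,
    list(target = mu_t, nontarget = mu_n),
    seed = 101
  )
  mix <- study_mixing()
  shuffled <- ep
  shuffled$label <- sample(shuffled$label)
  m1 <- train_llp(ep, mix)
  m2 <- train_llp(shuffled, mix)
  expect_identical(m1$weights, m2$weights)

  # held-out AUC grows from 1 training trial to all 12
  test_ep <- simulate_study_epochs(run$schedules, run$attended, grid,
    list(target = mu_t, nontarget = mu_n),
    seed = 202
  )
  small <- train_llp(ep[ep$trial == 1], mix)
  auc_small <- auc(score_epochs(small, test_ep), test_ep$label)
  auc_big <- auc(score_epochs(m1, test_ep), test_ep$label)
  expect_gt(auc_big, auc_small)
})

test_that("supervised training matches the Bayes direction and edge cases", {
  set.seed(5)
  n <- 10000
  mu_t <- c(2, 0)
  mu_n <- c(0, 1)
  ep <- labelled_gaussian_epochs(n, mu_t, mu_n)
  fit <- train_supervised(ep)
  bayes <- solve(diag(2), mu_t - mu_n)
  angle <- acos(sum(fit$weights * bayes) /
    sqrt(sum(fit$weights^2) * sum(bayes^2))) * 180 / pi
  expect_lt(angle, 5)

  # identical class means: zero weight vector
  ep0 <- epoch_set(rbind(c(1, 2), c(1, 2), c(3, 0), c(3, 0)),
    group = rep("g", 4),
    label = c("target", "nontarget", "target", "nontarget")
  )
  expect_equal(train_supervised(ep0)$weights, c(0, 0))

  ep1 <- epoch_set(matrix(rnorm(10), 5, 2),
    group = rep("g", 5),
    label = rep("target", 5)
  )
  expect_error(train_supervised(ep1), "both classes")
  # unweighted pooling is accepted and yields a valid model
  fit_u <- train_supervised(ep, pooling = "unweighted")
  expect_length(fit_u$weights, 2)
})

test_that("epoch scoring is the plain linear functional", {
  m <- structure(
    list(
      weights = c(1, 1),
      class_means = list(target = c(1, 1), nontarget = c(0, 0)),
      covariance = diag(2), shrinkage = 0, n_epochs_trained = 0,
      supervised = FALSE
    ),
    class = "llp_model"
  )
  expect_equal(score_epochs(m, matrix(c(2, 3), 1, 2)), 5)
  # invariance to shifts orthogonal to w
  x <- matrix(rnorm(20), 10, 2)
  shift <- matrix(c(1, -1), 10, 2, byrow = TRUE) # orthogonal to (1, 1)
  expect_equal(score_epochs(m, x + shift), score_epochs(m, x))
  expect_error(score_epochs(m, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("AUC follows the Mann-Whitney convention", {
  expect_equal(auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  sc <- c(0.1, 0.4, 0.35, 0.8)
  lb <- c("nontarget", "nontarget", "target", "target")
  expect_equal(auc(sc, lb), auc_brute(sc, lb))
  expect_equal(auc(sc, lb), 0.75)
  # ties count one half
  expect_equal(auc(c(1, 1), c(TRUE, FALSE)), 0.5)
  # chance level on independent labels
  set.seed(13)
  s <- rnorm(10000)
  l <- runif(10000) < 0.5
  expect_equal(auc(s, l), 0.5, tolerance = 0.02)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both")

  # rank-based implementation equals the brute-force pairwise oracle,
  # including ties
  set.seed(14)
  for (k in 1:10) {
    s <- sample(seq(0, 1, by = 0.25), 30, replace = TRUE)
    l <- ifelse(runif(30) < 0.4, "target", "nontarget")
    if (length(unique(l)) < 2) next
    expect_equal(auc(s, l), auc_brute(s, l), tolerance = 1e-12)
  }
})

test_that("symbol selection sums scores, excludes blanks, breaks ties low", {
  grid <- speller_grid()
  # symbol 1 appears in epochs 1 and 2 (sum 2), symbol 2 in 1 and 3 (sum 0)
  hl <- list(c(1L, 2L), 1L, 2L)
  expect_equal(select_symbol(c(1, 1, -1), hl, grid), 1L)
  # constant offsets cancel when symbols are highlighted equally often
  tr <- generate_trial(grid, seed = 21)
  hl_tr <- lapply(tr$events, `[[`, "highlighted")
  sc <- rnorm(68)
  expect_equal(
    select_symbol(sc, hl_tr, grid),
    select_symbol(sc + 5, hl_tr, grid)
  )
  # positive scaling never changes the winner
  expect_equal(
    select_symbol(sc, hl_tr, grid),
    select_symbol(3.7 * sc, hl_tr, grid)
  )
  # a blank with the top sum is never selected
  blank <- which(grid$blank)[1]
  hl_blank <- list(blank, 3L)
  expect_equal(select_symbol(c(100, 1), hl_blank, grid), 3L)
  # exact tie between symbols 4 and 2 resolves to the lowest index
  expect_equal(select_symbol(c(1, 1), list(4L, 2L), grid), 2L)
  expect_error(select_symbol(numeric(0), list(), grid), "non-empty")
})

test_that("model serialization round-trips bit-exactly", {
  set.seed(99)
  ep <- labelled_gaussian_epochs(200, c(1, 0, 0), c(0, 1, 0))
  m <- train_supervised(ep)
  path <- withr::local_tempfile(fileext = ".json")
  write_llp_model(m, path)
  m2 <- read_llp_model(path)
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$covariance, unname(m$covariance))
  expect_identical(m2$class_means$target, unname(m$class_means$target))
  expect_equal(m2$shrinkage, m$shrinkage)
  expect_equal(m2$n_epochs_trained, m$n_epochs_trained)
})
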