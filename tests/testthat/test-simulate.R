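test_that("default templates carry the intended ERP morphology", {
  tpl <- erp_templates()
  occ <- which(tpl$roles == "occipital")[1]
  cen <- which(tpl$roles == "central")[1]
  t_ms <- seq(0, 700, by = 1000 / tpl$rate)
  p_occ <- peak_statistics(
    tpl$target[occ, , drop = FALSE],
    t_ms, tpl$channels[occ], c(100, 200),
    mode = "min"
  )
  expect_equal(p_occ$amplitude, -8, tolerance = 1e-6)
  expect_equal(p_occ$latency, 150, tolerance = 1)
  p_cen <- peak_statistics(
    tpl$target[cen, , drop = FALSE],
    t_ms, tpl$channels[cen], c(250, 500),
    mode = "max"
  )
  expect_equal(p_cen$amplitude, 2, tolerance = 1e-6)
  expect_equal(p_cen$latency, 400, tolerance = 1)
  # non-target response stays below 30% of the target on those channels
  expect_true(all(abs(tpl$nontarget[c(occ, cen), ]) <=
    0.3 * max(abs(tpl$target[c(occ, cen), ]))))
  expect_error(erp_templates(nontarget_scale = 0.5), "nontarget_scale")
})

test_that("continuous synthesis is deterministic and respects snr = 0", {
  grid <- speller_grid()
  run <- make_study_run(2, grid, seed = 3)
  params <- simulation_params(snr = 2)
  sim1 <- simulate_recording(params, run$schedules, run$attended, grid,
    seed = 9
  )
  sim2 <- simulate_recording(params, run$schedules, run$attended, grid,
    seed = 9
  )
  expect_identical(sim1$recording$samples, sim2$recording$samples)
  expect_identical(sim1$labels, sim2$labels)
  expect_length(sim1$labels, 136)
  expect_equal(sum(sim1$labels == "target"), 32) # 16 per trial
  # onset spacing equals the SOA within each trial
  d <- diff(sim1$recording$onsets[1:68])
  expect_true(all(d == 250))

  # with snr = 0 the evoked signal vanishes: supervised decoding is at
  # chance on an epoch set of this recording
  sim0 <- simulate_recording(
    simulation_params(snr = 0), run$schedules, run$attended, grid,
    seed = 10
  )
  ep0 <- build_epoch_set(sim0$recording, run$schedules, labels = sim0$labels)
  # train on trial 1, test on trial 2 (labels used only for evaluation)
  fit <- train_supervised(ep0[ep0$trial == 1])
  a <- auc(
    score_epochs(fit, ep0[ep0$trial == 2]),
    ep0$label[ep0$trial == 2]
  )
  expect_gt(a, 0.3)
  expect_lt(a, 0.7)
})

test_that("high-snr synthesis yields near-perfect supervised decoding", {
  grid <- speller_grid()
  run <- make_study_run(6, grid, seed = 4)
  params <- simulation_params(snr = 6, noise_model = "white")
  sim <- simulate_recording(params, run$schedules, run$attended, grid,
    seed = 12
  )
  ep <- build_epoch_set(sim$recording, run$schedules, labels = sim$labels)
  expect_equal(ncol(ep$features), 174)
  train <- ep[ep$trial <= 4]
  test <- ep[ep$trial > 4]
  fit <- train_supervised(train)
  expect_gt(auc(score_epochs(fit, test), test$label), 0.97)
  # the discriminative information sits in the expected interval features:
  # occipital 121-200 ms and central 381-530 ms
  delta <- colMeans(ep$features[ep$label == "target", ]) -
    colMeans(ep$features[ep$label == "nontarget", ])
  expect_gt(abs(delta[["O1_121_200"]]), abs(delta[["O1_531_700"]]))
  expect_gt(abs(delta[["Cz_381_530"]]), abs(delta[["Cz_50_120"]]))
  expect_lt(delta[["O1_121_200"]], 0)
  expect_gt(delta[["Cz_381_530"]], 0)
})

test_that("feature-level sampling follows the mixing matrix", {
  mix <- study_mixing()
  cm <- list(target = c(1, 0), nontarget = c(0, 0))
  # a pure-target group labels everything target
  pure <- mixing_matrix(rbind(c(1, 0), c(0, 1)))
  ep <- sample_feature_epochs(pure, c(50, 50), cm, seed = 1)
  expect_true(all(ep$label[ep$group == "group1"] == "target"))
  expect_true(all(ep$label[ep$group == "group2"] == "nontarget"))

  # exact-count mode: exactly 16 targets per 68-epoch trial
  for (s in 1:20) {
    ep_s <- sample_feature_epochs(mix, c(32, 36), cm,
      seed = s,
      exact_counts = TRUE
    )
    expect_equal(sum(ep_s$label == "target"), 16)
    expect_equal(sum(ep_s$label[ep_s$group == "sequence1"] == "target"), 12)
  }
  # Bernoulli mode: mean target count near 16 over many trials
  set.seed(2)
  counts <- replicate(300, {
    sum(sample_feature_epochs(mix, c(32, 36), cm)$label == "target")
  })
  expect_equal(mean(counts), 16, tolerance = 0.5)

  # class-mean reconstruction error shrinks with many epochs
  big <- sample_feature_epochs(mix, c(5e4, 5e4), cm, seed = 3)
  rec <- reconstruct_class_means(estimate_group_means(big), mix)
  err <- sqrt(sum((rec$target - cm$target)^2) +
    sum((rec$nontarget - cm$nontarget)^2))
  expect_lt(err, 0.05 * sqrt(sum((cm$target - cm$nontarget)^2)) + 0.05)
  expect_error(
    sample_feature_epochs(mix, c(10, 10), cm, covariance = matrix(c(1, 2, 2, 1), 2)),
    "positive-definite"
  )
})

test_that("homogeneity violations shift exactly one group's target class", {
  mix <- study_mixing()
  cm <- list(target = c(1, 0), nontarget = c(0, 0))
  ep <- sample_feature_epochs(mix, c(100, 100), cm, seed = 5)
  same <- homogeneity_violation(ep, "sequence1", c(0, 0))
  expect_identical(same$features, ep$features)
  shifted <- homogeneity_violation(ep, "sequence1", c(2, -1))
  idx <- ep$group == "sequence1" & ep$label == "target"
  expect_equal(
    shifted$features[idx, ],
    ep$features[idx, ] + matrix(c(2, -1), sum(idx), 2, byrow = TRUE)
  )
  expect_identical(shifted$features[!idx, ], ep$features[!idx, ])
  expect_error(homogeneity_violation(ep, "nope", c(1, 1)), "not present")

  # mean-map bias grows linearly in the injected shift
  bias_at <- function(s) {
    v <- homogeneity_violation(ep, "sequence1", c(s, 0))
    rec <- reconstruct_class_means(estimate_group_means(v), mix)
    rec$target[1]
  }
  b0 <- bias_at(0)
  b1 <- bias_at(1)
  b2 <- bias_at(2)
  expect_equal(b2 - b1, b1 - b0, tolerance = 1e-9)
})

test_that("the study sentence preset has 63 selectable characters", {
  grid <- speller_grid()
  idx <- study_sentence(grid)
  expect_length(idx, 63)
  expect_true(all(!grid$blank[idx]))
  expect_equal(grid$symbols[idx[1]], "F")
})
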