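#' Turn a simulated or recorded signal into a decoder-ready epoch set
#'
#' Pipeline glue: band-pass filter and downsample, cut baseline-corrected
#' epochs, extract interval-mean features, and attach the per-epoch
#' metadata (sequence tag, trial id, highlighted symbols, optional labels)
#' from the schedules.
#'
#' @param recording a [continuous_recording()] whose onsets match the
#'   concatenated schedule events in order.
#' @param schedules list of [generate_trial()] schedules.
#' @param config a [feature_config()].
#' @param labels optional ground-truth labels (evaluation only).
#' @return an [epoch_set()] with one row per stimulus event.
#' @export
build_epoch_set <- function(recording, schedules, config = feature_config(),
                            labels = NULL) {
  if (inherits(schedules, "stimulus_schedule")) {
    schedules <- list(schedules)
  }
  events <- do.call(c, lapply(schedules, `[[`, "events"))
  if (length(events) != length(recording$onsets)) {
    stop(sprintf(
      "schedules describe %d events but the recording has %d onsets",
      length(events), length(recording$onsets)
    ), call. = FALSE)
  }
  proc <- preprocess(recording, config)
  windows <- extract_epochs(proc, config)
  feats <- interval_means(windows, config)
  epoch_set(
    feats,
    group = unlist(lapply(schedules, function(s) {
      vapply(s$events, `[[`, integer(1), "group")
    })),
    trial = unlist(lapply(schedules, function(s) {
      rep(s$trial_id, length(s$events))
    })),
    highlighted = lapply(events, `[[`, "highlighted"),
    label = labels
  )
}

#' Simulate online copy-spelling with per-character retraining
#'
#' Replays the study's online protocol on an epoch stream: after each
#' trial's 68 epochs arrive, the unsupervised LLP decoder is retrained on
#' all epochs observed so far (the current trial included) and the symbol
#' of the current trial is selected with that model. Labels are never used
#' for training; when ground truth is provided, per-character correctness
#' and the binary AUC of each retrained model on all epochs so far are
#' recorded for evaluation. After the last character the whole run is
#' re-decoded with the final model (post-hoc re-analysis).
#'
#' @param epochs an [epoch_set()] covering all trials, in chronological
#'   order, with `highlighted` metadata.
#' @param schedules list of schedules, one per trial, in the same order.
#' @param mixing a [mixing_matrix()].
#' @param grid a [speller_grid()].
#' @param attended optional integer vector of true attended symbols
#'   (evaluation only).
#' @param include_current train the trial-t model on trial t's own epochs
#'   (the end-of-trial retraining of the online protocol, default `TRUE`);
#'   `FALSE` scores trial t with the model of trials `1..t-1` (trial 1 uses
#'   its own epochs either way, since no earlier data exists).
#' @return an object of class `online_run`: list with `selected`,
#'   `correct`, `posthoc_selected`, `posthoc_correct`, `auc_trajectory`,
#'   `n_characters` and the final `model`.
#' @export
run_online <- function(epochs, schedules, mixing, grid = speller_grid(),
                       attended = NULL, include_current = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (inherits(schedules, "stimulus_schedule")) {
    schedules <- list(schedules)
  }
  if (is.null(epochs$highlighted)) {
    stop("online decoding needs highlighted-symbol metadata on the epochs",
      call. = FALSE
    )
  }
  trial_ids <- vapply(schedules, `[[`, integer(1), "trial_id")
  n_char <- length(trial_ids)
  if (!is.null(attended)) {
    stopifnot(length(attended) == n_char)
  }
  idx_by_trial <- lapply(trial_ids, function(t) which(epochs$trial == t))
  if (any(lengths(idx_by_trial) == 0L)) {
    stop("every schedule needs matching epochs (trial ids disagree)",
      call. = FALSE
    )
  }
  have_labels <- !anyNA(epochs$label)
  selected <- integer(n_char)
  auc_traj <- rep(NA_real_, n_char)
  model <- NULL
  for (t in seq_len(n_char)) {
    upto <- if (include_current || t == 1L) t else t - 1L
    seen <- sort(unlist(idx_by_trial[seq_len(upto)]))
    model <- train_llp(epochs[seen], mixing)
    cur <- idx_by_trial[[t]]
    scores <- score_epochs(model, epochs$features[cur, , drop = FALSE])
    selected[t] <- select_symbol(scores, epochs$highlighted[cur], grid)
    if (have_labels) {
      auc_traj[t] <- auc(
        score_epochs(model, epochs$features[seen, , drop = FALSE]),
        epochs$label[seen]
      )
    }
  }
  posthoc <- posthoc_reanalysis(model, epochs, schedules, grid)
  structure(
    list(
      selected = selected,
      correct = if (!is.null(attended)) selected == attended else NULL,
      posthoc_selected = posthoc,
      posthoc_correct = if (!is.null(attended)) posthoc == attended else NULL,
      auc_trajectory = auc_traj,
      n_characters = n_char,
      model = model
    ),
    class = "online_run"
  )
}

#' @export
print.online_run <- function(x, ...) {
  cat(sprintf("Online spelling run: %d characters\n", x$n_characters))
  if (!is.null(x$correct)) {
    cat(sprintf(
      "  online accuracy:   %.1f%%\n  post-hoc accuracy: %.1f%%\n",
      100 * mean(x$correct), 100 * mean(x$posthoc_correct)
    ))
  }
  invisible(x)
}

#' Re-decode every trial with the final model
#'
#' Post-hoc re-analysis: once spelling ends, the final (best-trained)
#' unsupervised model re-scores every earlier trial and re-selects its
#' symbol, typically correcting early ramp-up mistakes. Labels are not
#' consulted.
#'
#' @param model the final `llp_model` of a run.
#' @param epochs the full [epoch_set()] of the run.
#' @param schedules list of schedules, one per trial.
#' @param grid a [speller_grid()].
#' @return integer vector of re-selected symbol indices, one per trial.
#' @export
posthoc_reanalysis <- function(model, epochs, schedules,
                               grid = speller_grid()) {
  if (inherits(schedules, "stimulus_schedule")) {
    schedules <- list(schedules)
  }
  vapply(schedules, function(sch) {
    cur <- which(epochs$trial == sch$trial_id)
    scores <- score_epochs(model, epochs$features[cur, , drop = FALSE])
    select_symbol(scores, epochs$highlighted[cur], grid)
  }, integer(1))
}

# Random per-epoch group assignment realizing the mixing ratios on a
# labelled pool. Group sizes start equal and are then rebalanced between
# the lowest- and highest-target-ratio groups so that the groups'
# aggregate target demand matches the pool's target count: the pool's
# class ratio must lie inside the span of the mixing's target ratios.
.assign_groups <- function(labels, mixing) {
  n <- length(labels)
  g <- nrow(mixing)
  pi_t <- mixing[, "target"]
  n_t <- sum(labels == "target")
  if (n_t / n < min(pi_t) - 1e-9 || n_t / n > max(pi_t) + 1e-9) {
    stop(sprintf(
      paste(
        "pool target fraction %.3f lies outside the mixing's target-ratio",
        "range [%.3f, %.3f]: the requested mixing cannot be realized"
      ),
      n_t / n, min(pi_t), max(pi_t)
    ), call. = FALSE)
  }
  n_g <- rep(n %/% g, g)
  if (n %% g) {
    n_g[seq_len(n %% g)] <- n_g[seq_len(n %% g)] + 1L
  }
  i_max <- which.max(pi_t)
  i_min <- which.min(pi_t)
  deficit <- n_t - sum(n_g * pi_t)
  move <- round(deficit / (pi_t[i_max] - pi_t[i_min]))
  move <- max(-n_g[i_max] + 1L, min(n_g[i_min] - 1L, move))
  n_g[i_max] <- n_g[i_max] + move
  n_g[i_min] <- n_g[i_min] - move
  need_t <- as.integer(round(n_g * pi_t))
  # absorb rounding remainders into the largest group
  need_t[i_max] <- need_t[i_max] + (n_t - sum(need_t))
  need_n <- n_g - need_t
  if (any(need_t < 0L) || any(need_n < 0L)) {
    stop("class counts cannot realize the requested mixing ratios",
      call. = FALSE
    )
  }
  pool_t <- sample(which(labels == "target"))
  pool_n <- sample(which(labels != "target"))
  group <- character(n)
  ot <- 0L
  on <- 0L
  for (gi in seq_len(g)) {
    group[pool_t[ot + seq_len(need_t[gi])]] <- rownames(mixing)[gi]
    group[pool_n[on + seq_len(need_n[gi])]] <- rownames(mixing)[gi]
    ot <- ot + need_t[gi]
    on <- on + need_n[gi]
  }
  group
}

.chron_folds <- function(n, k) {
  split(seq_len(n), cut(seq_len(n), k, labels = FALSE))
}

#' Learning curves of LLP versus the supervised baseline
#'
#' For each training size `n` (a chronological prefix of the labelled
#' epoch pool) and each candidate mixing matrix: epochs are randomly
#' assigned to sequence groups realizing the mixing ratios, the LLP decoder
#' is trained on all `n` epochs (unsupervised, so the evaluation folds may
#' be included), and the binary target/non-target AUC is averaged over
#' 5-fold chronological cross-validation. The supervised shrinkage-LDA
#' baseline is trained per fold on the other folds only. Lower-NAF mixings
#' are expected to dominate at every `n`.
#'
#' @param epochs a labelled [epoch_set()] in chronological order.
#' @param mixings named list of [mixing_matrix()] objects.
#' @param n_grid integer vector of training sizes.
#' @param folds number of chronological CV folds.
#' @param seed optional integer seed for the group assignments.
#' @return an object of class `learning_curves`: data frame with columns
#'   `n`, `mixing`, `method`, `auc`, `naf`.
#' @export
learning_curves <- function(epochs, mixings, n_grid, folds = 5L,
                            seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (inherits(mixings, "mixing_matrix")) {
    mixings <- list(mixings)
  }
  if (is.null(names(mixings))) {
    names(mixings) <- paste0("mixing", seq_along(mixings))
  }
  if (anyNA(epochs$label)) {
    stop("learning curves need a labelled epoch pool", call. = FALSE)
  }
  if (max(n_grid) > n_epochs(epochs)) {
    stop(sprintf(
      "training size %d exceeds the %d available epochs",
      max(n_grid), n_epochs(epochs)
    ), call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    for (n in sort(as.integer(n_grid))) {
      prefix <- epochs[seq_len(n)]
      fold_idx <- .chron_folds(n, folds)
      # supervised baseline: per fold, train on the complement
      sup_auc <- mean(vapply(fold_idx, function(te) {
        fit <- train_supervised(prefix[setdiff(seq_len(n), te)])
        auc(
          score_epochs(fit, prefix$features[te, , drop = FALSE]),
          prefix$label[te]
        )
      }, numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, mixing = "supervised", method = "supervised",
        auc = sup_auc, naf = NA_real_
      )
      for (m in names(mixings)) {
        mix <- mixings[[m]]
        grp <- .assign_groups(prefix$label, mix)
        llp_pool <- epoch_set(
          prefix$features, grp, prefix$trial, prefix$highlighted,
          prefix$label
        )
        fit <- train_llp(llp_pool, mix)
        llp_auc <- mean(vapply(fold_idx, function(te) {
          auc(
            score_epochs(fit, prefix$features[te, , drop = FALSE]),
            prefix$label[te]
          )
        }, numeric(1)))
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, mixing = m, method = "llp", auc = llp_auc,
          naf = noise_amplification_factor(mix)
        )
      }
    }
    structure(do.call(rbind, rows),
      class = c("learning_curves", "data.frame")
    )
  })
}

#' Leave-one-out homogeneity bootstrap
#'
#' Tests, per class, whether the class-conditional response distribution is
#' the same in both sequence groups. For every epoch of the class in group
#' 1, the squared L2 distance to the leave-one-out class average of group 1
#' and the distance to the class average of group 2 are computed; a
#' two-sided paired t-test (flavor `"paired"`, the default; `"two_sample"`
#' for an unpaired Welch test) checks whether the two distance populations
#' differ. Under the homogeneity null the distances agree in expectation.
#' The caller applies any multiple-testing correction (the study divided
#' the level by the number of subjects).
#'
#' @param x numeric N x P matrix of epoch representations - typically the
#'   preprocessed epochs flattened over channels and the 0-700 ms window
#'   (see [flatten_epochs()]) - or an [epoch_set()] (its feature matrix is
#'   used).
#' @param labels length-N class labels (`"target"` / `"nontarget"`);
#'   defaults to the epoch set's labels.
#' @param groups length-N group tags; defaults to the epoch set's tags.
#'   Exactly two distinct groups are required; the first in sort order
#'   plays the role of group 1.
#' @param flavor `"paired"` or `"two_sample"`.
#' @return data frame with one row per class: `class`, `statistic`, `p`,
#'   `n` (epochs entering the test).
#' @export
homogeneity_bootstrap <- function(x, labels = NULL, groups = NULL,
                                  flavor = c("paired", "two_sample")) {
  flavor <- match.arg(flavor)
  if (inherits(x, "epoch_set")) {
    if (is.null(labels)) labels <- x$label
    if (is.null(groups)) groups <- x$group
    x <- x$features
  }
  x <- as.matrix(x)
  stopifnot(length(labels) == nrow(x), length(groups) == nrow(x))
  if (anyNA(labels)) {
    stop("the homogeneity bootstrap needs labelled epochs", call. = FALSE)
  }
  gl <- sort(unique(as.character(groups)))
  if (length(gl) != 2L) {
    stop("exactly two sequence groups are required", call. = FALSE)
  }
  out <- lapply(c("target", "nontarget"), function(cl) {
    i1 <- which(groups == gl[1L] & labels == cl)
    i2 <- which(groups == gl[2L] & labels == cl)
    if (!length(i1) || !length(i2)) {
      stop(sprintf("class '%s' is absent in one of the groups", cl),
        call. = FALSE
      )
    }
    if (length(i1) < 2L) {
      stop(sprintf(
        "class '%s' has a single epoch in group %s: leave-one-out undefined",
        cl, gl[1L]
      ), call. = FALSE)
    }
    x1 <- x[i1, , drop = FALSE]
    mean2 <- colMeans(x[i2, , drop = FALSE])
    sum1 <- colSums(x1)
    n1 <- length(i1)
    # leave-one-out means of group 1, one row per held-out epoch
    loo <- (matrix(sum1, n1, ncol(x), byrow = TRUE) - x1) / (n1 - 1)
    d1 <- rowSums((x1 - loo)^2)
    d2 <- rowSums(sweep(x1, 2L, mean2)^2)
    tt <- if (flavor == "paired") {
      stats::t.test(d1, d2, paired = TRUE)
    } else {
      stats::t.test(d1, d2)
    }
    data.frame(
      class = cl, statistic = unname(tt$statistic), p = tt$p.value, n = n1
    )
  })
  do.call(rbind, out)
}
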