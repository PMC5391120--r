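#' Default simulated electrode montage
#'
#' A plausible 31-channel layout containing the frontal channels that the
#' default preprocessing excludes (Fp1, Fp2), a set of occipital channels
#' carrying the early target negativity, and central channels carrying the
#' late positivity.
#'
#' @return character vector of 31 channel names with a `role` attribute
#'   (`"occipital"`, `"central"` or `"other"`).
#' @export
default_channels <- function() {
  ch <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8", "CP5", "CP1", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8", "PO7", "O1", "Oz", "O2", "PO8", "POz"
  )
  role <- rep("other", length(ch))
  role[ch %in% c("PO7", "O1", "Oz", "O2", "PO8", "POz")] <- "occipital"
  role[ch %in% c("C3", "Cz", "C4", "CP1", "CP2")] <- "central"
  attr(ch, "role") <- role
  ch
}

#' Stimulus-locked ERP waveform templates
#'
#' Class-conditional response templates added to the simulated signal at
#' each stimulus onset. The default target response has a Gaussian trough
#' of -8 microvolts at 150 ms (sd 25 ms) on occipital channels - the strong
#' early negativity seen with salient visual highlighting - and a Gaussian
#' bump of +2 microvolts at 400 ms (sd 60 ms) on central channels - the
#' weaker late positivity. The non-target response is zero by default; a
#' nonzero `nontarget_scale` gives non-targets the same waveform scaled
#' down (capped at 0.3 so targets stay dominant on discriminative
#' channels).
#'
#' @param channels channel-name vector with a `role` attribute, as from
#'   [default_channels()].
#' @param rate template sampling rate in Hz.
#' @param duration_ms template length in ms from stimulus onset.
#' @param n150_amp,n150_lat,n150_sd early-negativity amplitude (microvolts,
#'   negative), latency and width (ms).
#' @param p300_amp,p300_lat,p300_sd late-positivity amplitude, latency and
#'   width (ms).
#' @param nontarget_scale non-target response as a fraction of the target
#'   response, in `[0, 0.3]`.
#' @return an object of class `erp_templates`: list with `target`,
#'   `nontarget` (C x S matrices), `rate`, `channels`, `roles`.
#' @export
erp_templates <- function(channels = default_channels(), rate = 1000,
                          duration_ms = 700,
                          n150_amp = -8, n150_lat = 150, n150_sd = 25,
                          p300_amp = 2, p300_lat = 400, p300_sd = 60,
                          nontarget_scale = 0) {
  stopifnot(nontarget_scale >= 0, nontarget_scale <= 0.3)
  roles <- attr(channels, "role")
  if (is.null(roles)) {
    roles <- rep("other", length(channels))
  }
  t_ms <- seq(0, duration_ms, by = 1000 / rate)
  n150 <- n150_amp * exp(-(t_ms - n150_lat)^2 / (2 * n150_sd^2))
  p300 <- p300_amp * exp(-(t_ms - p300_lat)^2 / (2 * p300_sd^2))
  target <- matrix(0, length(channels), length(t_ms),
    dimnames = list(channels, NULL)
  )
  target[roles == "occipital", ] <- rep(n150, each = sum(roles == "occipital"))
  target[roles == "central", ] <- rep(p300, each = sum(roles == "central"))
  structure(
    list(
      target = target,
      nontarget = target * nontarget_scale,
      rate = rate,
      channels = channels,
      roles = roles
    ),
    class = "erp_templates"
  )
}

#' Simulation parameters for continuous pseudo-EEG synthesis
#'
#' @param n_channels number of channels (defaults to the template montage).
#' @param sampling_rate recording rate in Hz.
#' @param soa_ms stimulus onset asynchrony in ms.
#' @param snr signal-to-noise ratio: the peak amplitude of the scaled
#'   target template divided by the noise standard deviation (the noise has
#'   unit marginal variance, so the template is rescaled to peak at `snr`).
#'   `snr = 0` removes the evoked signal entirely.
#' @param noise_model `"ar1"` (default) or `"white"`.
#' @param ar_rho AR(1) coefficient at the recording rate, in `[0, 1)`;
#'   0.95 at 1 kHz gives EEG-like low-frequency-dominated spectra.
#' @param templates an [erp_templates()] object.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(n_channels = NULL, sampling_rate = 1000,
                              soa_ms = 250, snr = 2,
                              noise_model = c("ar1", "white"),
                              ar_rho = 0.95,
                              templates = erp_templates(rate = sampling_rate)) {
  noise_model <- match.arg(noise_model)
  stopifnot(snr >= 0, ar_rho >= 0, ar_rho < 1)
  stopifnot(templates$rate == sampling_rate)
  if (is.null(n_channels)) {
    n_channels <- length(templates$channels)
  }
  stopifnot(n_channels == length(templates$channels))
  structure(
    list(
      n_channels = n_channels, sampling_rate = sampling_rate,
      soa_ms = soa_ms, snr = snr, noise_model = noise_model,
      ar_rho = ar_rho, templates = templates
    ),
    class = "simulation_params"
  )
}

.ar1_noise <- function(n_channels, n_samples, rho) {
  innov_sd <- sqrt(1 - rho^2) # unit marginal variance
  t(vapply(seq_len(n_channels), function(ch) {
    e <- stats::rnorm(n_samples, sd = innov_sd)
    as.numeric(stats::filter(e, rho, method = "recursive",
      init = stats::rnorm(1)
    ))
  }, numeric(n_samples)))
}

#' Synthesize a continuous recording from stimulus schedules
#'
#' Builds a continuous multichannel signal by placing the target or
#' non-target ERP template (per the ground-truth label of each event) at
#' onsets spaced by the SOA, scaling the templates so the target peak
#' equals `snr` noise standard deviations, and adding unit-variance noise.
#' Trials follow each other with an inter-trial gap long enough for the
#' last epoch window to fit. Ground-truth labels are returned separately
#' from the recording and are never consumed by the decoder.
#'
#' @param params a [simulation_params()].
#' @param schedules list of [generate_trial()] schedules.
#' @param attended integer vector of attended symbol indices, one per
#'   schedule.
#' @param grid the [speller_grid()] the schedules were generated on.
#' @param seed optional integer seed (bit-identical output on repeat).
#' @return list with `recording` (a [continuous_recording()]), `labels`
#'   (character vector over all events), `trial` (trial id per event) and
#'   `groups` (sequence tag per event).
#' @export
simulate_recording <- function(params, schedules, attended,
                               grid = speller_grid(), seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (inherits(schedules, "stimulus_schedule")) {
    schedules <- list(schedules)
  }
  stopifnot(length(attended) == length(schedules))
  fs <- params$sampling_rate
  soa <- as.integer(round(params$soa_ms * fs / 1000))
  tmpl_len <- ncol(params$templates$target)
  peak <- max(abs(params$templates$target))
  scale <- if (peak > 0) params$snr / peak else 0
  n_events <- vapply(schedules, function(s) length(s$events), integer(1))
  # 300 ms lead-in so the -200 ms epoch edge fits before the first onset
  lead <- as.integer(round(0.3 * fs))
  gap <- tmpl_len
  onsets <- integer(0)
  labels <- character(0)
  trial <- integer(0)
  groups <- integer(0)
  cursor <- lead
  for (i in seq_along(schedules)) {
    sch <- schedules[[i]]
    on_i <- cursor + soa * (seq_len(n_events[i]) - 1L)
    onsets <- c(onsets, on_i)
    labels <- c(labels, label_events(sch, attended[i], grid))
    trial <- c(trial, rep(sch$trial_id, n_events[i]))
    groups <- c(groups, vapply(sch$events, `[[`, integer(1), "group"))
    cursor <- on_i[n_events[i]] + soa + gap
  }
  n_samples <- cursor + tmpl_len
  with_seed(seed, {
    x <- if (params$noise_model == "ar1") {
      .ar1_noise(params$n_channels, n_samples, params$ar_rho)
    } else {
      matrix(stats::rnorm(params$n_channels * n_samples),
        params$n_channels, n_samples
      )
    }
    if (scale > 0) {
      for (k in seq_along(onsets)) {
        tm <- if (labels[k] == "target") {
          params$templates$target
        } else {
          params$templates$nontarget
        }
        idx <- onsets[k]:(onsets[k] + tmpl_len - 1L)
        x[, idx] <- x[, idx] + scale * tm
      }
    }
    list(
      recording = continuous_recording(
        x, fs, onsets, params$templates$channels
      ),
      labels = labels, trial = trial, groups = as.character(groups)
    )
  })
}

#' Sample feature epochs directly from class-conditional Gaussians
#'
#' Skips the signal level entirely: draws epochs whose features follow
#' `N(mu_class, Sigma)`, with group membership and class labels set by the
#' mixing matrix. In `exact_counts` mode each group receives exactly
#' `round(n * pi+)` targets (the paradigm's deterministic counts); in
#' Bernoulli mode each epoch is a target independently with probability
#' `pi+` of its group (the IID setting of the convergence theory).
#'
#' @param mixing a [mixing_matrix()].
#' @param n_per_group integer vector of epochs per group (recycled to G).
#' @param class_means list with `target` and `nontarget` D-vectors.
#' @param covariance D x D positive-definite matrix (scalar = spherical).
#' @param seed optional integer seed.
#' @param exact_counts deterministic per-group target counts? Default
#'   `FALSE` (Bernoulli).
#' @param trial optional trial id stored on all epochs.
#' @return a labelled [epoch_set()] with group tags equal to the mixing's
#'   group names.
#' @export
sample_feature_epochs <- function(mixing, n_per_group, class_means,
                                  covariance = NULL, seed = NULL,
                                  exact_counts = FALSE, trial = 1L) {
  stopifnot(inherits(mixing, "mixing_matrix"))
  g <- nrow(mixing)
  n_per_group <- rep_len(as.integer(n_per_group), g)
  stopifnot(all(n_per_group >= 1L))
  mu_t <- as.numeric(class_means$target)
  mu_n <- as.numeric(class_means$nontarget)
  d <- length(mu_t)
  stopifnot(length(mu_n) == d)
  if (is.null(covariance)) {
    covariance <- diag(d)
  } else if (length(covariance) == 1L) {
    covariance <- diag(as.numeric(covariance), d)
  }
  covariance <- as.matrix(covariance)
  stopifnot(nrow(covariance) == d, ncol(covariance) == d)
  ch <- tryCatch(chol(covariance), error = function(e) {
    stop("covariance must be symmetric positive-definite", call. = FALSE)
  })
  with_seed(seed, {
    n_tot <- sum(n_per_group)
    group <- rep(rownames(mixing), n_per_group)
    is_target <- logical(n_tot)
    off <- 0L
    for (gi in seq_len(g)) {
      n_g <- n_per_group[gi]
      pi_t <- mixing[gi, "target"]
      lab_g <- if (exact_counts) {
        k <- as.integer(round(n_g * pi_t))
        sample(rep(c(TRUE, FALSE), c(k, n_g - k)))
      } else {
        stats::runif(n_g) < pi_t
      }
      is_target[off + seq_len(n_g)] <- lab_g
      off <- off + n_g
    }
    noise <- matrix(stats::rnorm(n_tot * d), n_tot, d) %*% ch
    mu <- matrix(mu_n, n_tot, d, byrow = TRUE)
    mu[is_target, ] <- matrix(mu_t, sum(is_target), d, byrow = TRUE)
    epoch_set(
      mu + noise, group,
      trial = rep(as.integer(trial), n_tot),
      label = ifelse(is_target, "target", "nontarget")
    )
  })
}

#' Sample study-paradigm feature epochs for given schedules
#'
#' Feature-level counterpart of [simulate_recording()]: takes generated
#' stimulus schedules and attended symbols, labels every event from the
#' schedule (target iff the attended symbol is highlighted), and draws each
#' epoch's features from the Gaussian of its class. Group tags, trial ids
#' and highlighted sets come from the schedules, so the result can be fed
#' straight into [run_online()]. Much cheaper than continuous synthesis;
#' used for ensemble experiments.
#'
#' @param schedules list of [generate_trial()] schedules.
#' @param attended integer vector of attended symbols, one per schedule.
#' @param grid the [speller_grid()].
#' @param class_means list with `target` and `nontarget` D-vectors.
#' @param covariance D x D positive-definite matrix (scalar = spherical,
#'   default identity).
#' @param seed optional integer seed.
#' @return a labelled [epoch_set()].
#' @export
simulate_study_epochs <- function(schedules, attended, grid = speller_grid(),
                                  class_means, covariance = NULL,
                                  seed = NULL) {
  if (inherits(schedules, "stimulus_schedule")) {
    schedules <- list(schedules)
  }
  stopifnot(length(attended) == length(schedules))
  mu_t <- as.numeric(class_means$target)
  mu_n <- as.numeric(class_means$nontarget)
  d <- length(mu_t)
  if (is.null(covariance)) {
    covariance <- diag(d)
  } else if (length(covariance) == 1L) {
    covariance <- diag(as.numeric(covariance), d)
  }
  ch <- chol(as.matrix(covariance))
  labels <- unlist(lapply(seq_along(schedules), function(i) {
    label_events(schedules[[i]], attended[i], grid)
  }))
  n <- length(labels)
  with_seed(seed, {
    mu <- matrix(mu_n, n, d, byrow = TRUE)
    mu[labels == "target", ] <- matrix(
      mu_t, sum(labels == "target"), d,
      byrow = TRUE
    )
    epoch_set(
      mu + matrix(stats::rnorm(n * d), n, d) %*% ch,
      group = unlist(lapply(schedules, function(s) {
        vapply(s$events, `[[`, integer(1), "group")
      })),
      trial = unlist(lapply(schedules, function(s) {
        rep(s$trial_id, length(s$events))
      })),
      highlighted = do.call(c, lapply(schedules, function(s) {
        lapply(s$events, `[[`, "highlighted")
      })),
      label = labels
    )
  })
}

#' Inject a homogeneity violation into one group
#'
#' Adds a constant shift to the features of the target-class epochs of one
#' group, breaking the assumption that class-conditional distributions are
#' identical across groups. Used to probe the power of the homogeneity
#' bootstrap and the resulting bias of the mean-map reconstruction (which
#' grows linearly in the shift).
#'
#' @param epochs a labelled [epoch_set()].
#' @param group group tag to perturb.
#' @param shift numeric D-vector (or scalar) added to the group's target
#'   epochs.
#' @param class which class to shift (default `"target"`).
#' @return the perturbed [epoch_set()].
#' @export
homogeneity_violation <- function(epochs, group, shift, class = "target") {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!group %in% epochs$group) {
    stop(sprintf("group '%s' not present in the epochs", group),
      call. = FALSE
    )
  }
  idx <- which(epochs$group == group & !is.na(epochs$label) &
    epochs$label == class)
  if (length(idx)) {
    shift <- rep_len(as.numeric(shift), ncol(epochs$features))
    epochs$features[idx, ] <- sweep(
      epochs$features[idx, , drop = FALSE], 2L, shift, `+`
    )
  }
  epochs
}

#' The study's copy-spelling sentence preset
#'
#' The 63-character pangram-like German test sentence spelled three times
#' per session, mapped to grid symbol indices (space as `"_"`, lower case
#' folded to upper case).
#'
#' @param grid a [speller_grid()].
#' @return integer vector of 63 symbol indices with the character vector as
#'   names.
#' @export
study_sentence <- function(grid = speller_grid()) {
  txt <- "FRANZY JAGT IM KOMPLETT VERWAHRLOSTEN TAXI QUER DURCH FREIBURG."
  chars <- strsplit(txt, "")[[1]]
  chars[chars == " "] <- "_"
  idx <- match(chars, grid$symbols)
  stopifnot(!anyNA(idx))
  names(idx) <- chars
  idx
}
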