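#' Ledoit-Wolf shrinkage covariance estimate
#'
#' Analytic shrinkage of the sample covariance toward a scaled identity:
#' returns `(1 - gamma) S + gamma nu I`, where `S` is the sample covariance
#' (denominator N), `nu` the mean of its diagonal, and `gamma` the
#' Ledoit-Wolf shrinkage intensity clipped to `[0, 1]`. For N >> D the
#' intensity goes to 0 and the estimate approaches `S`; for N << D it goes
#' to 1 and the estimate approaches the well-conditioned `nu I`, keeping the
#' result positive-definite whenever the data are not all identical.
#'
#' @param x numeric N x D matrix of observations (rows), N >= 2. If
#'   `center = FALSE` rows are taken as already-centered residuals (used for
#'   pooled within-class estimation).
#' @param center subtract column means first? Default `TRUE`.
#' @return list with `sigma` (D x D), `gamma` (shrinkage intensity) and
#'   `nu` (shrinkage target scale).
#' @export
shrinkage_covariance <- function(x, center = TRUE) {
  x <- as.matrix(x)
  assert_finite_matrix(x, "observations")
  n <- nrow(x)
  d <- ncol(x)
  if (n < 2L) {
    stop("shrinkage covariance needs at least 2 observations", call. = FALSE)
  }
  if (center) {
    x <- sweep(x, 2L, colMeans(x))
  }
  s <- crossprod(x) / n
  nu <- mean(diag(s))
  # squared Frobenius distances per Ledoit & Wolf (2004), scaled by 1/d
  d2 <- sum((s - nu * diag(d))^2) / d
  if (d2 <= .Machine$double.eps) {
    gamma <- 0
  } else {
    row_sq <- rowSums(x^2)
    # sum_i ||x_i x_i' - S||_F^2 = sum_i (x_i'x_i)^2 - 2 sum_i x_i'Sx_i + n||S||_F^2
    cross <- sum((x %*% s) * x)
    b2bar <- (sum(row_sq^2) - 2 * cross + n * sum(s^2)) / (n^2 * d)
    gamma <- min(1, max(0, b2bar / d2))
    if (b2bar <= d2 * 1e-14) {
      # the dispersion statistic is degenerate (e.g. two centered
      # observations are antipodal, so every x_i x_i' equals S); if S is
      # itself rank-deficient the formula would return a singular
      # estimate, so shrink fully to the well-conditioned target
      ev_min <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min <= nu * 1e-12) {
        gamma <- 1
      }
    }
  }
  sigma <- (1 - gamma) * s + gamma * nu * diag(d)
  list(sigma = sigma, gamma = gamma, nu = nu)
}

.make_llp_model <- function(class_means, cov_fit, n, supervised) {
  delta <- class_means$target - class_means$nontarget
  # SPD solve via Cholesky rather than explicit inversion
  ch <- chol(cov_fit$sigma)
  w <- drop(backsolve(ch, forwardsolve(t(ch), delta)))
  structure(
    list(
      weights = w,
      class_means = class_means,
      covariance = cov_fit$sigma,
      shrinkage = cov_fit$gamma,
      n_epochs_trained = n,
      supervised = supervised
    ),
    class = "llp_model"
  )
}

#' @export
print.llp_model <- function(x, ...) {
  cat(sprintf(
    "%s linear ERP decoder: D = %d, trained on %d epochs, shrinkage = %.3f\n",
    if (x$supervised) "Supervised (shrinkage-LDA)" else "LLP (mean-map)",
    length(x$weights), x$n_epochs_trained, x$shrinkage
  ))
  invisible(x)
}

#' Train the unsupervised LLP decoder
#'
#' Estimates group means from the epochs' sequence tags, reconstructs the
#' target / non-target class means through the mixing matrix, estimates the
#' pooled (global, class-ignorant) shrinkage covariance on all epochs, and
#' forms the projection `w = Sigma^-1 (mu+ - mu-)`. Per-epoch labels are
#' never consulted.
#'
#' @param epochs an [epoch_set()] with group tags.
#' @param mixing a [mixing_matrix()] whose rows match the group tags
#'   (matched by sorted tag order, or by name when tags equal the mixing's
#'   group names).
#' @return an object of class `llp_model`.
#' @export
train_llp <- function(epochs, mixing) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(mixing, "mixing_matrix"))
  tags <- sort(unique(as.character(epochs$group)))
  groups <- if (setequal(tags, rownames(mixing))) rownames(mixing) else tags
  if (length(groups) != nrow(mixing)) {
    stop(sprintf(
      "epochs carry %d group tags but the mixing matrix has %d groups",
      length(groups), nrow(mixing)
    ), call. = FALSE)
  }
  gm <- estimate_group_means(epochs, groups = groups)
  cm <- reconstruct_class_means(gm, mixing)
  cov_fit <- shrinkage_covariance(epochs$features, center = TRUE)
  .make_llp_model(cm, cov_fit, n_epochs(epochs), supervised = FALSE)
}

#' Train the supervised shrinkage-LDA baseline
#'
#' Class means are the labelled sample means; the covariance is the pooled
#' within-class shrinkage estimate (class-wise centered residuals pooled,
#' weighting each class by its epoch count; `pooling = "unweighted"`
#' averages the per-class shrinkage estimates instead). Projection as in
#' [train_llp()].
#'
#' @param epochs a fully labelled [epoch_set()].
#' @param pooling `"weighted"` (default) or `"unweighted"` class pooling.
#' @return an object of class `llp_model`.
#' @export
train_supervised <- function(epochs, pooling = c("weighted", "unweighted")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(epochs, "epoch_set"))
  lab <- epochs$label
  if (anyNA(lab)) {
    stop("supervised training needs fully labelled epochs", call. = FALSE)
  }
  x <- epochs$features
  pos <- lab == "target"
  if (!sum(pos) || !sum(!pos)) {
    stop("both classes must be present to train the supervised baseline",
      call. = FALSE
    )
  }
  mu_pos <- colMeans(x[pos, , drop = FALSE])
  mu_neg <- colMeans(x[!pos, , drop = FALSE])
  cm <- structure(list(target = mu_pos, nontarget = mu_neg),
    class = "class_means"
  )
  if (pooling == "weighted") {
    resid <- rbind(
      sweep(x[pos, , drop = FALSE], 2L, mu_pos),
      sweep(x[!pos, , drop = FALSE], 2L, mu_neg)
    )
    cov_fit <- shrinkage_covariance(resid, center = FALSE)
  } else {
    f_pos <- shrinkage_covariance(x[pos, , drop = FALSE])
    f_neg <- shrinkage_covariance(x[!pos, , drop = FALSE])
    cov_fit <- list(
      sigma = (f_pos$sigma + f_neg$sigma) / 2,
      gamma = (f_pos$gamma + f_neg$gamma) / 2,
      nu = (f_pos$nu + f_neg$nu) / 2
    )
  }
  .make_llp_model(cm, cov_fit, n_epochs(epochs), supervised = TRUE)
}

#' Score epochs with a trained decoder
#'
#' The decoder output is the bias-free linear score `w' x`; only score
#' differences matter downstream (symbol sums, AUC), so no intercept is
#' fitted.
#'
#' @param model an `llp_model`.
#' @param epochs an [epoch_set()] or a bare N x D feature matrix.
#' @return numeric vector of N scores.
#' @export
score_epochs <- function(model, epochs) {
  stopifnot(inherits(model, "llp_model"))
  x <- if (inherits(epochs, "epoch_set")) epochs$features else as.matrix(epochs)
  if (ncol(x) != length(model$weights)) {
    stop(sprintf(
      "feature dimension mismatch: model expects %d features, epochs have %d",
      length(model$weights), ncol(x)
    ), call. = FALSE)
  }
  drop(x %*% model$weights)
}

#' Select the spelled symbol of one trial
#'
#' Sums the classifier scores of all epochs in which each selectable symbol
#' was highlighted and returns the symbol with the highest sum. Visual
#' blanks are excluded from selection. Because every selectable symbol is
#' highlighted equally often within a trial of the study paradigm, a
#' constant score offset shifts all sums equally and cannot change the
#' winner. Ties break toward the lowest symbol index.
#'
#' @param scores numeric vector of per-epoch scores for one trial.
#' @param epochs the matching [epoch_set()] carrying `highlighted` sets, or
#'   a bare list of highlighted-index vectors.
#' @param grid a [speller_grid()].
#' @return integer symbol index (1-based position in `grid$symbols`).
#' @export
select_symbol <- function(scores, epochs, grid) {
  highlighted <- if (inherits(epochs, "epoch_set")) {
    epochs$highlighted
  } else {
    epochs
  }
  if (is.null(highlighted) || !length(highlighted)) {
    stop("symbol selection needs a non-empty trial with highlighted sets",
      call. = FALSE
    )
  }
  stopifnot(length(scores) == length(highlighted))
  sums <- numeric(length(grid$symbols))
  for (i in seq_along(scores)) {
    idx <- highlighted[[i]]
    sums[idx] <- sums[idx] + scores[i]
  }
  selectable <- which(!grid$blank)
  selectable[which.max(sums[selectable])]
}

#' Area under the ROC curve for target versus non-target scores
#'
#' The probability that a uniformly drawn target epoch scores higher than a
#' uniformly drawn non-target epoch, ties counting one half (Mann-Whitney
#' convention). Chance level is 0.5.
#'
#' @param scores numeric vector.
#' @param labels vector with values `"target"` / `"nontarget"` (or a
#'   logical vector, `TRUE` = target).
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "target"
  stopifnot(length(scores) == length(pos), !anyNA(pos), all(is.finite(scores)))
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (!n_pos || !n_neg) {
    stop("AUC needs both target and non-target epochs", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Save a trained decoder to disk
#'
#' Scalar fields, shapes and metadata go to a JSON header; the numeric
#' arrays (weights, class means, covariance) go to a little-endian float64
#' sidecar `<path>.bin`, so the round trip is bit-exact.
#'
#' @param model an `llp_model`.
#' @param path path of the JSON header to write.
#' @return `path`, invisibly.
#' @export
write_llp_model <- function(model, path) {
  stopifnot(inherits(model, "llp_model"))
  d <- length(model$weights)
  arrays <- c(
    model$weights, model$class_means$target, model$class_means$nontarget,
    as.vector(model$covariance)
  )
  bin <- paste0(path, ".bin")
  con <- file(bin, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.double(arrays), con, size = 8L, endian = "little")
  header <- list(
    format = "llpspeller-model-v1",
    d = d,
    shrinkage = model$shrinkage,
    n_epochs_trained = model$n_epochs_trained,
    supervised = model$supervised,
    sidecar = basename(bin)
  )
  jsonlite::write_json(header, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a decoder saved by [write_llp_model()]
#'
#' @param path path of the JSON header.
#' @return an `llp_model`.
#' @export
read_llp_model <- function(path) {
  header <- jsonlite::fromJSON(path)
  stopifnot(identical(header$format, "llpspeller-model-v1"))
  d <- as.integer(header$d)
  bin <- file.path(dirname(path), header$sidecar)
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE)
  arrays <- readBin(con, "double",
    n = 3L * d + d * d, size = 8L,
    endian = "little"
  )
  structure(
    list(
      weights = arrays[seq_len(d)],
      class_means = structure(
        list(
          target = arrays[d + seq_len(d)],
          nontarget = arrays[2L * d + seq_len(d)]
        ),
        class = "class_means"
      ),
      covariance = matrix(arrays[3L * d + seq_len(d * d)], d, d),
      shrinkage = header$shrinkage,
      n_epochs_trained = as.integer(header$n_epochs_trained),
      supervised = isTRUE(header$supervised)
    ),
    class = "llp_model"
  )
}
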