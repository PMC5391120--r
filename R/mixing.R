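#' Mixing matrix of per-group class proportions
#'
#' A mixing matrix holds, for each stimulus sequence group, the known
#' proportion of target and non-target epochs. Row g is
#' `(pi+_g, pi-_g)`, the target and non-target fraction of group g. The
#' mean-map reconstruction inverts this matrix (its Moore-Penrose
#' pseudoinverse for more than two groups) to map group-wise feature means
#' to class-wise means.
#'
#' @param proportions numeric G x 2 matrix (or coercible) of group-wise
#'   target / non-target proportions; each row must sum to 1.
#' @param group_names optional character vector of G group labels.
#' @return an object of class `mixing_matrix`: the validated G x 2 matrix
#'   with rownames set to the group names.
#' @export
#' @examples
#' mixing_matrix(rbind(c(3 / 8, 5 / 8), c(2 / 18, 16 / 18)))
mixing_matrix <- function(proportions, group_names = NULL) {
  pr <- as.matrix(proportions)
  if (ncol(pr) != 2L) {
    stop("a mixing matrix has exactly 2 columns (target, non-target)",
      call. = FALSE
    )
  }
  if (nrow(pr) < 2L) {
    stop("a mixing matrix needs at least 2 groups", call. = FALSE)
  }
  if (!all(is.finite(pr)) || any(pr < 0) || any(pr > 1)) {
    stop("mixing proportions must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(pr) - 1) > 1e-12)) {
    stop("every mixing-matrix row must sum to 1", call. = FALSE)
  }
  if (is.null(group_names)) {
    group_names <- paste0("group", seq_len(nrow(pr)))
  }
  stopifnot(length(group_names) == nrow(pr))
  dimnames(pr) <- list(as.character(group_names), c("target", "nontarget"))
  .check_mixing_rank(pr)
  structure(pr, class = c("mixing_matrix", "matrix"))
}

.check_mixing_rank <- function(pr, tol = 1e-10) {
  sv <- svd(pr, nu = 0, nv = 0)$d
  if (sv[2L] < tol * sv[1L]) {
    stop(paste(
      "mixing matrix is rank-deficient (all groups share the same class",
      "proportions): target and non-target means are not identifiable"
    ), call. = FALSE)
  }
  invisible(pr)
}

#' @export
print.mixing_matrix <- function(x, ...) {
  cat(sprintf(
    "Mixing matrix: %d groups, NAF = %.2f\n",
    nrow(x), noise_amplification_factor(x)
  ))
  print(unclass(x), ...)
  invisible(x)
}

#' The two-sequence mixing matrix of the study paradigm
#'
#' Sequence 1 highlights every selectable symbol 3 times in 8 stimuli
#' (target ratio 3/8); sequence 2 highlights every selectable symbol twice
#' in 18 stimuli (target ratio 2/18).
#'
#' @return a [mixing_matrix()] with rows (3/8, 5/8) and (2/18, 16/18).
#' @export
study_mixing <- function() {
  mixing_matrix(
    rbind(c(3 / 8, 5 / 8), c(2 / 18, 16 / 18)),
    group_names = c("sequence1", "sequence2")
  )
}

#' Read a mixing matrix from a JSON configuration file
#'
#' The file holds a list of rows, each a two-element array
#' `[target_fraction, nontarget_fraction]`; entries may be decimals or exact
#' rational strings such as `"3/8"`.
#'
#' @param path path to a JSON file.
#' @return a [mixing_matrix()].
#' @export
read_mixing <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- if (!is.null(raw$rows)) raw$rows else raw
  pr <- t(vapply(rows, function(r) parse_fraction(unlist(r)), numeric(2)))
  mixing_matrix(pr, group_names = if (!is.null(raw$group_names)) {
    unlist(raw$group_names)
  })
}

#' Write a mixing matrix to a JSON configuration file
#'
#' @param mixing a [mixing_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mixing <- function(mixing, path) {
  stopifnot(inherits(mixing, "mixing_matrix"))
  obj <- list(
    group_names = rownames(mixing),
    rows = lapply(seq_len(nrow(mixing)), function(g) unname(mixing[g, ]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bundled mixing-matrix presets
#'
#' A set of synthetic mixing matrices for learning-curve experiments,
#' ordered by ascending noise amplification factor, plus the study's
#' two-sequence mixing. Preset `pi3` extends `pi2` by the additional
#' sequence (2/10, 8/10); dropping that sequence lowers the NAF, which is
#' the configuration effect the learning-curve experiments probe. These
#' are illustrative presets shipped with the package, not measured
#' configurations.
#'
#' @return named list of [mixing_matrix()] objects.
#' @export
#' @examples
#' sapply(mixing_presets(), noise_amplification_factor)
mixing_presets <- function() {
  path <- system.file("extdata", "mixing_presets.json",
    package = "llpspeller", mustWork = TRUE
  )
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw$presets, function(p) {
    pr <- t(vapply(p$rows, function(r) parse_fraction(unlist(r)), numeric(2)))
    mixing_matrix(pr, group_names = unlist(p$group_names))
  })
}

#' Group-wise empirical feature means
#'
#' Computes the unweighted arithmetic mean feature vector of every sequence
#' group. These are the only data-dependent quantities the unsupervised
#' mean-map reconstruction consumes; per-epoch labels are never read.
#'
#' @param epochs an [epoch_set()].
#' @param groups optional character vector fixing the group order; defaults
#'   to the sorted unique group tags of `epochs`.
#' @return an object of class `group_means`: list with `means` (G x D
#'   matrix), `counts` (integer G), `groups` (character G).
#' @export
estimate_group_means <- function(epochs, groups = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  tags <- epochs$group
  if (anyNA(tags)) {
    stop("every epoch needs a group tag", call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- sort(unique(as.character(tags)))
  }
  missing <- setdiff(as.character(unique(tags)), groups)
  if (length(missing)) {
    stop(
      sprintf("epochs carry unknown group tags: %s", toString(missing)),
      call. = FALSE
    )
  }
  x <- epochs$features
  means <- matrix(NA_real_, length(groups), ncol(x),
    dimnames = list(groups, colnames(x))
  )
  counts <- integer(length(groups))
  for (g in seq_along(groups)) {
    idx <- which(tags == groups[g])
    if (!length(idx)) {
      stop(sprintf("group '%s' has no epochs", groups[g]), call. = FALSE)
    }
    counts[g] <- length(idx)
    means[g, ] <- colMeans(x[idx, , drop = FALSE])
  }
  structure(list(means = means, counts = counts, groups = groups),
    class = "group_means"
  )
}

#' Pseudoinverse reconstruction coefficients of a mixing matrix
#'
#' Returns the 2 x G coefficient matrix `(Pi' Pi)^-1 Pi'` mapping group
#' means to class means, computed through a QR least-squares factorization
#' rather than by forming the normal equations explicitly. Row 1 holds the
#' target coefficients, row 2 the non-target coefficients.
#'
#' @param mixing a [mixing_matrix()].
#' @return 2 x G numeric matrix with rows `target`, `nontarget`.
#' @export
#' @examples
#' round(pseudoinverse_coefficients(study_mixing()), 2)
pseudoinverse_coefficients <- function(mixing) {
  stopifnot(inherits(mixing, "mixing_matrix"))
  .check_mixing_rank(mixing)
  g <- nrow(mixing)
  coef <- qr.solve(qr(unclass(mixing)), diag(g))
  dimnames(coef) <- list(c("target", "nontarget"), rownames(mixing))
  coef
}

#' Reconstruct class means from group means
#'
#' Solves the linear system `group_means = Pi %*% class_means` in the
#' least-squares sense: for G = 2 this is the exact inverse solution, for
#' G > 2 the Moore-Penrose pseudoinverse solution. Exact when the group
#' means are exact mixtures of the class means (the homogeneity assumption).
#'
#' @param group_means a `group_means` object from [estimate_group_means()],
#'   or a bare G x D matrix.
#' @param mixing a [mixing_matrix()] with as many rows as there are groups.
#' @return an object of class `class_means`: list with `target` and
#'   `nontarget` D-vectors.
#' @export
reconstruct_class_means <- function(group_means, mixing) {
  mu <- if (inherits(group_means, "group_means")) {
    group_means$means
  } else {
    as.matrix(group_means)
  }
  if (nrow(mu) != nrow(mixing)) {
    stop(sprintf(
      "group means have %d rows but the mixing matrix has %d groups",
      nrow(mu), nrow(mixing)
    ), call. = FALSE)
  }
  coef <- pseudoinverse_coefficients(mixing)
  cm <- coef %*% mu
  structure(
    list(target = cm["target", ], nontarget = cm["nontarget", ]),
    class = "class_means"
  )
}

#' Noise amplification factor of a mixing matrix
#'
#' The factor by which the variance of the unsupervised class-mean estimate
#' is inflated relative to a supervised mean over the same total number of
#' epochs: the number of groups G times the squared Frobenius norm of the
#' pseudoinverse, i.e. G times the sum of all squared reconstruction
#' coefficients. Identity mixing (pure groups) gives the minimum of 4 for
#' G = 2; near-identical group proportions blow it up.
#'
#' @param mixing a [mixing_matrix()].
#' @return positive scalar.
#' @export
#' @examples
#' noise_amplification_factor(study_mixing())
noise_amplification_factor <- function(mixing) {
  coef <- pseudoinverse_coefficients(mixing)
  nrow(mixing) * sum(coef^2)
}

#' Label-dependent term of the squared loss
#'
#' The squared loss of a linear scorer splits into a label-free part and the
#' label-dependent term `2 w'(N+ mu+ - N- mu-)`, which depends on the data
#' only through the class means and class counts. This diagnostic computes
#' that term either per sample from the labels or from the class means;
#' the two routes agree to numerical precision, which is the identity that
#' justifies decoding from reconstructed means. Test-only: requires labels.
#'
#' @param epochs a labelled [epoch_set()].
#' @param w numeric weight vector of length D.
#' @param method `"class_means"` (default) or `"per_sample"`.
#' @return scalar.
#' @export
squared_loss_label_term <- function(epochs, w,
                                    method = c("class_means", "per_sample")) {
  method <- match.arg(method)
  stopifnot(inherits(epochs, "epoch_set"), length(w) == ncol(epochs$features))
  lab <- epochs$label
  if (anyNA(lab)) {
    stop("squared_loss_label_term needs fully labelled epochs", call. = FALSE)
  }
  x <- epochs$features
  pos <- lab == "target"
  if (method == "per_sample") {
    2 * sum(w * (colSums(x[pos, , drop = FALSE]) -
      colSums(x[!pos, , drop = FALSE])))
  } else {
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    mu_pos <- if (n_pos) colMeans(x[pos, , drop = FALSE]) else numeric(ncol(x))
    mu_neg <- if (n_neg) colMeans(x[!pos, , drop = FALSE]) else numeric(ncol(x))
    2 * sum(w * (n_pos * mu_pos - n_neg * mu_neg))
  }
}
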