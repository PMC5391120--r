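#' Epoch container: features plus per-epoch metadata
#'
#' The tabular unit every decoder-facing function consumes: one row per
#' stimulus epoch, with the feature vector, the sequence-group tag the label
#' proportions attach to, the trial (character) the epoch belongs to, the
#' set of grid symbols highlighted by the stimulus, and an optional true
#' label. Labels are carried for evaluation only; unsupervised code paths
#' never read them.
#'
#' @param features numeric N x D matrix, all values finite.
#' @param group character (or factor) length-N sequence-group tags.
#' @param trial integer length-N trial ids; defaults to 1.
#' @param highlighted optional list of N integer vectors of highlighted
#'   symbol indices (1-based grid positions).
#' @param label optional length-N vector with values `"target"`,
#'   `"nontarget"` or `NA` (unknown).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(features, group, trial = NULL, highlighted = NULL,
                      label = NULL) {
  features <- as.matrix(features)
  assert_finite_matrix(features, "epoch features")
  n <- nrow(features)
  group <- as.character(group)
  stopifnot(length(group) == n)
  if (is.null(trial)) {
    trial <- rep(1L, n)
  }
  trial <- as.integer(trial)
  stopifnot(length(trial) == n)
  if (!is.null(highlighted)) {
    stopifnot(is.list(highlighted), length(highlighted) == n)
    highlighted <- lapply(highlighted, as.integer)
  }
  if (is.null(label)) {
    label <- rep(NA_character_, n)
  } else {
    label <- as.character(label)
    stopifnot(length(label) == n)
    bad <- !is.na(label) & !label %in% c("target", "nontarget")
    if (any(bad)) {
      stop("labels must be 'target', 'nontarget' or NA", call. = FALSE)
    }
  }
  structure(
    list(
      features = features, group = group, trial = trial,
      highlighted = highlighted, label = label
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  n_lab <- sum(!is.na(x$label))
  cat(sprintf(
    "EpochSet: %d epochs x %d features, %d trials, groups: %s, %s\n",
    nrow(x$features), ncol(x$features), length(unique(x$trial)),
    toString(sort(unique(x$group))),
    if (n_lab) sprintf("%d labelled", n_lab) else "unlabelled"
  ))
  invisible(x)
}

#' @export
`[.epoch_set` <- function(x, i) {
  epoch_set(
    x$features[i, , drop = FALSE], x$group[i], x$trial[i],
    if (!is.null(x$highlighted)) x$highlighted[i], x$label[i]
  )
}

#' Number of epochs in an epoch set
#' @param x an [epoch_set()].
#' @return integer.
#' @export
n_epochs <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  nrow(x$features)
}

#' Concatenate epoch sets
#' @param ... [epoch_set()] objects with identical feature dimension.
#' @return an [epoch_set()].
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
    !inherits(sets[[1L]], "epoch_set")) {
    sets <- sets[[1L]]
  }
  stopifnot(all(vapply(sets, inherits, logical(1), "epoch_set")))
  hl <- lapply(sets, `[[`, "highlighted")
  has_hl <- !vapply(hl, is.null, logical(1))
  epoch_set(
    do.call(rbind, lapply(sets, `[[`, "features")),
    unlist(lapply(sets, `[[`, "group")),
    unlist(lapply(sets, `[[`, "trial")),
    if (all(has_hl)) do.call(c, hl) else NULL,
    unlist(lapply(sets, `[[`, "label"))
  )
}

#' Write an epoch set as a tabular file plus JSON metadata sidecar
#'
#' Features go to a plain TSV (one epoch per row); group tags, trial ids,
#' highlighted-symbol sets (0-based in the file) and labels go to
#' `<path>.meta.json`.
#'
#' @param epochs an [epoch_set()].
#' @param path path of the TSV file to write.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  utils::write.table(epochs$features, path,
    sep = "\t", row.names = FALSE,
    col.names = FALSE
  )
  meta <- list(
    group = epochs$group,
    trial = epochs$trial,
    highlighted = if (!is.null(epochs$highlighted)) {
      lapply(epochs$highlighted, function(h) h - 1L)
    },
    label = epochs$label
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
    auto_unbox = FALSE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path path of the TSV file.
#' @return an [epoch_set()].
#' @export
read_epochs <- function(path) {
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- NULL
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"),
    simplifyVector = TRUE, simplifyMatrix = FALSE
  )
  hl <- meta$highlighted
  if (!is.null(hl)) {
    hl <- lapply(hl, function(h) as.integer(h) + 1L)
  }
  label <- unlist(meta$label)
  if (is.null(label)) label <- NULL
  epoch_set(x, unlist(meta$group), unlist(meta$trial), hl, label)
}
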