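#' The 6 x 7 speller grid
#'
#' The default spelling matrix: 26 letters, the symbols
#' `"_" "." "," "!" "?" "<"` (space, punctuation and backspace), and 10
#' `"#"` visual blanks in the last 10 positions. Blanks equalize stimulus
#' brightness in the sparse sequence; they are never selectable and never
#' targets. Symbol indices are 1-based, row-major over the grid.
#'
#' @param rows,cols grid dimensions; `rows * cols` must equal the number of
#'   symbols.
#' @param symbols character vector of grid symbols.
#' @param blank symbol marking visual blanks.
#' @return an object of class `speller_grid`: list with `rows`, `cols`,
#'   `symbols` and logical `blank` flags.
#' @export
#' @examples
#' g <- speller_grid()
#' sum(!g$blank) # 32 selectable symbols
speller_grid <- function(rows = 6L, cols = 7L,
                         symbols = c(
                           LETTERS, "_", ".", ",", "!", "?", "<",
                           rep("#", 10L)
                         ),
                         blank = "#") {
  stopifnot(rows * cols == length(symbols))
  blank_flags <- symbols == blank
  structure(
    list(
      rows = as.integer(rows), cols = as.integer(cols),
      symbols = symbols, blank = blank_flags
    ),
    class = "speller_grid"
  )
}

#' @export
print.speller_grid <- function(x, ...) {
  cat(sprintf(
    "Speller grid %d x %d: %d selectable symbols, %d blanks\n",
    x$rows, x$cols, sum(!x$blank), sum(x$blank)
  ))
  print(matrix(x$symbols, x$rows, x$cols, byrow = TRUE), quote = FALSE)
  invisible(x)
}

# per-sequence stimulus bookkeeping: events per block, highlights per
# selectable symbol, symbols highlighted per event
.seq_spec <- function(sequence_id) {
  switch(as.character(sequence_id),
    "1" = list(n_events = 8L, per_symbol = 3L, event_size = 12L),
    "2" = list(n_events = 18L, per_symbol = 2L, event_size = 12L),
    stop("sequence_id must be 1 or 2", call. = FALSE)
  )
}

# Greedy constrained assignment of selectable symbols to the events of one
# block. Walks the events in order; at each event, symbols that would
# otherwise run out of non-adjacent future slots are forced in, the rest of
# the event is sampled with probability proportional to the remaining
# highlight count. Returns NULL on a dead end (caller restarts).
.try_block_assignment <- function(selectable, per_symbol, n_events, sizes,
                                  first_forbidden) {
  rem <- rep(per_symbol, length(selectable))
  events <- vector("list", n_events)
  prev <- integer(0)
  for (e in seq_len(n_events)) {
    k_remaining <- n_events - e + 1L
    forbidden <- if (e == 1L) first_forbidden else prev
    allowed <- which(rem > 0L)
    allowed <- setdiff(allowed, forbidden)
    # no-double-flash feasibility: ceil(k/2) appearances fit in k events
    if (any(rem > ceiling(k_remaining / 2))) {
      return(NULL)
    }
    forced <- allowed[rem[allowed] > ceiling((k_remaining - 1L) / 2)]
    need <- sizes[e]
    if (length(forced) > need || length(allowed) < need) {
      return(NULL)
    }
    rest <- setdiff(allowed, forced)
    extra <- need - length(forced)
    picked <- if (extra > 0L) {
      if (length(rest) == extra) {
        rest
      } else {
        sample(rest, extra, prob = rem[rest])
      }
    } else {
      integer(0)
    }
    ev <- sort(c(forced, picked))
    rem[ev] <- rem[ev] - 1L
    events[[e]] <- ev
    prev <- ev
  }
  if (any(rem != 0L)) {
    return(NULL)
  }
  events
}

#' Generate one constrained stimulus block
#'
#' Sequence 1 blocks are 8 events in which every selectable symbol is
#' highlighted exactly 3 times and no blanks appear; sequence 2 blocks are
#' 18 events in which every selectable symbol is highlighted exactly twice
#' and visual blanks fill each event up to 12 highlights. No selectable
#' symbol appears in two consecutive events (double-flash avoidance);
#' blanks are exempt, since a sequence-2 block needs 152 blank slots, more
#' than 10 blanks could supply without consecutive repeats. The assignment
#' is randomized subject to these constraints; construction restarts on
#' dead ends, up to `max_restarts` times.
#'
#' @param grid a [speller_grid()].
#' @param sequence_id 1 or 2.
#' @param seed optional integer seed.
#' @param prev_event integer vector of symbol indices highlighted by the
#'   event immediately preceding this block (enforces the double-flash rule
#'   across block boundaries); default none.
#' @param max_restarts restart cap for the randomized construction.
#' @return list of events, each a sorted integer vector of 12 highlighted
#'   symbol indices.
#' @export
generate_block <- function(grid, sequence_id, seed = NULL,
                           prev_event = integer(0), max_restarts = 10000L) {
  spec <- .seq_spec(sequence_id)
  selectable <- which(!grid$blank)
  blanks <- which(grid$blank)
  with_seed(seed, {
    n_sel_slots <- length(selectable) * spec$per_symbol
    prev_sel <- match(intersect(prev_event, selectable), selectable)
    for (attempt in seq_len(max_restarts)) {
      if (sequence_id == 1L) {
        sizes <- rep(spec$event_size, spec$n_events)
        if (n_sel_slots != sum(sizes)) {
          stop("sequence-1 block cannot tile: counts do not add up",
            call. = FALSE
          )
        }
      } else {
        # distribute the selectable highlights over events: at least 2 per
        # event (so that at most 10 blanks are needed to fill to 12)
        base <- 3L
        sizes <- rep(base, spec$n_events)
        extras <- n_sel_slots - sum(sizes)
        if (extras < 0L) {
          sizes <- rep(2L, spec$n_events)
          extras <- n_sel_slots - sum(sizes)
        }
        if (extras > 0L) {
          bump <- sample(rep(seq_len(spec$n_events),
            length.out = extras * 4L
          ), extras)
          for (b in bump) sizes[b] <- sizes[b] + 1L
        }
        if (any(sizes > spec$event_size) ||
          any(spec$event_size - sizes > length(blanks))) {
          next
        }
      }
      assign <- .try_block_assignment(
        selectable, spec$per_symbol, spec$n_events, sizes, prev_sel
      )
      if (is.null(assign)) {
        next
      }
      events <- vector("list", spec$n_events)
      ok <- TRUE
      for (e in seq_len(spec$n_events)) {
        sel <- selectable[assign[[e]]]
        n_blank <- spec$event_size - length(sel)
        if (n_blank > length(blanks)) {
          ok <- FALSE
          break
        }
        bl <- if (n_blank > 0L) sample(blanks, n_blank) else integer(0)
        events[[e]] <- sort(c(sel, bl))
      }
      if (ok) {
        return(events)
      }
    }
    stop(sprintf(
      paste(
        "could not generate a feasible sequence-%d block in %d restarts",
        "(double-flash / count constraints)"
      ),
      sequence_id, max_restarts
    ), call. = FALSE)
  })
}

#' Generate the stimulus schedule of one trial
#'
#' A trial (one character selection) concatenates 4 sequence-1 blocks and 2
#' sequence-2 blocks - 68 highlighting events in total - in a randomly
#' interleaved order. Block-level interleaving (default) randomizes the
#' order of whole blocks, preserving the within-block count guarantees;
#' `interleave = "event"` merges the blocks event-by-event in random order
#' while preserving each block's internal event order. In both modes the
#' double-flash constraint on selectable symbols is enforced across block
#' boundaries.
#'
#' @param grid a [speller_grid()].
#' @param seed optional integer seed.
#' @param trial_id integer id stored in the schedule.
#' @param n_seq1,n_seq2 number of sequence-1 / sequence-2 blocks.
#' @param interleave `"block"` or `"event"`.
#' @param max_restarts restart cap passed to the randomized construction.
#' @return an object of class `stimulus_schedule`: list with `events` (each
#'   `list(highlighted, group, block)`) and `trial_id`.
#' @export
generate_trial <- function(grid, seed = NULL, trial_id = 1L,
                           n_seq1 = 4L, n_seq2 = 2L,
                           interleave = c("block", "event"),
                           max_restarts = 10000L) {
  interleave <- match.arg(interleave)
  with_seed(seed, {
    block_seq <- sample(rep(c(1L, 2L), c(n_seq1, n_seq2)))
    selectable <- which(!grid$blank)
    if (interleave == "block") {
      events <- list()
      prev <- integer(0)
      for (b in seq_along(block_seq)) {
        blk <- generate_block(grid, block_seq[b],
          prev_event = prev,
          max_restarts = max_restarts
        )
        events <- c(events, lapply(blk, function(h) {
          list(highlighted = h, group = block_seq[b], block = b)
        }))
        prev <- blk[[length(blk)]]
      }
    } else {
      blocks <- lapply(seq_along(block_seq), function(b) {
        generate_block(grid, block_seq[b], max_restarts = max_restarts)
      })
      events <- .merge_blocks_eventwise(
        blocks, block_seq, selectable, max_restarts
      )
    }
    structure(list(events = events, trial_id = as.integer(trial_id)),
      class = "stimulus_schedule"
    )
  })
}

# Random merge of block event streams preserving within-block order, such
# that consecutive merged events never share a selectable symbol.
.merge_blocks_eventwise <- function(blocks, block_seq, selectable,
                                    max_restarts) {
  for (attempt in seq_len(max_restarts)) {
    heads <- rep(1L, length(blocks))
    lens <- lengths(blocks)
    out <- vector("list", sum(lens))
    prev <- integer(0)
    ok <- TRUE
    for (k in seq_along(out)) {
      open <- which(heads <= lens)
      cand <- open[vapply(open, function(b) {
        h <- blocks[[b]][[heads[b]]]
        !length(intersect(intersect(h, selectable), prev))
      }, logical(1))]
      if (!length(cand)) {
        ok <- FALSE
        break
      }
      b <- if (length(cand) == 1L) cand else {
        sample(cand, 1L, prob = lens[cand] - heads[cand] + 1L)
      }
      h <- blocks[[b]][[heads[b]]]
      out[[k]] <- list(highlighted = h, group = block_seq[b], block = b)
      heads[b] <- heads[b] + 1L
      prev <- h
    }
    if (ok) {
      return(out)
    }
  }
  stop("could not interleave blocks without a double flash", call. = FALSE)
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  gr <- vapply(x$events, `[[`, integer(1), "group")
  cat(sprintf(
    "Stimulus schedule (trial %d): %d events (%s)\n",
    x$trial_id, length(x$events),
    paste(sprintf("%d of sequence %s", tabulate(gr), seq_along(tabulate(gr))),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' Label the events of a schedule for a given attended symbol
#'
#' An event is a target iff the attended symbol is among its highlights.
#' By construction of the paradigm the label counts per trial are fixed:
#' 16 targets and 52 non-targets, whichever selectable symbol is attended.
#'
#' @param schedule a [generate_trial()] schedule.
#' @param attended integer index of the attended symbol.
#' @param grid a [speller_grid()] (to reject blank symbols).
#' @return character vector of `"target"` / `"nontarget"` labels.
#' @export
label_events <- function(schedule, attended, grid) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (attended < 1L || attended > length(grid$symbols) ||
    grid$blank[attended]) {
    stop("the attended symbol must be a selectable (non-blank) grid symbol",
      call. = FALSE
    )
  }
  vapply(schedule$events, function(ev) {
    if (attended %in% ev$highlighted) "target" else "nontarget"
  }, character(1))
}

#' Recover the mixing matrix implied by a schedule
#'
#' Counts, for every selectable symbol, the fraction of each group's events
#' that highlight it. The paradigm guarantees this fraction is identical
#' for every selectable symbol (that is what makes the label proportions
#' known without labels); if the counts disagree across symbols the
#' schedule violates the paradigm and an error is raised.
#'
#' @param schedule a [generate_trial()] schedule (or list of event lists).
#' @param grid a [speller_grid()].
#' @return a [mixing_matrix()] with one row per sequence group.
#' @export
mixing_from_schedule <- function(schedule, grid) {
  events <- if (inherits(schedule, "stimulus_schedule")) {
    schedule$events
  } else {
    schedule
  }
  groups <- sort(unique(vapply(events, `[[`, integer(1), "group")))
  selectable <- which(!grid$blank)
  rows <- matrix(NA_real_, length(groups), 2L)
  for (gi in seq_along(groups)) {
    evs <- Filter(function(e) e$group == groups[gi], events)
    counts <- vapply(
      selectable,
      function(s) sum(vapply(evs, function(e) s %in% e$highlighted, logical(1))),
      integer(1)
    )
    if (length(unique(counts)) != 1L) {
      stop(sprintf(
        paste(
          "group %s highlights selectable symbols unequally",
          "(%d to %d times): the label proportions are not well defined"
        ),
        groups[gi], min(counts), max(counts)
      ), call. = FALSE)
    }
    rows[gi, 1L] <- counts[1L] / length(evs)
    rows[gi, 2L] <- 1 - rows[gi, 1L]
  }
  mixing_matrix(rows, group_names = paste0("sequence", groups))
}

#' Spelling timing arithmetic
#'
#' Pure arithmetic of the paradigm's pacing: with a 250 ms stimulus onset
#' asynchrony, 68 events span 17 s of highlighting; adding the cue and
#' feedback phases gives the per-character budget and the maximal spelling
#' rate.
#'
#' @param soa_ms stimulus onset asynchrony in ms.
#' @param n_events highlighting events per trial.
#' @param cue_s,feedback_s cue and feedback durations in seconds.
#' @return list with `highlight_s`, `trial_s` and `chars_per_min`.
#' @export
#' @examples
#' spelling_timing() # 17 s highlighting, 25 s per character, 2.4 char/min
spelling_timing <- function(soa_ms = 250, n_events = 68L, cue_s = 4,
                            feedback_s = 4) {
  highlight_s <- soa_ms * n_events / 1000
  trial_s <- highlight_s + cue_s + feedback_s
  list(
    highlight_s = highlight_s,
    trial_s = trial_s,
    chars_per_min = 60 / trial_s
  )
}

#' Write schedules as JSON lines
#'
#' One event per line: `trial_id`, `group_tag`, `block_id` and the 0-based
#' `highlighted` symbol indices.
#'
#' @param schedules a [generate_trial()] schedule or list of schedules.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedules <- function(schedules, path) {
  if (inherits(schedules, "stimulus_schedule")) {
    schedules <- list(schedules)
  }
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (sch in schedules) {
    for (ev in sch$events) {
      line <- jsonlite::toJSON(
        list(
          trial_id = sch$trial_id, group_tag = ev$group,
          block_id = ev$block, highlighted = ev$highlighted - 1L
        ),
        auto_unbox = TRUE, digits = NA
      )
      writeLines(line, con)
    }
  }
  invisible(path)
}

#' Read schedules written by [write_schedules()]
#'
#' @param path path of the JSON-lines file.
#' @return list of `stimulus_schedule` objects, one per trial id.
#' @export
read_schedules <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  trials <- vapply(recs, `[[`, integer(1), "trial_id")
  lapply(unique(trials), function(t) {
    evs <- recs[trials == t]
    structure(
      list(
        events = lapply(evs, function(r) {
          list(
            highlighted = as.integer(r$highlighted) + 1L,
            group = as.integer(r$group_tag),
            block = as.integer(r$block_id)
          )
        }),
        trial_id = as.integer(t)
      ),
      class = "stimulus_schedule"
    )
  })
}
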