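# Task timelines for the three stimulation runs (emotional clips, movie
# scenes, music), laid out from their printed block structure.  Onsets are
# 0-based seconds; intervals are half-open [onset, onset + duration).

.builtin_runs <- function() {
  list(
    # 5-s fixation, four stimulation blocks (two 55-s neutral, one 110-s joy,
    # one 110-s fear; within-block 1-s inter-clip fixations are part of the
    # block totals) separated by 15-s fixations.  Block order is
    # counterbalanced in the study and irrelevant to the totals.
    clips = data.frame(
      condition = c("fixation", "neutral", "fixation", "joy", "fixation",
                    "neutral", "fixation", "fear"),
      duration  = c(5, 55, 15, 110, 15, 55, 15, 110),
      stringsAsFactors = FALSE),
    # 5-s fixation, Farewell (Stepmom) scene, 20-s fixation, Snakes scene,
    # 20-s closing fixation.
    movie = data.frame(
      condition = c("fixation", "farewell", "fixation", "snakes", "fixation"),
      duration  = c(5, 501, 20, 321, 20),
      stringsAsFactors = FALSE),
    # 5-s fixation, one musical piece, 20-s closing fixation.
    music = data.frame(
      condition = c("fixation", "music", "fixation"),
      duration  = c(5, 423, 20),
      stringsAsFactors = FALSE)
  )
}

#' Build a task run timeline from its block structure
#'
#' Lays stimulation and fixation blocks back-to-back and returns the event
#' table together with the total run duration.  The three runs of the study
#' design are built in (`"clips"`: 380 s, `"movie"`: 867 s, `"music"`:
#' 448 s); arbitrary designs can be given as a custom block table.
#'
#' @param run_spec either the name of a built-in run (`"clips"`, `"movie"`,
#'   `"music"`) or a `data.frame` with columns `condition` (character) and
#'   `duration` (seconds, all > 0).
#' @param name run label stored in the result (defaults to the run name or
#'   `"custom"`).
#' @return an object of class `TaskTimeline`: a list with `events` (a
#'   `data.frame` with `onset`, `duration`, `condition`), `total_s` and
#'   `name`.
#' @examples
#' tl <- build_run_timeline("movie")
#' tl$total_s  # 867
#' @export
build_run_timeline <- function(run_spec, name = NULL) {
  if (is.character(run_spec) && length(run_spec) == 1L) {
    runs <- .builtin_runs()
    if (!run_spec %in% names(runs)) {
      stopf("unknown run '%s'; supply one of %s or a custom block table",
            run_spec, paste(sQuote(names(runs)), collapse = ", "))
    }
    blocks <- runs[[run_spec]]
    if (is.null(name)) name <- run_spec
  } else if (is.data.frame(run_spec)) {
    blocks <- run_spec
    if (!all(c("condition", "duration") %in% names(blocks))) {
      stopf("custom run spec needs 'condition' and 'duration' columns")
    }
    if (is.null(name)) name <- "custom"
  } else {
    stopf("run_spec must be a run name or a block data.frame")
  }
  if (nrow(blocks) == 0L || any(!is.finite(blocks$duration)) ||
      any(blocks$duration <= 0)) {
    stopf("all block durations must be finite and > 0")
  }
  onset <- cumsum(c(0, blocks$duration[-nrow(blocks)]))
  events <- data.frame(onset = onset,
                       duration = blocks$duration,
                       condition = as.character(blocks$condition),
                       stringsAsFactors = FALSE)
  structure(list(events = events,
                 total_s = sum(blocks$duration),
                 name = name),
            class = "TaskTimeline")
}

#' @export
print.TaskTimeline <- function(x, ...) {
  cat(sprintf("TaskTimeline '%s': %d events, total %g s\n",
              x$name, nrow(x$events), x$total_s))
  print(x$events)
  invisible(x)
}

#' Number of fMRI volumes needed to cover a run
#'
#' Smallest integer count of repetition times (TRs) covering `total_s`
#' seconds, i.e. `ceiling(total_s / tr)`.  Reproduces the acquisition
#' counts of the study design: 254 volumes for the 380-s clips runs, 578
#' for the 867-s movie run, 299 for the 448-s music run at TR = 1.5 s.
#'
#' @param total_s run duration in seconds (> 0).
#' @param tr repetition time in seconds (> 0, default 1.5).
#' @return integer volume count.
#' @examples
#' required_volumes(867)  # 578
#' @export
required_volumes <- function(total_s, tr = 1.5) {
  if (!is_scalar_num(total_s) || total_s <= 0) stopf("total_s must be > 0")
  if (!is_scalar_num(tr) || tr <= 0) stopf("tr must be > 0")
  # epsilon guards float noise so an exact multiple of tr never rounds up
  as.integer(ceiling(total_s / tr - 1e-9))
}

#' Extract scene windows from a timeline
#'
#' Returns the `[start, end]` second windows of all events with the given
#' condition label, e.g. the two movie scenes used by the reactivity
#' analysis.
#'
#' @param timeline a `TaskTimeline`.
#' @param condition condition label to select.
#' @return a matrix with one row per event and columns `start`, `end`.
#' @export
scene_windows <- function(timeline, condition) {
  stopifnot(inherits(timeline, "TaskTimeline"))
  ev <- timeline$events[timeline$events$condition == condition, , drop = FALSE]
  if (nrow(ev) == 0L) stopf("no events with condition '%s'", condition)
  cbind(start = ev$onset, end = ev$onset + ev$duration)
}

#' Write / read a BIDS-style events table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`.
#'
#' @param timeline a `TaskTimeline`.
#' @param path output file path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns a `TaskTimeline`.
#' @export
write_events_tsv <- function(timeline, path) {
  stopifnot(inherits(timeline, "TaskTimeline"))
  df <- timeline$events
  names(df) <- c("onset", "duration", "trial_type")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param name run label for the reconstructed timeline.
#' @export
read_events_tsv <- function(path, name = "events") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  build_run_timeline(data.frame(condition = df$trial_type,
                                duration = df$duration),
                     name = name)
}
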