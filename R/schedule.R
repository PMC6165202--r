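# Event schedules for the two paradigms. A schedule is a tibble with one row
# per event (label, onset_s, duration_s) and a total_duration attribute, so
# it composes with dplyr verbs while staying a first-class domain object.

new_schedule <- function(label, onset_s, duration_s, total_duration = NULL) {
  sch <- tibble::tibble(
    label = as.character(label),
    onset_s = as.numeric(onset_s),
    duration_s = as.numeric(duration_s)
  )
  if (is.null(total_duration)) {
    total_duration <- if (nrow(sch)) max(sch$onset_s + sch$duration_s) else 0
  }
  attr(sch, "total_duration") <- total_duration
  class(sch) <- c("eeg_schedule", class(sch))
  validate_schedule(sch)
  sch
}

validate_schedule <- function(sch) {
  if (nrow(sch) == 0) return(invisible(sch))
  if (any(sch$onset_s < 0)) abort("schedule onsets must be >= 0")
  if (any(sch$duration_s <= 0)) abort("schedule durations must be > 0")
  if (is.unsorted(sch$onset_s)) abort("schedule events must be sorted by onset")
  offs <- sch$onset_s + sch$duration_s
  if (any(sch$onset_s[-1] < offs[-nrow(sch)] - 1e-9)) {
    abort("schedule events must not overlap")
  }
  if (attr(sch, "total_duration") < max(offs) - 1e-9) {
    abort("total_duration shorter than last event offset")
  }
  invisible(sch)
}

#' Total duration of a schedule
#' @param schedule An `eeg_schedule`.
#' @return Duration in seconds.
#' @export
schedule_duration <- function(schedule) attr(schedule, "total_duration")

#' Eyes-closed / eyes-open block schedule
#'
#' Alternating eyes-closed (EC) and eyes-open (EO) blocks, EC first,
#' repeated `reps` times with no gaps. The defaults give the standard
#' 30 s x 6 repetition resting protocol (12 blocks, 360 s).
#'
#' @param block_s Block length in seconds (> 0).
#' @param reps Number of EC/EO repetitions (>= 1).
#' @return An `eeg_schedule` tibble with columns `label`, `onset_s`,
#'   `duration_s`.
#' @export
#' @examples
#' generate_ec_eo_schedule(30, 6)
generate_ec_eo_schedule <- function(block_s = 30, reps = 6) {
  if (block_s <= 0) abort("block_s must be > 0")
  if (reps < 1) abort("reps must be >= 1")
  n <- 2L * as.integer(reps)
  new_schedule(
    label = rep(c("EC", "EO"), reps),
    onset_s = (seq_len(n) - 1L) * block_s,
    duration_s = rep(block_s, n)
  )
}

#' Main-experiment schedule: mental arithmetic vs light cognitive trials
#'
#' Builds the trial timeline of the main paradigm. Each session opens with an
#' initial rest (5 s blank plus 10 s rest, emitted as one `REST` event) and
#' contains `trials_per_cond` mental-arithmetic (`MA`) and `trials_per_cond`
#' light-cognitive (`LC`) trials in randomized order, balanced within the
#' session. A trial is a 5 s `INSTRUCTION` event, a 10 s task event (`MA` or
#' `LC`), and a rest drawn uniformly from `rest_range_s`. Sessions are laid
#' out contiguously.
#'
#' @param sessions Number of sessions (>= 1).
#' @param trials_per_cond Trials per condition per session (>= 1).
#' @param rest_range_s Length-2 numeric, min/max inter-trial rest in seconds.
#' @param seed Optional integer; fixes the trial order and rest durations.
#' @param instruction_s,task_s Instruction and task durations in seconds.
#' @param initial_rest_s Initial per-session rest (blank + fixation), seconds.
#' @return An `eeg_schedule` tibble.
#' @export
#' @examples
#' sch <- generate_main_schedule(5, 10, c(10, 15), seed = 1)
#' table(sch$label)
generate_main_schedule <- function(sessions = 5, trials_per_cond = 10,
                                   rest_range_s = c(10, 15), seed = NULL,
                                   instruction_s = 5, task_s = 10,
                                   initial_rest_s = 15) {
  if (sessions < 1 || trials_per_cond < 1) abort("counts must be >= 1")
  if (length(rest_range_s) != 2 || rest_range_s[1] > rest_range_s[2] ||
      rest_range_s[1] < 0) {
    abort("rest_range_s must be (min, max) with 0 <= min <= max")
  }
  gen <- function() {
    lab <- character(0); ons <- numeric(0); dur <- numeric(0)
    t <- 0
    for (s in seq_len(sessions)) {
      lab <- c(lab, "REST"); ons <- c(ons, t); dur <- c(dur, initial_rest_s)
      t <- t + initial_rest_s
      order_s <- sample(rep(c("MA", "LC"), each = trials_per_cond))
      for (cond in order_s) {
        lab <- c(lab, "INSTRUCTION"); ons <- c(ons, t); dur <- c(dur, instruction_s)
        t <- t + instruction_s
        lab <- c(lab, cond); ons <- c(ons, t); dur <- c(dur, task_s)
        t <- t + task_s
        rest <- runif(1, rest_range_s[1], rest_range_s[2])
        lab <- c(lab, "REST"); ons <- c(ons, t); dur <- c(dur, rest)
        t <- t + rest
      }
    }
    new_schedule(lab, ons, dur, total_duration = t)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Write / read a schedule as CSV
#'
#' Plain CSV with columns `label`, `onset_s`, `duration_s`; the total
#' duration is recovered as the last event offset on read.
#'
#' @param schedule An `eeg_schedule`.
#' @param path File path.
#' @return `write_schedule_csv()` returns `path` invisibly;
#'   `read_schedule_csv()` returns an `eeg_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  readr::write_csv(as.data.frame(schedule), path)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  new_schedule(df$label, df$onset_s, df$duration_s)
}
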