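#' All counterbalanced orders of a condition set
#'
#' @param conditions character vector of condition labels.
#' @return A list of character vectors, one per permutation.
#' @export
condition_orders <- function(conditions) {
  n <- length(conditions)
  if (n == 0) return(list())
  if (n == 1) return(list(conditions))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in condition_orders(conditions[-i])) {
      out[[length(out) + 1L]] <- c(conditions[i], rest)
    }
  }
  out
}

#' Build a block-design paradigm
#'
#' Expands an ordered list of condition runs into a gapless, sorted block
#' table. Each run alternates `block_s` seconds of task with `rest_s` seconds
#' of rest until `run_length_s` is filled (defaults: 15 s task + 15 s rest
#' cycles in a 120 s run, i.e. 4 task blocks per run). The whole sequence of
#' runs is repeated `n_repeats` times.
#'
#' @param order character vector of condition labels, one per run, e.g.
#'   `c("live", "static")`.
#' @param n_repeats how many times the run order is repeated.
#' @param block_s task block duration (s).
#' @param rest_s rest block duration (s).
#' @param run_length_s duration of one condition run (s); must be a multiple
#'   of `block_s + rest_s`.
#'
#' @return A tibble of class `fnirs_paradigm` with columns `onset`,
#'   `duration`, `condition` (task label or `"rest"`) and `run`, plus a
#'   `run_length_s` attribute.
#' @export
#' @examples
#' p <- generate_paradigm(c("live", "static"), n_repeats = 2)
#' sum(p$condition != "rest")  # 16 task blocks
generate_paradigm <- function(order, n_repeats = 1L, block_s = 15,
                              rest_s = 15, run_length_s = 120) {
  if (n_repeats < 1) abort("`n_repeats` must be a positive integer.")
  if (block_s <= 0 || rest_s <= 0) abort("block durations must be positive.")
  cycle <- block_s + rest_s
  n_cycles <- run_length_s / cycle
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    abort("`run_length_s` must be a whole number of task+rest cycles.")
  }
  n_cycles <- as.integer(round(n_cycles))
  runs <- rep(order, n_repeats)
  rows <- list()
  t0 <- 0
  for (i in seq_along(runs)) {
    for (k in seq_len(n_cycles)) {
      rows[[length(rows) + 1L]] <- tibble(
        onset = c(t0, t0 + block_s),
        duration = c(block_s, rest_s),
        condition = c(runs[i], "rest"),
        run = i
      )
      t0 <- t0 + cycle
    }
  }
  out <- if (length(rows)) bind_rows(rows) else {
    tibble(onset = double(), duration = double(),
           condition = character(), run = integer())
  }
  out <- arrange(out, .data$onset)
  validate_paradigm(out)
  structure(out, run_length_s = run_length_s,
            class = c("fnirs_paradigm", class(out)))
}

#' Validate a block table
#'
#' Checks that blocks are sorted by onset and non-overlapping; used on both
#' generated paradigms and event tables read from disk.
#'
#' @param events a data frame with `onset` and `duration` columns (s).
#' @return The input, invisibly, on success.
#' @export
validate_paradigm <- function(events) {
  stopifnot(all(c("onset", "duration") %in% names(events)))
  if (nrow(events) < 2) return(invisible(events))
  if (is.unsorted(events$onset)) abort("blocks must be sorted by onset.")
  ends <- events$onset + events$duration
  bad <- which(events$onset[-1] < ends[-length(ends)] - 1e-9)
  if (length(bad)) {
    abort(sprintf("overlapping blocks at rows: %s",
                  paste(bad + 1L, collapse = ", ")))
  }
  invisible(events)
}

#' Total paradigm duration in seconds
#' @param paradigm a paradigm/event tibble.
#' @return duration (s).
#' @export
paradigm_duration <- function(paradigm) {
  if (nrow(paradigm) == 0) return(0)
  max(paradigm$onset + paradigm$duration)
}

# Indicator (boxcar) of one condition's task blocks on a sampling grid.
condition_boxcar <- function(paradigm, condition, n_samples, rate) {
  t <- (seq_len(n_samples) - 1) / rate
  box <- numeric(n_samples)
  blocks <- paradigm[paradigm$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(blocks))) {
    box[t >= blocks$onset[i] & t < blocks$onset[i] + blocks$duration[i]] <- 1
  }
  box
}
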