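#' Per-period inter-brain coherence for one dyad
#'
#' Computes wavelet coherence between the two partners' ROI residual series
#' separately within every condition run of the paradigm, averages the
#' magnitude-squared coherence over time within each run, and then averages
#' across that condition's repeats, giving one MSC value per grid period per
#' condition. Residuals are expected to come from the activation GLM on the
#' ROI-averaged HHb series, so common task effects are already removed.
#'
#' @param res_a,res_b full-session residual series of the selected ROI for
#'   partners A and B (numeric vectors, same rate and length).
#' @param paradigm the shared paradigm (run/condition structure).
#' @param rate sampling rate in Hz.
#' @param grid a [build_scale_grid()].
#' @param conditions task conditions to evaluate; default every non-rest
#'   condition in the paradigm. Missing ones are an error.
#' @param paradigm_b partner B's paradigm when it differs (shuffled pairs
#'   may have different counterbalanced orders); the k-th run of each
#'   condition in A is then matched with the k-th in B.
#' @param ... passed to [wavelet_coherence()] (wavelet order, smoothing).
#' @return A tibble `condition`, `period_s`, `msc`.
#' @export
dyad_coherence <- function(res_a, res_b, paradigm, rate,
                           grid = build_scale_grid(), conditions = NULL,
                           paradigm_b = paradigm, ...) {
  condition_runs <- function(par) {
    par %>%
      group_by(.data$run) %>%
      summarise(start = min(.data$onset),
                end = max(.data$onset + .data$duration),
                condition = setdiff(unique(.data$condition), "rest")[1],
                .groups = "drop")
  }
  runs_a <- condition_runs(paradigm)
  runs_b <- condition_runs(paradigm_b)
  present <- intersect(stats::na.omit(runs_a$condition),
                       stats::na.omit(runs_b$condition))
  conditions <- conditions %||% present
  missing <- setdiff(conditions, present)
  if (length(missing)) {
    abort(sprintf("condition(s) absent from paradigm: %s",
                  paste(missing, collapse = ", ")))
  }
  segment <- function(res, start, end) {
    i0 <- max(1L, floor(start * rate) + 1L)
    i1 <- min(length(res), ceiling(end * rate))
    res[i0:i1]
  }
  out <- lapply(conditions, function(cond) {
    ra <- runs_a[runs_a$condition == cond, , drop = FALSE]
    rb <- runs_b[runs_b$condition == cond, , drop = FALSE]
    n_runs <- min(nrow(ra), nrow(rb))
    per_run <- lapply(seq_len(n_runs), function(i) {
      xa <- segment(res_a, ra$start[i], ra$end[i])
      xb <- segment(res_b, rb$start[i], rb$end[i])
      n <- min(length(xa), length(xb))
      wtc <- wavelet_coherence(xa[seq_len(n)], xb[seq_len(n)], rate, grid, ...)
      rowMeans(wtc$msc)
    })
    tibble(condition = cond, period_s = grid$periods,
           msc = rowMeans(do.call(cbind, per_run)))
  })
  bind_rows(out)
}

#' Cross-site shuffled (surrogate) dyad assignment
#'
#' Builds the permutation null: participants are re-paired across sites so
#' that every shuffled pair consists of one participant from each
#' laboratory (keeping shuffled partners comparable with real partners) and
#' no shuffled pair reproduces a real pair (a cross-site derangement).
#' Deterministic for a given seed.
#'
#' @param real tibble of real pairs with columns `uk` and `us` (participant
#'   identifiers).
#' @param n_pairs number of shuffled pairs to return; defaults to the
#'   number of real pairs. More than `nrow(real)` pairs are drawn from
#'   additional independent derangements.
#' @param seed integer seed.
#' @return A tibble `uk`, `us`, `kind = "shuffled"`.
#' @export
make_shuffled_pairs <- function(real, n_pairs = nrow(real), seed = 1L) {
  n <- nrow(real)
  if (n < 2) abort("a derangement needs at least 2 real dyads.")
  derange <- function() {
    repeat {
      p <- sample.int(n)
      if (all(p != seq_len(n))) return(p)
    }
  }
  with_seed(seed, {
    rows <- list()
    while (length(rows) * n < n_pairs) {
      p <- derange()
      rows[[length(rows) + 1L]] <- tibble(uk = real$uk, us = real$us[p])
    }
  })
  out <- bind_rows(rows)[seq_len(n_pairs), ]
  out$kind <- "shuffled"
  out
}

#' Average coherence profile across dyads
#'
#' Mean and standard deviation of MSC over dyads, per period, condition and
#' dyad kind.
#'
#' @param results long tibble with columns `dyad`, `kind`, `condition`,
#'   `period_s`, `msc` (one row per dyad x condition x period).
#' @return A tibble of class `coherence_profile`: `period_s`, `condition`,
#'   `kind`, `mean`, `sd`, `n`.
#' @export
coherence_profile <- function(results) {
  stopifnot(all(c("dyad", "kind", "condition", "period_s", "msc")
                %in% names(results)))
  out <- results %>%
    group_by(.data$period_s, .data$condition, .data$kind) %>%
    summarise(mean = mean(.data$msc), sd = sd(.data$msc), n = n(),
              .groups = "drop") %>%
    mutate(sd = ifelse(is.na(.data$sd), 0, .data$sd))
  class(out) <- c("coherence_profile", class(out))
  out
}

#' Plot coherence profiles
#'
#' Mean MSC per period with a +/- 1 SD ribbon, coloured by condition and
#' faceted by dyad kind (real vs shuffled).
#'
#' @param object a [coherence_profile()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.coherence_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$period_s, y = .data$mean,
                                       colour = .data$condition,
                                       fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kind) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "period (s)", y = "magnitude-squared coherence") +
    ggplot2::theme_minimal()
}
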