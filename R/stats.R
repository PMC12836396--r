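#' Period-wise paired condition test within real dyads
#'
#' Paired t-test (two-sided) of live vs static MSC across dyads, one test
#' per grid period. No multiplicity correction is applied by default; a
#' BH-FDR column is added when `fdr = TRUE`.
#'
#' @param results long tibble with columns `dyad`, `condition`, `period_s`,
#'   `msc` for the real dyads (two conditions per dyad per period).
#' @param conditions the two condition labels to contrast, ordered
#'   (first - second).
#' @param fdr add a Benjamini-Hochberg adjusted column.
#' @return A tibble: `period_s`, `mean_diff`, `t`, `dof`, `p`
#'   (and `p_fdr` when requested).
#' @export
per_period_condition_test <- function(results,
                                      conditions = c("live", "static"),
                                      fdr = FALSE) {
  wide <- results %>%
    filter(.data$condition %in% conditions) %>%
    tidyr::pivot_wider(id_cols = c("dyad", "period_s"),
                       names_from = "condition", values_from = "msc")
  if (!all(conditions %in% names(wide))) {
    abort("both conditions must be present in `results`.")
  }
  out <- wide %>%
    group_by(.data$period_s) %>%
    summarise(res = list({
      d <- .data[[conditions[1]]] - .data[[conditions[2]]]
      if (length(d) < 2) abort("need at least 2 dyads.")
      if (sd(d) == 0) {
        tibble(mean_diff = mean(d), t = 0, dof = length(d) - 1, p = 1)
      } else {
        tt <- t.test(d)
        tibble(mean_diff = mean(d), t = unname(tt$statistic),
               dof = unname(tt$parameter), p = tt$p.value)
      }
    }), .groups = "drop") %>%
    tidyr::unnest("res")
  if (fdr) out$p_fdr <- p.adjust(out$p, method = "BH")
  out
}

#' Period-wise 2x2 ANOVA: dyad type x condition
#'
#' Fixed-effects two-way ANOVA with interaction on the four-cell layout
#' (real/shuffled x live/static), treating each dyad x condition MSC value
#' as one observation, fitted per period. With 20 real and 20 shuffled
#' dyads this gives the interaction F(1, 76). A repeated-measures variant
#' (condition within dyad; `repeated = TRUE`) is available but not the
#' default.
#'
#' @param results long tibble with columns `dyad`, `kind` (real/shuffled),
#'   `condition`, `period_s`, `msc`.
#' @param repeated use a dyad-stratified (repeated-measures) error term for
#'   the within-dyad condition factor.
#' @return A tibble of class `anova_by_period`, one row per period:
#'   `period_s`, `F_dyad_type`, `p_dyad_type`, `F_condition`,
#'   `p_condition`, `F_interaction`, `p_interaction`, `df_effect`,
#'   `df_error`.
#' @export
anova_2x2 <- function(results, repeated = FALSE) {
  needed <- c("dyad", "kind", "condition", "period_s", "msc")
  stopifnot(all(needed %in% names(results)))
  cells <- results %>%
    group_by(.data$kind, .data$condition) %>%
    summarise(n = n(), .groups = "drop")
  if (nrow(cells) < 4 || any(cells$n == 0)) {
    abort("all four kind x condition cells must be non-empty.")
  }
  per_period <- results %>%
    group_by(.data$period_s) %>%
    dplyr::group_split()
  out <- lapply(per_period, function(df) {
    df$kind <- factor(df$kind); df$condition <- factor(df$condition)
    if (repeated) {
      fit <- aov(msc ~ kind * condition + Error(factor(dyad)), data = df)
      tab <- summary(fit)
      within <- tab[["Error: Within"]][[1]]
      between <- tab[[1]][[1]]
      f_int <- within["kind:condition", "F value"]
      p_int <- within["kind:condition", "Pr(>F)"]
      tibble(period_s = df$period_s[1],
             F_dyad_type = between["kind", "F value"],
             p_dyad_type = between["kind", "Pr(>F)"],
             F_condition = within["condition", "F value"],
             p_condition = within["condition", "Pr(>F)"],
             F_interaction = f_int, p_interaction = p_int,
             df_effect = 1,
             df_error = within["Residuals", "Df"])
    } else {
      fit <- lm(msc ~ kind * condition, data = df)
      tab <- anova(fit)
      tibble(period_s = df$period_s[1],
             F_dyad_type = tab["kind", "F value"],
             p_dyad_type = tab["kind", "Pr(>F)"],
             F_condition = tab["condition", "F value"],
             p_condition = tab["condition", "Pr(>F)"],
             F_interaction = tab["kind:condition", "F value"],
             p_interaction = tab["kind:condition", "Pr(>F)"],
             df_effect = tab["kind:condition", "Df"],
             df_error = tab["Residuals", "Df"])
    }
  })
  out <- bind_rows(out) %>% arrange(.data$period_s)
  class(out) <- c("anova_by_period", class(out))
  out
}

#' @export
glance.anova_by_period <- function(x, ...) {
  tibble(n_periods = nrow(x),
         min_p_interaction = min(x$p_interaction),
         period_min_p = x$period_s[which.min(x$p_interaction)],
         df_effect = x$df_effect[1], df_error = x$df_error[1])
}
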