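#' Fit the channel-wise (or ROI-wise) GLM by ordinary least squares
#'
#' Regresses every row of `y` on the design matrix by OLS. Betas minimise
#' the squared error; residuals are the data minus the fitted values and are
#' passed downstream to the coherence stage so common task effects are
#' removed. No prewhitening is applied (plain OLS).
#'
#' @param y numeric matrix, series x samples (typically HbDiff per channel,
#'   or HHb per ROI for the residual pathway). A vector is treated as one
#'   series.
#' @param design design matrix from [build_design()] (samples x regressors).
#' @return A list of class `glm_fit`: `betas` (series x regressors),
#'   `residuals` (series x samples), `fitted`, `dof`
#'   (= samples - rank(design)), `design`.
#' @export
fit_glm <- function(y, design) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  n_t <- ncol(y)
  if (nrow(design) != n_t) abort("design rows must equal sample count.")
  if (n_t <= ncol(design)) abort("need more samples than regressors.")
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) abort("rank-deficient design matrix.")
  betas <- t(qr.coef(qr_x, t(y)))
  fitted <- betas %*% t(design)
  res <- y - fitted
  colnames(betas) <- colnames(design)
  structure(
    list(betas = betas, residuals = res, fitted = fitted,
         dof = n_t - qr_x$rank, design = design),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d series x %d regressors (dof = %d)\n",
              nrow(x$betas), ncol(x$betas), x$dof))
  invisible(x)
}

#' @export
tidy.glm_fit <- function(x, ...) {
  as_tibble(x$betas) %>%
    mutate(series = seq_len(nrow(x$betas)), .before = 1) %>%
    tidyr::pivot_longer(-"series", names_to = "regressor",
                        values_to = "beta")
}

#' @export
glance.glm_fit <- function(x, ...) {
  tibble(n_series = nrow(x$betas), n_regressors = ncol(x$betas),
         dof = x$dof,
         sigma = sqrt(mean(x$residuals^2)))
}

#' Group-level condition contrast
#'
#' Paired design: for every channel, the within-participant contrast
#' (live - static) is tested against zero with a one-sample t-test across
#' participants, giving `dof = n_participants - 1` (e.g. 39 for 40
#' participants).
#'
#' @param betas_live,betas_static participants x channels beta matrices,
#'   aligned on the participant dimension.
#' @return A tibble with one row per channel: `channel`, `mean_contrast`,
#'   `t`, `p` (two-sided), `dof`.
#' @export
group_contrast_test <- function(betas_live, betas_static) {
  betas_live <- as.matrix(betas_live); betas_static <- as.matrix(betas_static)
  if (!identical(dim(betas_live), dim(betas_static))) {
    abort("beta matrices must be participant-aligned with equal dimensions.")
  }
  n <- nrow(betas_live)
  if (n < 2) abort("need at least 2 participants.")
  diffs <- betas_live - betas_static
  res <- lapply(seq_len(ncol(diffs)), function(ch) {
    d <- diffs[, ch]
    if (sd(d) == 0) {
      # degenerate but well-defined: no variability across participants
      tibble(channel = ch, mean_contrast = mean(d),
             t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
             p = if (mean(d) == 0) 1 else 0, dof = n - 1)
    } else {
      tt <- t.test(d)
      tibble(channel = ch, mean_contrast = mean(d),
             t = unname(tt$statistic), p = tt$p.value,
             dof = unname(tt$parameter))
    }
  })
  bind_rows(res)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up control of the false discovery rate at level `q`: a hypothesis is
#' rejected when its BH-adjusted p-value is at most `q`.
#'
#' @param pvals p-values in \[0, 1\].
#' @param q FDR level.
#' @return Logical rejection mask, same length/order as `pvals`.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH") <= q
}
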