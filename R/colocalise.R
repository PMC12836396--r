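#' Pairwise channel distances
#'
#' Euclidean distances (mm) between every mask channel and every input
#' channel, both in MNI coordinates.
#'
#' @param input input-montage geometry tibble (`x`, `y`, `z` in mm).
#' @param mask mask-montage geometry tibble.
#' @return Numeric matrix, mask channels x input channels.
#' @export
pairwise_distances <- function(input, mask) {
  if (nrow(input) == 0 || nrow(mask) == 0) abort("empty geometry.")
  a <- as.matrix(mask[, c("x", "y", "z")])
  b <- as.matrix(input[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Gaussian co-localisation kernel
#'
#' Weight between input (participant) channel i and mask channel j falls off
#' as a Gaussian of their distance d_ij. Two parameterisations of the
#' exponent are offered because the smoothing constant is written both ways
#' in the field: `form = "sigma_times_d2"` (default) uses
#' `exp(-sigma * d^2)`, where `sigma = 0.01` mm^-2 gives a 10 mm decay
#' length (localised smoothing with preserved spatial specificity);
#' `form = "d2_over_sigma"` uses `exp(-d^2 / sigma)`. The kernel is stored
#' input channels x mask channels and each column (one mask channel) is
#' divided by its sum, so the weights over input channels sum to one per
#' mask channel: mask series are weighted means of input series, which
#' preserves relative signal amplitudes and maps constants to constants.
#'
#' @param distances mask x input distance matrix in mm
#'   ([pairwise_distances()]).
#' @param sigma smoothing constant (mm^-2 for the default form).
#' @param form exponent parameterisation, see above.
#' @return A list of class `coloc_kernel`: `weights` (input x mask, every
#'   column summing to 1), `sigma`, `form`.
#' @export
build_kernel <- function(distances, sigma = 0.01,
                         form = c("sigma_times_d2", "d2_over_sigma")) {
  form <- match.arg(form)
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (any(distances < 0)) abort("distances must be non-negative.")
  d <- t(distances)                      # input x mask
  raw <- switch(form,
    sigma_times_d2 = exp(-sigma * d^2),
    d2_over_sigma = exp(-d^2 / sigma)
  )
  colsums <- colSums(raw)
  zero <- which(colsums == 0)
  if (length(zero)) {
    abort(sprintf("mask channel(s) %s receive zero total weight (orphaned).",
                  paste(zero, collapse = ", ")))
  }
  w <- sweep(raw, 2, colsums, "/")
  structure(list(weights = w, sigma = sigma, form = form),
            class = "coloc_kernel")
}

#' @export
print.coloc_kernel <- function(x, ...) {
  cat(sprintf("<coloc_kernel> %d input x %d mask channels (sigma = %g, %s)\n",
              nrow(x$weights), ncol(x$weights), x$sigma, x$form))
  invisible(x)
}

#' Project a haemoglobin series onto the mask montage
#'
#' Mask-channel series are the column-normalised, kernel-weighted
#' combination of input-channel series, per sample and chromophore:
#' `mask = t(W) %*% input`. Input channels excluded by QC are dropped
#' together with their kernel rows and the columns renormalised, so the
#' weighted-mean property is retained.
#'
#' @param hb an [hb_series()] on the input montage.
#' @param kernel a `coloc_kernel` whose input dimension matches `hb`.
#' @return An [hb_series()] with mask-montage channel count.
#' @export
colocalise <- function(hb, kernel) {
  stopifnot(inherits(hb, "hb_series"), inherits(kernel, "coloc_kernel"))
  w <- kernel$weights
  if (nrow(w) != nrow(hb$hbo2)) {
    abort(sprintf("kernel expects %d input channels, data has %d.",
                  nrow(w), nrow(hb$hbo2)))
  }
  keep <- hb$channel_mask
  if (!all(keep)) {
    w <- w[keep, , drop = FALSE]
    cs <- colSums(w)
    if (any(cs == 0)) abort("mask channel lost all contributing inputs.")
    w <- sweep(w, 2, cs, "/")
  }
  hb_series(
    hbo2 = t(w) %*% hb$hbo2[keep, , drop = FALSE],
    hhb = t(w) %*% hb$hhb[keep, , drop = FALSE],
    sampling_rate = hb$sampling_rate,
    site_id = hb$site_id
  )
}
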