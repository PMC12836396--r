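#' The packaged bilateral region-of-interest table
#'
#' Fourteen bilateral regions defined by shared Brodmann-area anatomy:
#' angular gyrus (BA39), dorsolateral prefrontal cortex (BA9 and BA46), pars
#' triangularis (BA45), supramarginal gyrus (BA40), middle temporal gyrus
#' (BA21), superior temporal gyrus (BA22), somatosensory cortex (BA1-3),
#' somatosensory association cortex (BA7), premotor/supplementary motor
#' cortex (BA6), subcentral area (BA43), inferior frontal gyrus (BA47),
#' visual area V3 (BA19) and the frontal eye fields (BA8). Each hemisphere
#' row carries an approximate MNI centroid (mm) used for nearest-centroid
#' channel assignment; centroids are package-supplied approximations, not an
#' atlas product.
#'
#' @return A tibble with columns `region`, `hemisphere`, `brodmann`, `x`,
#'   `y`, `z` (28 rows: 14 regions x 2 hemispheres).
#' @export
roi_table <- function() {
  path <- system.file("extdata", "roi_table_v1.csv", package = "fnirsdyad",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Assign mask channels to regions of interest
#'
#' Nearest-centroid assignment: each mask channel joins the bilateral region
#' whose (hemisphere-specific) centroid is closest in MNI space.
#'
#' @param mask_geometry mask geometry tibble (`channel`, `x`, `y`, `z`).
#' @param rois ROI table (default [roi_table()]).
#' @return A tibble `channel`, `region`, `hemisphere`, `distance_mm`.
#' @export
assign_rois <- function(mask_geometry, rois = roi_table()) {
  d <- pairwise_distances(rois, mask_geometry)   # mask channels x roi rows
  nearest <- apply(d, 1, which.min)
  tibble(
    channel = mask_geometry$channel,
    region = rois$region[nearest],
    hemisphere = rois$hemisphere[nearest],
    distance_mm = d[cbind(seq_len(nrow(d)), nearest)]
  )
}

#' Average mask-channel series into ROI series
#'
#' Unweighted mean of member-channel series per bilateral region (both
#' hemispheres pooled), per chromophore. Averaging over anatomically related
#' channels raises the signal-to-noise ratio before coherence analysis.
#'
#' @param hb an [hb_series()] on the mask montage.
#' @param assignment channel-to-region assignment ([assign_rois()]).
#' @param regions regions to return; default every region present in
#'   `assignment`, erroring if any has no included channel.
#' @return A list of class `roi_series`: `hbo2`, `hhb` (regions x samples
#'   matrices with region rownames), `sampling_rate`, `n_channels` (members
#'   per region).
#' @export
roi_average <- function(hb, assignment, regions = NULL) {
  stopifnot(inherits(hb, "hb_series"))
  if (nrow(assignment) != nrow(hb$hbo2)) {
    abort("assignment and series channel counts differ.")
  }
  keep <- hb$channel_mask
  regions <- regions %||% unique(assignment$region)
  members <- lapply(regions, function(r) {
    which(assignment$region == r & keep)
  })
  empty <- regions[lengths(members) == 0]
  if (length(empty)) {
    abort(sprintf("ROI(s) with zero included channels: %s",
                  paste(empty, collapse = ", ")))
  }
  pool <- function(m) {
    out <- t(vapply(members, function(idx) colMeans(m[idx, , drop = FALSE]),
                    numeric(ncol(m))))
    rownames(out) <- regions
    out
  }
  structure(
    list(hbo2 = pool(hb$hbo2), hhb = pool(hb$hhb),
         sampling_rate = hb$sampling_rate,
         n_channels = setNames(lengths(members), regions)),
    class = "roi_series"
  )
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> %d regions x %d samples @ %.2f Hz\n",
              nrow(x$hbo2), ncol(x$hbo2), x$sampling_rate))
  invisible(x)
}
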