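#' Packaged extinction coefficient table
#'
#' Specific extinction coefficients of oxy- and deoxyhaemoglobin at the three
#' LABNIRS wavelengths, in cm^-1 mM^-1 (values of the order used throughout
#' the continuous-wave NIRS literature; 805 nm is near the isosbestic point).
#' Because the differential pathlength factor is a fixed dimensionless guess,
#' recovered concentrations are in arbitrary-but-consistent units, which all
#' downstream statistics tolerate.
#'
#' @param wavelengths wavelengths in nm; must be a subset of 780/805/830
#'   unless a custom table is supplied elsewhere.
#' @return A 3 x 2 matrix, rows = wavelengths, columns = (HbO2, HHb).
#' @export
default_extinction <- function(wavelengths = c(780, 805, 830)) {
  tab <- rbind(
    `780` = c(hbo2 = 0.710, hhb = 1.058),
    `805` = c(hbo2 = 0.830, hhb = 0.793),
    `830` = c(hbo2 = 0.974, hhb = 0.693)
  )
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab))) {
    abort("packaged extinction table covers 780/805/830 nm only.")
  }
  tab[key, , drop = FALSE]
}

# Forward modified Beer-Lambert model: concentration changes -> optical
# density changes. dOD (wavelengths) = E %*% c(dHbO2, dHHb) * L * dpf * unit.
# conc_unit = 1e-3 treats concentrations as micromolar against an extinction
# table in cm^-1 mM^-1, keeping dOD in a physiological range.
mbll_conc_unit <- 1e-3

mbll_forward_od <- function(hbo2, hhb, extinction, separation_cm, dpf,
                            conc_unit = mbll_conc_unit) {
  # hbo2/hhb: channels x samples; returns channels x samples x wavelengths
  n_ch <- nrow(hbo2); n_t <- ncol(hbo2); n_wl <- nrow(extinction)
  od <- array(0, dim = c(n_ch, n_t, n_wl))
  for (w in seq_len(n_wl)) {
    od[, , w] <- (extinction[w, 1] * hbo2 + extinction[w, 2] * hhb) *
      separation_cm * dpf[w] * conc_unit
  }
  od
}

#' Simulate raw intensities from known concentration changes
#'
#' Inverts the modified Beer-Lambert law: concentration changes are mapped to
#' optical-density changes through the extinction table, pathlength and DPF,
#' and then to intensities around a unit baseline, `I = I0 * 10^(-dOD)`.
#' Used by the synthetic generator so that [mbll_convert()] can recover the
#' generated concentrations.
#'
#' @param hbo2,hhb channels x samples concentration-change matrices (a.u.).
#' @param geometry channel geometry tibble providing `separation_cm`.
#' @param sampling_rate sampling rate in Hz.
#' @param site_id site label.
#' @param dpf differential pathlength factors per wavelength.
#' @param extinction 3 x 2 extinction table (rows = wavelengths).
#' @param i0 baseline intensity (a.u.).
#'
#' @return An [fnirs_raw()] object.
#' @export
mbll_intensity <- function(hbo2, hhb, geometry, sampling_rate,
                           site_id = "unknown", dpf = rep(6, 3),
                           extinction = default_extinction(), i0 = 1) {
  sep <- geometry$separation_cm
  od <- mbll_forward_od(hbo2, hhb, extinction, sep, dpf)
  fnirs_raw(i0 * 10^(-od), sampling_rate, site_id = site_id)
}

#' Convert raw intensities to haemoglobin concentration changes (MBLL)
#'
#' Optical density change is `dOD = -log10(I / I0)` with baseline `I0` the
#' whole-run temporal mean per channel and wavelength. The three-wavelength,
#' two-chromophore modified Beer-Lambert system is solved per channel and
#' sample by least squares, scaled by 1 / (separation x DPF). Because the
#' baseline is the run mean, concentrations come out relative to their own
#' run mean.
#'
#' @param raw an [fnirs_raw()] recording.
#' @param geometry channel geometry providing `separation_cm`.
#' @param dpf differential pathlength factors, one per wavelength.
#' @param extinction extinction table, wavelengths x (HbO2, HHb).
#' @param i0 optional explicit baseline intensities (channels x wavelengths);
#'   default is the temporal mean.
#'
#' @return An [hb_series()].
#' @export
mbll_convert <- function(raw, geometry, dpf = rep(6, 3),
                         extinction = default_extinction(), i0 = NULL) {
  stopifnot(inherits(raw, "fnirs_raw"))
  if (dim(raw$data)[3] != 3L) abort("exactly 3 wavelengths are required.")
  if (nrow(extinction) != 3L || ncol(extinction) != 2L) {
    abort("`extinction` must be 3 x 2 (wavelength x chromophore).")
  }
  if (abs(det(crossprod(extinction))) < 1e-12) {
    abort("singular extinction table.")
  }
  if (any(raw$data <= 0)) abort("non-positive intensity encountered.")
  n_ch <- dim(raw$data)[1]; n_t <- dim(raw$data)[2]
  sep <- geometry$separation_cm
  if (length(sep) == 1L) sep <- rep(sep, n_ch)
  if (length(sep) != n_ch) abort("geometry/raw channel count mismatch.")

  # dOD: channels x samples x wavelengths
  od <- array(0, dim = dim(raw$data))
  for (w in 1:3) {
    base <- if (is.null(i0)) rowMeans(raw$data[, , w, drop = FALSE][, , 1]) else i0[, w]
    od[, , w] <- -log10(raw$data[, , w] / base)
  }
  # least-squares solve of E c = od/(L*dpf) per wavelength, vectorised:
  # stack wavelength equations, weight rows by 1 (plain LS as in the 3x2 fit)
  pinv <- solve(crossprod(extinction), t(extinction))  # 2 x 3
  hbo2 <- matrix(0, n_ch, n_t); hhb <- matrix(0, n_ch, n_t)
  # per-channel scaled OD matrices through the pseudoinverse
  for (ch in seq_len(n_ch)) {
    odm <- rbind(od[ch, , 1] / (sep[ch] * dpf[1] * mbll_conc_unit),
                 od[ch, , 2] / (sep[ch] * dpf[2] * mbll_conc_unit),
                 od[ch, , 3] / (sep[ch] * dpf[3] * mbll_conc_unit))  # 3 x samples
    conc <- pinv %*% odm                            # 2 x samples
    hbo2[ch, ] <- conc[1, ]
    hhb[ch, ] <- conc[2, ]
  }
  hb_series(hbo2, hhb, raw$sampling_rate, site_id = raw$site_id)
}
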