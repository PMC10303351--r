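# Wavelength grids, disease stages and the parametric artery/vein
# reflectance model used by the phantom generator.

#' Visible-band wavelength grid
#'
#' The pipeline works on the visible band, 380--780 nm, sampled uniformly.
#'
#' @param start,stop Band limits in nm.
#' @param step Grid spacing in nm (default 1 nm).
#' @return Numeric vector of wavelengths, strictly increasing.
#' @export
#' @examples
#' length(wavelength_grid()) # 401
wavelength_grid <- function(start = 380, stop = 780, step = 1) {
  if (step <= 0 || stop <= start) stop("need stop > start and step > 0")
  seq(start, stop, by = step)
}

#' Diabetic-retinopathy severity stages
#'
#' Four stages following the International Council of Ophthalmology grading:
#' normal, background DR (BDR), pre-proliferative DR (PPDR) and
#' proliferative DR (PDR). Each stage carries a `contrast_scale` in (0, 1]
#' that multiplies the artery--vein spectral difference: as retinopathy
#' progresses, arterial and venous reflectance spectra converge, so later
#' stages get smaller scales.
#'
#' @return A tibble with columns `stage` and `contrast_scale`, ordered from
#'   normal to PDR with strictly decreasing contrast.
#' @export
severity_levels <- function() {
  tibble::tibble(
    stage = c("normal", "BDR", "PPDR", "PDR"),
    contrast_scale = c(1.0, 0.6, 0.45, 0.25)
  )
}

contrast_scale_for <- function(stage) {
  lev <- severity_levels()
  i <- match(stage, lev$stage)
  if (is.na(i)) {
    stop("unknown stage '", stage, "'; expected one of ",
         paste(lev$stage, collapse = ", "), call. = FALSE)
  }
  lev$contrast_scale[i]
}

#' Parameters of the parametric artery/vein reflectance model
#'
#' Arterial and venous spectra are modelled as a shared hemoglobin-like
#' midline curve plus/minus half of a class-difference curve scaled by the
#' stage's `contrast_scale`. The midline is a logistic red-edge ramp (low
#' reflectance in the blue, rising steeply around `red_edge_center` nm)
#' with a broad green bump and two narrow absorption dips near 542 and
#' 577 nm mimicking the oxyhemoglobin double trough. The difference curve
#' is a logistic ramp confined to the red band, where oxygenated arterial
#' blood reflects more than venous blood. A mild mid-band (around 532 nm)
#' depression common to both classes grows with severity, reflecting the
#' reported fall of reflectance in 495--570 nm as lesions progress.
#'
#' @param red_edge_center,red_edge_width Logistic midline ramp, nm.
#' @param base_lo,base_hi Midline asymptotes (unitless reflectance).
#' @param green_amp,green_center,green_sd Broad green bump.
#' @param dip1_amp,dip1_center,dip1_sd First absorption dip (542 nm).
#' @param dip2_amp,dip2_center,dip2_sd Second absorption dip (577 nm).
#' @param diff_amp Peak artery-vein reflectance difference in the deep red.
#' @param diff_center,diff_width Logistic ramp of the difference curve, nm.
#' @param midband_drop_amp Depth of the severity-linked mid-band depression
#'   at full severity (contrast_scale -> 0).
#' @param background_scale Fundus background reflectance as a fraction of
#'   the vessel midline curve.
#' @return A list of class `spectral_params`.
#' @export
spectral_params <- function(red_edge_center = 585, red_edge_width = 22,
                            base_lo = 0.08, base_hi = 0.62,
                            green_amp = 0.10, green_center = 540, green_sd = 30,
                            dip1_amp = 0.05, dip1_center = 542, dip1_sd = 12,
                            dip2_amp = 0.04, dip2_center = 577, dip2_sd = 11,
                            diff_amp = 0.15, diff_center = 600, diff_width = 20,
                            midband_drop_amp = 0.04,
                            background_scale = 0.38) {
  p <- as.list(environment())
  class(p) <- "spectral_params"
  p
}

gauss_bump <- function(x, center, sd) exp(-0.5 * ((x - center) / sd)^2)

# Shared midline ("mean vessel") reflectance curve.
midline_spectrum <- function(wl, p) {
  p$base_lo + p$base_hi * stats::plogis((wl - p$red_edge_center) / p$red_edge_width) +
    p$green_amp * gauss_bump(wl, p$green_center, p$green_sd) -
    p$dip1_amp * gauss_bump(wl, p$dip1_center, p$dip1_sd) -
    p$dip2_amp * gauss_bump(wl, p$dip2_center, p$dip2_sd)
}

# Full-contrast artery-vein difference curve (>= 0 everywhere, red band).
difference_spectrum <- function(wl, p) {
  p$diff_amp * stats::plogis((wl - p$diff_center) / p$diff_width)
}

#' Artery and vein reflectance spectra for a severity stage
#'
#' Evaluates the parametric model: `artery = mid + s * d / 2` and
#' `vein = mid - s * d / 2`, where `s` is the stage's contrast scale and
#' `d` the full-contrast difference curve, plus a severity-linked mid-band
#' depression shared by both classes. Consequences of the construction:
#' the artery-vein difference is pointwise proportional to `s`, so it is
#' positive throughout the red band (600--780 nm) at every stage and
#' shrinks strictly from normal to PDR, while venous red-band reflectance
#' rises as severity grows.
#'
#' @param stage Stage name (see [severity_levels()]) or a `contrast_scale`
#'   value in (0, 1] supplied via `contrast_scale`.
#' @param params A [spectral_params()] list.
#' @param wavelength Wavelength grid in nm.
#' @param contrast_scale Optional explicit contrast scale overriding the
#'   stage lookup.
#' @return A tibble with columns `wavelength`, `artery`, `vein`,
#'   `background` (all reflectances in \[0, 1\]).
#' @export
#' @examples
#' sp <- av_spectra("normal")
#' range(sp$artery)
av_spectra <- function(stage = "normal", params = spectral_params(),
                       wavelength = wavelength_grid(),
                       contrast_scale = NULL) {
  s <- if (is.null(contrast_scale)) contrast_scale_for(stage) else contrast_scale
  if (s <= 0 || s > 1) stop("contrast_scale must lie in (0, 1]")
  mid <- midline_spectrum(wavelength, params)
  d <- difference_spectrum(wavelength, params)
  drop <- params$midband_drop_amp * (1 - s) * gauss_bump(wavelength, 532, 35)
  artery <- mid + s * d / 2 - drop
  vein <- mid - s * d / 2 - drop
  background <- params$background_scale * mid
  out <- tibble::tibble(wavelength = wavelength, artery = artery,
                        vein = vein, background = background)
  if (any(out$artery < 0 | out$artery > 1 | out$vein < 0 | out$vein > 1)) {
    stop("spectral parameters produce reflectance outside [0, 1]")
  }
  out
}
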