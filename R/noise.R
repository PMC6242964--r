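#' Poisson-Gaussian camera noise model
#'
#' Standard EMCCD approximation: photon shot noise (Poisson, controlled by
#' `photon_scale`, the number of detected electrons per intensity unit) plus
#' additive Gaussian read noise (`read_sigma`, intensity units) on top of a
#' constant `background_level`. `photon_scale = 0` disables the shot-noise
#' term; `read_sigma = 0` disables read noise. With both zero the model is
#' noiseless. The same `seed` always yields bit-identical output.
#'
#' @param photon_scale electrons per intensity unit (>= 0).
#' @param read_sigma additive Gaussian sd, intensity units (>= 0).
#' @param background_level constant offset added before the shot-noise draw,
#'   intensity units (>= 0).
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photon_scale = 0, read_sigma = 0,
                        background_level = 0, seed = 1L) {
  if (!is.numeric(photon_scale) || photon_scale < 0)
    stop("photon_scale must be >= 0")
  if (!is.numeric(read_sigma) || read_sigma < 0)
    stop("read_sigma must be >= 0")
  if (!is.numeric(background_level) || background_level < 0)
    stop("background_level must be >= 0")
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Apply camera noise to clean intensities
#'
#' Adds the background level, draws Poisson counts at `photon_scale`
#' electrons per unit (when `photon_scale > 0`), rescales back to intensity
#' units, and adds Gaussian read noise. The RNG state is restored on exit,
#' so the draw is a pure function of (`x`, `noise`).
#'
#' @param x numeric vector/array of clean intensities (>= 0 where
#'   `photon_scale > 0`).
#' @param noise a [noise_model()].
#' @param seed_offset integer added to the model seed, used internally to
#'   decorrelate multiple draws from one model.
#' @return Numeric object of the same shape as `x`.
#' @export
apply_camera_noise <- function(x, noise, seed_offset = 0L) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$photon_scale == 0 && noise$read_sigma == 0)
    return(x + noise$background_level)
  withr::with_seed(noise$seed + as.integer(seed_offset), {
    out <- x + noise$background_level
    if (noise$photon_scale > 0) {
      lam <- pmax(out * noise$photon_scale, 0)
      out[] <- stats::rpois(length(lam), lam) / noise$photon_scale
    }
    if (noise$read_sigma > 0)
      out <- out + stats::rnorm(length(out), 0, noise$read_sigma)
    out
  })
}
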