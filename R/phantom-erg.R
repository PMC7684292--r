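# Synthetic flash ERG generator: biphasic waveform with saturating
# (Naka-Rushton-style) intensity-response amplitudes and a closed-form
# ground truth for recovery testing.

#' Configuration for the ERG waveform generator
#'
#' The flash response is modelled as a negative Gaussian lobe (a-wave,
#' photoreceptor) peaking at `a_time` followed by a positive Gaussian lobe
#' (b-wave, bipolar/Müller) peaking at `b_time`. Amplitudes follow the
#' saturating hyperbolic intensity-response function
#' `A(I) = a_amp_max * I^n / (I^n + K^n)` (and likewise for the b-wave).
#' Amplitude conventions match measurement practice: `a_amp_max` is the
#' baseline-to-trough amplitude and `b_amp_max` the trough-to-peak
#' amplitude, so the positive lobe height is `B(I) - A(I)` (requiring
#' `b_amp_max >= a_amp_max`).
#'
#' @param a_amp_max,b_amp_max saturated a-/b-wave amplitudes, µV.
#' @param a_time,b_time implicit times of the two lobes, ms after flash.
#' @param a_sigma,b_sigma Gaussian lobe widths, ms.
#' @param semi_saturation_K flash intensity at half-saturation, mcd·s/m².
#' @param hill_n Hill coefficient of the intensity-response function.
#' @param noise_sd additive Gaussian noise SD, µV.
#' @param sampling_rate Hz.
#' @param pre_ms,post_ms recorded window around the flash (t = 0), ms.
#' @param flash_intensities default scotopic series, mcd·s/m².
#' @param seed integer seed.
#' @return a list of class `erg_phantom_config`.
#' @export
erg_phantom_config <- function(a_amp_max = 150, b_amp_max = 300,
                               a_time = 15, b_time = 60,
                               a_sigma = 8, b_sigma = 12,
                               semi_saturation_K = 1000, hill_n = 1,
                               noise_sd = 0, sampling_rate = 1000,
                               pre_ms = 20, post_ms = 200,
                               flash_intensities = c(100, 300, 1000,
                                                     3000, 10000, 25000),
                               seed = 1L) {
  cfg <- list(a_amp_max = a_amp_max, b_amp_max = b_amp_max,
              a_time = a_time, b_time = b_time,
              a_sigma = a_sigma, b_sigma = b_sigma,
              semi_saturation_K = semi_saturation_K, hill_n = hill_n,
              noise_sd = noise_sd, sampling_rate = sampling_rate,
              pre_ms = pre_ms, post_ms = post_ms,
              flash_intensities = flash_intensities, seed = as.integer(seed))
  if (cfg$a_time >= cfg$b_time) rdx_config_error("need a_time < b_time")
  if (any(cfg$flash_intensities <= 0)) {
    rdx_config_error("flash intensities must be > 0")
  }
  if (cfg$b_amp_max < cfg$a_amp_max) {
    rdx_config_error("need b_amp_max >= a_amp_max (trough-to-peak convention)")
  }
  if (cfg$pre_ms < 20) rdx_config_error("need >= 20 ms pre-flash baseline")
  structure(cfg, class = "erg_phantom_config")
}

#' Saturating intensity-response amplitude
#'
#' `amp_max * I^n / (I^n + K^n)`: the closed form the generator draws from,
#' exported so recovery tests can compare against it.
#'
#' @param intensity flash intensity, mcd·s/m².
#' @param amp_max saturated amplitude, µV.
#' @param K semi-saturation intensity.
#' @param n Hill coefficient.
#' @return expected amplitude, µV.
#' @export
naka_rushton_amplitude <- function(intensity, amp_max, K, n = 1) {
  amp_max * intensity^n / (intensity^n + K^n)
}

#' Generate a synthetic flash ERG trace
#'
#' @param cfg an [erg_phantom_config()].
#' @param intensity flash intensity, mcd·s/m² (> 0).
#' @return an [erg_trace()] with `flash_intensity = intensity`; the
#'   noiseless closed-form amplitudes are attached as attribute
#'   `"truth"` (list `a_amp`, `b_amp`).
#' @export
make_erg_trace <- function(cfg, intensity) {
  if (!inherits(cfg, "erg_phantom_config")) {
    cfg <- do.call(erg_phantom_config, as.list(cfg))
  }
  if (intensity <= 0) rdx_input_error("flash intensity must be > 0")
  dt <- 1000 / cfg$sampling_rate
  t <- seq(-cfg$pre_ms, cfg$post_ms, by = dt)
  a <- naka_rushton_amplitude(intensity, cfg$a_amp_max,
                              cfg$semi_saturation_K, cfg$hill_n)
  b <- naka_rushton_amplitude(intensity, cfg$b_amp_max,
                              cfg$semi_saturation_K, cfg$hill_n)
  lobe <- function(centre, sigma) exp(-(t - centre)^2 / (2 * sigma^2))
  v <- -a * lobe(cfg$a_time, cfg$a_sigma) +
    (b - a) * lobe(cfg$b_time, cfg$b_sigma)
  v[t <= 0] <- 0  # quiescent until the flash; response begins at t > 0
  if (cfg$noise_sd > 0) {
    seed_i <- (cfg$seed + as.integer(round(intensity)) %% 1000003L) %% .Machine$integer.max
    v <- withr::with_seed(seed_i, v + rnorm(length(v), 0, cfg$noise_sd))
  }
  out <- erg_trace(t, v, flash_intensity = intensity,
                   protocol = "scotopic_series")
  attr(out, "truth") <- list(a_amp = a, b_amp = b,
                             a_time = cfg$a_time, b_time = cfg$b_time)
  out
}
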