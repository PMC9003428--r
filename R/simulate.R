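#' Simulation configuration
#'
#' Parameters of the synthetic fNIRS generator. The defaults emulate the
#' acquisition the pipeline targets: 12 channels over left M1 sampled at
#' 1.81 Hz, a treadmill-walking block paradigm (30 s rest, ten trials of
#' 10 s walk + 20 s rest, 30 s closing baseline), a canonical double-gamma
#' hemodynamic response on the informative channels, and physiological
#' (sinusoidal), drift and white noise on every channel.
#'
#' Noise model: each channel receives a sum of random-phase sinusoids
#' (default 0.28 Hz respiratory at sd 0.3 uM and 1.1 Hz cardiac at sd 0.2
#' uM — the cardiac line aliases to 0.71 Hz at fs = 1.81), a linear drift
#' with random slope (ramp sd `drift_sd`), and white Gaussian noise
#' (`white_sd`). The whole noise mixture is rescaled so that
#' `amplitude_uM / sd(total noise) = snr`.
#'
#' @param n_channels number of channels (default 12).
#' @param informative_channels indices carrying the task response
#'   (default `c(2, 5, 9)`).
#' @param fs sampling rate in Hz (default 1.81).
#' @param paradigm a [nirs_paradigm()]; default [default_paradigm()].
#' @param hrf_peak_s,hrf_undershoot_s,undershoot_ratio hemodynamic
#'   response shape, see [canonical_hrf()].
#' @param amplitude_uM peak task-response amplitude in uM (default 1).
#' @param snr amplitude-to-total-noise-sd ratio (default 1).
#' @param sinusoids data frame with columns `freq_hz` and `sd` describing
#'   physiological oscillations.
#' @param drift_sd standard deviation contributed by the linear drift (uM).
#' @param white_sd white-noise standard deviation (uM).
#' @param hbr_ratio HbR is simulated as `-hbr_ratio * HbO` plus
#'   independent white noise; this only exercises the optical-density
#'   path, with no claim of physiological fidelity.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 12,
                       informative_channels = c(2, 5, 9),
                       fs = 1.81,
                       paradigm = default_paradigm(),
                       hrf_peak_s = 6, hrf_undershoot_s = 16,
                       undershoot_ratio = 1 / 6,
                       amplitude_uM = 1, snr = 1,
                       sinusoids = data.frame(freq_hz = c(0.28, 1.1),
                                              sd = c(0.3, 0.2)),
                       drift_sd = 0.2, white_sd = 0.5,
                       hbr_ratio = 0.3, seed = 1) {
  if (!all(informative_channels %in% seq_len(n_channels)))
    stop("informative_channels must be a subset of 1..n_channels")
  if (snr <= 0) stop("`snr` must be > 0 (use a large value for near-noiseless)")
  if (fs <= 0) stop("`fs` must be > 0")
  if (any(sinusoids$sd < 0) || drift_sd < 0 || white_sd < 0)
    stop("noise standard deviations must be >= 0")
  structure(list(n_channels = as.integer(n_channels),
                 informative_channels = as.integer(informative_channels),
                 fs = fs, paradigm = paradigm,
                 hrf_peak_s = hrf_peak_s, hrf_undershoot_s = hrf_undershoot_s,
                 undershoot_ratio = undershoot_ratio,
                 amplitude_uM = amplitude_uM, snr = snr,
                 sinusoids = sinusoids, drift_sd = drift_sd,
                 white_sd = white_sd, hbr_ratio = hbr_ratio,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Canonical double-gamma hemodynamic response
#'
#' Difference of two gamma densities (response minus a delayed
#' undershoot), evaluated on the sampling grid over 32 s and normalised to
#' unit peak. With `scale = 1` the gamma shape parameters are
#' `peak_s + 1` and `undershoot_s + 1`, putting the response maximum at
#' `peak_s` seconds.
#'
#' @param fs sampling rate (Hz).
#' @param peak_s time-to-peak of the positive lobe (s), must be smaller
#'   than `undershoot_s`.
#' @param undershoot_s time-to-trough of the undershoot lobe (s).
#' @param ratio undershoot amplitude ratio (0 disables the undershoot and
#'   yields a non-negative kernel).
#' @param duration_s kernel length (default 32 s).
#' @return numeric kernel vector with unit peak.
#' @export
canonical_hrf <- function(fs, peak_s = 6, undershoot_s = 16, ratio = 1 / 6,
                          duration_s = 32) {
  if (fs <= 0 || peak_s <= 0 || undershoot_s <= peak_s || ratio < 0)
    stop("invalid HRF shape parameters (need fs > 0, 0 < peak_s < undershoot_s, ratio >= 0)")
  t <- seq(0, duration_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  h / max(h)
}

# Internal: one channel's noise mixture before SNR scaling.
channel_noise <- function(cfg, t) {
  n <- length(t)
  x <- numeric(n)
  if (nrow(cfg$sinusoids))
    for (i in seq_len(nrow(cfg$sinusoids))) {
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + cfg$sinusoids$sd[i] * sqrt(2) *
        sin(2 * pi * cfg$sinusoids$freq_hz[i] * t + ph)
    }
  if (cfg$drift_sd > 0) {
    # centred unit ramp has sd 1/sqrt(12) per unit slope-range
    ramp <- (t - mean(t)) / (max(t) - min(t))
    x <- x + cfg$drift_sd * ramp / stats::sd(ramp) * stats::rnorm(1)
  }
  if (cfg$white_sd > 0) x <- x + stats::rnorm(n, sd = cfg$white_sd)
  x
}

#' Simulate an HbO recording
#'
#' Informative channels carry `amplitude_uM * (task boxcar convolved with
#' the canonical HRF)` plus noise; uninformative channels carry noise
#' only. The noise mixture is scaled to the configured SNR
#' (`amplitude_uM / sd_total`); setting every noise sd to 0 gives the
#' noiseless response exactly. Reproducible per seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `rec` (HbO [nirs_recording()]) and `paradigm`.
#' @export
simulate_hbo <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  n <- floor(cfg$paradigm$total_duration_s * cfg$fs)
  t <- (seq_len(n) - 1L) / cfg$fs
  boxcar <- as.numeric(paradigm_labels(cfg$paradigm, cfg$fs, n) == "task")
  hrf <- canonical_hrf(cfg$fs, cfg$hrf_peak_s, cfg$hrf_undershoot_s,
                       cfg$undershoot_ratio)
  resp <- stats::convolve(c(boxcar, numeric(length(hrf))), rev(hrf),
                          type = "open")[seq_len(n)]
  # normalise the evoked response to unit peak so amplitude_uM is the true
  # response scale and snr = amplitude / total-noise-sd holds as stated
  resp <- cfg$amplitude_uM * resp / max(abs(resp))

  sd_nominal <- sqrt(sum(cfg$sinusoids$sd^2) + cfg$drift_sd^2 + cfg$white_sd^2)
  scale <- if (sd_nominal > 0 && is.finite(cfg$snr))
    (cfg$amplitude_uM / cfg$snr) / sd_nominal else 0

  vals <- matrix(0, cfg$n_channels, n)
  for (ch in seq_len(cfg$n_channels)) {
    vals[ch, ] <- scale * channel_noise(cfg, t)
    if (ch %in% cfg$informative_channels)
      vals[ch, ] <- vals[ch, ] + resp
  }
  list(rec = nirs_recording(vals, cfg$fs, "hbo"), paradigm = cfg$paradigm)
}

#' Simulate raw dual-wavelength optical density
#'
#' Generates HbO via [simulate_hbo()], derives HbR as
#' `-hbr_ratio * HbO` plus independent white noise (scaled with the same
#' SNR factor), and maps both through the forward modified Beer-Lambert
#' law. [mbll_inverse()] applied to the output recovers the HbO ground
#' truth up to the noise floor (exactly, in the noiseless setting).
#'
#' @param cfg a [sim_config()].
#' @param params a [mbll_params()].
#' @return list with `od` (optical-density recording), `hbo_truth`,
#'   `paradigm`.
#' @export
simulate_raw_od <- function(cfg, params = mbll_params()) {
  sim <- simulate_hbo(cfg)
  hbo <- sim$rec
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed + 1L)
  sd_nominal <- sqrt(sum(cfg$sinusoids$sd^2) + cfg$drift_sd^2 + cfg$white_sd^2)
  scale <- if (sd_nominal > 0 && is.finite(cfg$snr))
    (cfg$amplitude_uM / cfg$snr) / sd_nominal else 0
  hbr_vals <- -cfg$hbr_ratio * hbo$values +
    scale * cfg$white_sd * matrix(stats::rnorm(length(hbo$values)),
                                  nrow(hbo$values))
  hbr <- nirs_recording(hbr_vals, hbo$fs, "hbr",
                        channel_labels = hbo$channel_labels)
  list(od = mbll_forward(hbo, hbr, params),
       hbo_truth = hbo, paradigm = sim$paradigm)
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from the master seed
#' (`seed * 1000 + subject`, kept under 2^31). With `jitter_informative`,
#' each subject's informative set is independently perturbed (one channel
#' swapped for a random uninformative one) to emulate inter-subject
#' variation in recruited cortex.
#'
#' @param n_subjects cohort size (default 9).
#' @param cfg a [sim_config()] template.
#' @param seed master seed (overrides `cfg$seed`).
#' @param jitter_informative logical (default FALSE).
#' @return list of per-subject lists `(rec, paradigm, informative, seed)`.
#' @export
generate_cohort <- function(n_subjects = 9, cfg = sim_config(), seed = 1,
                            jitter_informative = FALSE) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(s) {
    scfg <- cfg
    scfg$seed <- (as.integer(seed) %% 2000000L) * 1000L + s
    if (jitter_informative) {
      old_seed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(scfg$seed + 500L)
      inf <- scfg$informative_channels
      out <- setdiff(seq_len(scfg$n_channels), inf)
      if (length(out)) {
        inf[sample.int(length(inf), 1)] <- out[sample.int(length(out), 1)]
        scfg$informative_channels <- sort(unique(inf))
      }
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }
    sim <- simulate_hbo(scfg)
    list(rec = sim$rec, paradigm = sim$paradigm,
         informative = scfg$informative_channels, seed = scfg$seed)
  })
}
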