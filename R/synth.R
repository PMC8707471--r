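#' ECG morphology profile
#'
#' Parameter set for the synthetic ECG generator: one Gaussian bump per
#' wave (P, Q, R, S, T) on each cardiac cycle, with per-class amplitude and
#' width multipliers for three blood-pressure classes. The class templates
#' are documented defaults chosen to make the classes clearly distinct; no
#' clinical fidelity is claimed.
#'
#' @param class_label `"normal"`, `"hypotension"` or `"hypertension"`.
#' @param hr_bpm target heart rate in beats per minute (> 0).
#' @param rr_jitter fractional beat-to-beat jitter of the RR interval
#'   (standard deviation as a fraction of the mean RR; default 0.02).
#' @return An object of class `ecg_profile`: the wave table (amplitude in
#'   mV, width and centre offset in s, relative to the R peak) plus rate.
#' @export
ecg_profile <- function(class_label = c("normal", "hypotension", "hypertension"),
                        hr_bpm = 75, rr_jitter = 0.02) {
  class_label <- match.arg(class_label)
  if (!is.finite(hr_bpm) || hr_bpm <= 0) {
    stop("`hr_bpm` must be positive", call. = FALSE)
  }
  # Base template: amplitudes mV, widths s, centres s relative to R.
  waves <- data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    amp    = c(0.15, -0.10, 1.00, -0.18, 0.30),
    width  = c(0.025, 0.010, 0.012, 0.010, 0.050),
    centre = c(-0.200, -0.035, 0.000, 0.035, 0.280)
  )
  mult <- switch(class_label,
    normal       = c(P = 1.0, Q = 1.0, R = 1.0, S = 1.0, T = 1.0),
    # Hypotension template: globally lower voltages, flat T.
    hypotension  = c(P = 0.6, Q = 0.7, R = 0.65, S = 0.7, T = 0.45),
    # Hypertension template: tall R (ventricular strain look), deep S,
    # inverted/biphasic T.
    hypertension = c(P = 1.1, Q = 1.3, R = 1.45, S = 1.8, T = -0.8)
  )
  waves$amp <- waves$amp * mult[waves$wave]
  if (abs(waves$amp[waves$wave == "R"]) <= abs(waves$amp[waves$wave == "P"])) {
    stop("profile invariant violated: |R| must exceed |P|", call. = FALSE)
  }
  structure(list(class_label = class_label, waves = waves, hr_bpm = hr_bpm,
                 rr_jitter = rr_jitter),
            class = "ecg_profile")
}

#' Generate a synthetic ECG trace
#'
#' Sums one parameterised Gaussian bump per wave (P, Q, R, S, T) per beat,
#' at the profile's heart rate with seeded beat-to-beat RR jitter. The
#' result is a clean, noiseless millivolt-scale trace; pass it through
#' [apply_capacitive_channel()] to emulate non-contact acquisition.
#'
#' @param profile an [ecg_profile()].
#' @param duration_s duration in seconds (>= 0).
#' @param fs sampling rate in Hz (>= 250).
#' @param seed integer seed for the RR jitter; `NULL` uses the current RNG.
#' @return A [signal_trace()] in mV, channel `"ecg"`.
#' @examples
#' ecg <- gen_ecg(ecg_profile("normal", hr_bpm = 60), duration_s = 10,
#'                fs = 500, seed = 1)
#' @export
gen_ecg <- function(profile, duration_s, fs = 1000, seed = NULL) {
  stopifnot(inherits(profile, "ecg_profile"))
  if (!is.finite(fs) || fs < 250) stop("`fs` must be >= 250 Hz", call. = FALSE)
  if (!is.finite(duration_s) || duration_s < 0) {
    stop("`duration_s` must be >= 0", call. = FALSE)
  }
  n <- floor(duration_s * fs)
  if (n == 0L) return(signal_trace(numeric(0), fs, "ecg", "mV"))
  t <- (seq_len(n) - 1) / fs
  rr_mean <- 60 / profile$hr_bpm
  with_seed(seed, {
    # Enough beats to cover the trace plus margin on both sides so that
    # T waves of the last beat and P waves of the first are complete.
    n_beats <- ceiling(duration_s / rr_mean) + 3L
    rr <- rr_mean * (1 + profile$rr_jitter * stats::rnorm(n_beats))
    rr <- pmax(rr, 0.3)  # refractory floor
    beat_times <- cumsum(c(rr_mean / 2, rr[-1]))
    x <- numeric(n)
    for (b in beat_times) {
      if (b < -0.5 || b > duration_s + 0.5) next
      for (w in seq_len(nrow(profile$waves))) {
        amp <- profile$waves$amp[w]
        wid <- profile$waves$width[w]
        ctr <- b + profile$waves$centre[w]
        # Gaussian support is effectively 4 widths; skip off-trace bumps.
        if (ctr + 4 * wid < 0 || ctr - 4 * wid > duration_s) next
        x <- x + amp * exp(-0.5 * ((t - ctr) / wid)^2)
      }
    }
    signal_trace(x, fs, "ecg", "mV")
  })
}

#' EEG state specification
#'
#' Amplitude specification for the synthetic EEG generator. Each cognitive
#' state is a mixture of a narrow-band alpha component (8-12 Hz), a
#' narrow-band beta component (14-25 Hz) and broadband Gaussian noise.
#' Alpha amplitude is constrained to the physiological 5-150 microvolt
#' range (zero is also accepted, meaning "no alpha component").
#'
#' Default amplitudes per state (alpha, beta, noise, in microvolts):
#' eyes_open (15, 25, 5), eyes_closed_relaxed (40, 10, 5), drowsy (60, 8, 5),
#' stress (8, 45, 5), emotion (22, 35, 5), distraction (10, 12, 25).
#' Relaxed/drowsy states have alpha dominant; every active state
#' (eyes_open, stress, emotion, distraction) has beta dominant, with
#' distraction additionally marked by raised broadband noise.
#'
#' @param state one of `"eyes_open"`, `"eyes_closed_relaxed"`, `"drowsy"`,
#'   `"stress"`, `"emotion"`, `"distraction"`.
#' @param alpha_amp,beta_amp,broadband_noise_amp amplitudes in microvolts;
#'   `NULL` picks the state's documented default.
#' @return An object of class `eeg_state_spec`.
#' @export
eeg_state_spec <- function(state = c("eyes_open", "eyes_closed_relaxed",
                                     "drowsy", "stress", "emotion",
                                     "distraction"),
                           alpha_amp = NULL, beta_amp = NULL,
                           broadband_noise_amp = NULL) {
  state <- match.arg(state)
  def <- switch(state,
    eyes_open           = c(15, 25, 5),
    eyes_closed_relaxed = c(40, 10, 5),
    drowsy              = c(60, 8, 5),
    stress              = c(8, 45, 5),
    emotion             = c(22, 35, 5),
    distraction         = c(10, 12, 25)
  )
  alpha_amp <- if (is.null(alpha_amp)) def[1] else as.numeric(alpha_amp)
  beta_amp <- if (is.null(beta_amp)) def[2] else as.numeric(beta_amp)
  noise <- if (is.null(broadband_noise_amp)) def[3] else
    as.numeric(broadband_noise_amp)
  if (alpha_amp != 0 && (alpha_amp < 5 || alpha_amp > 150)) {
    stop("`alpha_amp` must be 0 or within the physiological 5-150 uV range",
         call. = FALSE)
  }
  if (beta_amp < 0 || noise < 0) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  structure(list(state = state, alpha_amp = alpha_amp, beta_amp = beta_amp,
                 broadband_noise_amp = noise,
                 alpha_band = c(8, 12), beta_band = c(14, 25)),
            class = "eeg_state_spec")
}

# Narrow-band oscillation: carrier at the band centre with slow seeded
# amplitude/frequency wander confined to the band. Peak envelope == amp.
narrowband_osc <- function(t, band, amp) {
  if (amp == 0 || !length(t)) return(numeric(length(t)))
  f0 <- mean(band)
  # frequency wander within +-40% of the half-bandwidth, at ~0.2 Hz
  fdev <- 0.4 * diff(band) / 2
  phase <- 2 * pi * (f0 * t +
    fdev / (2 * pi * 0.2) * sin(2 * pi * 0.2 * t + stats::runif(1, 0, 2 * pi)))
  # waxing/waning envelope at a spindle-like rate, fast enough that an
  # 8-s epoch averages over several cycles
  env <- 0.75 + 0.25 * sin(2 * pi * 0.35 * t + stats::runif(1, 0, 2 * pi))
  amp * env * sin(phase + stats::runif(1, 0, 2 * pi))
}

#' Generate a synthetic EEG trace
#'
#' Sum of a narrow-band alpha oscillation (8-12 Hz), a narrow-band beta
#' oscillation (14-25 Hz) and white broadband noise, with amplitudes set by
#' the state specification. The modulated envelopes never exceed the stated
#' component amplitude, so the alpha component of any valid spec respects
#' the 150 microvolt physiological ceiling.
#'
#' @param spec an [eeg_state_spec()].
#' @param duration_s duration in seconds.
#' @param fs sampling rate in Hz (>= 100); default 1000 Hz.
#' @param seed integer seed; `NULL` uses the current RNG.
#' @return A [signal_trace()] in microvolts, channel `"eeg"`.
#' @examples
#' eeg <- gen_eeg(eeg_state_spec("drowsy"), duration_s = 8, fs = 250, seed = 2)
#' @export
gen_eeg <- function(spec, duration_s, fs = 1000, seed = NULL) {
  stopifnot(inherits(spec, "eeg_state_spec"))
  if (!is.finite(fs) || fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)
  n <- floor(duration_s * fs)
  if (n == 0L) return(signal_trace(numeric(0), fs, "eeg", "uV"))
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    x <- narrowband_osc(t, spec$alpha_band, spec$alpha_amp) +
      narrowband_osc(t, spec$beta_band, spec$beta_amp)
    if (spec$broadband_noise_amp > 0) {
      x <- x + spec$broadband_noise_amp * stats::rnorm(n)
    }
    signal_trace(x, fs, "eeg", "uV")
  })
}

#' Generate a dual-wavelength PPG pair with known oxygen saturation
#'
#' Synthesizes red (660 nm) and infrared (910 nm) photoplethysmogram
#' channels, each a DC level plus a pulsatile component at the requested
#' heart rate. The per-channel AC/DC modulation depths are chosen by
#' inverting the oximetry module's own ratio-of-ratios formula against the
#' supplied calibration table, so that running the estimation pipeline on a
#' clean pair recovers `spo2_true` (round-trip by construction, independent
#' of which table is configured).
#'
#' @param spo2_true ground-truth saturation in percent, within 70-100.
#' @param hr_bpm pulse rate in beats per minute.
#' @param duration_s duration in seconds.
#' @param fs sampling rate in Hz; default 1000 Hz.
#' @param seed integer seed for additive measurement noise.
#' @param table calibration table used for the inversion
#'   (default [default_calibration_table()]).
#' @param noise_sd relative intensity noise (fraction of DC; default 0 =
#'   clean).
#' @return An object of class `ppg_pair`: list with `red` and `ir`
#'   [signal_trace()]s and `spo2_true`.
#' @export
gen_ppg_pair <- function(spo2_true, hr_bpm = 75, duration_s = 10, fs = 1000,
                         seed = NULL, table = default_calibration_table(),
                         noise_sd = 0) {
  if (!is.finite(spo2_true) || spo2_true < 70 || spo2_true > 100) {
    stop("`spo2_true` must be within 70-100 %", call. = FALSE)
  }
  n <- floor(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  # Invert the calibration table: SpO2 -> R.
  R <- ratio_for_spo2(spo2_true, table)
  # Fix the infrared modulation depth and solve the printed log-ratio
  # formula R = log(m_red) / log(m_ir) for the red depth.
  m_ir <- 0.04
  m_red <- m_ir^R
  dc_red <- 2.0
  dc_ir <- 2.2
  f <- hr_bpm / 60
  with_seed(seed, {
    ph <- stats::runif(1, 0, 2 * pi)
    # Pulse shape: fundamental plus a small in-phase harmonic would change
    # the peak-to-trough/DC ratio; a pure sinusoid keeps the modulation
    # depth exact (peak-to-trough = 2 * amplitude).
    pulse <- sin(2 * pi * f * t + ph)
    red <- dc_red * (1 + (m_red / 2) * pulse)
    ir <- dc_ir * (1 + (m_ir / 2) * pulse)
    if (noise_sd > 0) {
      red <- red + noise_sd * dc_red * stats::rnorm(n)
      ir <- ir + noise_sd * dc_ir * stats::rnorm(n)
    }
    structure(
      list(red = signal_trace(red, fs, "ppg_red", "a.u."),
           ir = signal_trace(ir, fs, "ppg_ir", "a.u."),
           spo2_true = spo2_true),
      class = "ppg_pair"
    )
  })
}

#' Generate a sequence of synthetic 8x8 thermal frames
#'
#' Emulates a 64-point thermopile array under three regimes: `ambient`
#' (constant baseline plus pixel noise), `warming` (slow linear ramp on a
#' sub-region, default ~0.08 degC/s, the kind of rise a closed cabin shows
#' on a hot day) and `flame` (localized hot pixels with large
#' frame-to-frame transitions, reaching a few hundred degC).
#'
#' @param regime `"ambient"`, `"warming"` or `"flame"`.
#' @param n_frames number of frames (>= 1).
#' @param fps frame rate in Hz (default 10).
#' @param seed integer seed.
#' @param baseline_c ambient baseline in degC (default 22).
#' @param noise_sd per-pixel i.i.d. Gaussian noise, degC (default 0.3).
#' @return A list of [thermal_frame()] objects with monotone timestamps.
#' @export
gen_thermal_sequence <- function(regime = c("ambient", "warming", "flame"),
                                 n_frames = 50, fps = 10, seed = NULL,
                                 baseline_c = 22, noise_sd = 0.3) {
  regime <- match.arg(regime)
  if (!is.finite(n_frames) || n_frames < 1) {
    stop("`n_frames` must be >= 1", call. = FALSE)
  }
  n_frames <- as.integer(n_frames)
  times <- (seq_len(n_frames) - 1) / fps
  with_seed(seed, {
    hot_r <- sample(2:7, 1)
    hot_c <- sample(2:7, 1)
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      g <- matrix(baseline_c, 8, 8)
      tk <- times[k]
      if (regime == "warming") {
        # 2x2 sub-region ramping at ~0.08 degC/s
        g[hot_r + (0:1) - 1, hot_c + (0:1) - 1] <-
          g[hot_r + (0:1) - 1, hot_c + (0:1) - 1] + 0.08 * tk
      } else if (regime == "flame") {
        # flame appears a third of the way in, flickering hot core
        if (k > n_frames / 3) {
          core <- baseline_c + 250 + 80 * stats::runif(1, -1, 1)
          g[hot_r, hot_c] <- core
          g[hot_r + sample(c(-1, 1), 1), hot_c] <- baseline_c + 120 +
            60 * stats::runif(1, -1, 1)
        }
      }
      if (noise_sd > 0) g <- g + noise_sd * matrix(stats::rnorm(64), 8, 8)
      frames[[k]] <- thermal_frame(g, time_s = tk)
    }
    frames
  })
}

#' Capacitive coupling channel model
#'
#' Models non-contact acquisition through clothing: each insulating layer
#' between the body and the electrode plate contributes a series LC
#' impedance `Z_i = j*w*L_i + 1/(j*w*C_i)`, summed over layers into
#' `Z_tot(w)`, which forms a voltage divider against the amplifier input
#' impedance. On top of the frequency-dependent attenuation, the vehicular
#' environment adds 50 Hz mains hum and seeded impulsive voltage spikes
#' (engine ignition / inductive transients), modelled as Poisson-timed
#' biphasic impulses.
#'
#' Layer inductance/capacitance values for real clothing are not tabulated
#' anywhere; the defaults are illustrative (a single 10 nF layer).
#'
#' @param layers list of `c(L, C)` pairs (henry, farad), one per insulating
#'   layer; `list()` means no attenuation.
#' @param z_in amplifier input impedance in ohm (resistive; default 100 Mohm,
#'   a typical high-impedance front end).
#' @param mains_amp amplitude of the 50 Hz hum, in the units of the trace
#'   it is applied to (default 0).
#' @param mains_hz mains frequency (default 50).
#' @param spike_rate expected impulses per second (default 0).
#' @param spike_amp impulse amplitude (default 0).
#' @param seed integer seed controlling hum phase and spike times.
#' @return An object of class `capacitive_channel`.
#' @export
capacitive_channel <- function(layers = list(c(L = 0, C = 10e-9)),
                               z_in = 1e8, mains_amp = 0, mains_hz = 50,
                               spike_rate = 0, spike_amp = 0, seed = NULL) {
  for (ly in layers) {
    if (length(ly) != 2L) stop("each layer is a (L, C) pair", call. = FALSE)
    if (ly[[2]] <= 0) stop("layer capacitance must be > 0", call. = FALSE)
    if (ly[[1]] < 0) stop("layer inductance must be >= 0", call. = FALSE)
  }
  if (z_in <= 0) stop("`z_in` must be > 0", call. = FALSE)
  structure(list(layers = layers, z_in = z_in, mains_amp = mains_amp,
                 mains_hz = mains_hz, spike_rate = spike_rate,
                 spike_amp = spike_amp, seed = seed),
            class = "capacitive_channel")
}

#' Transfer gain of the capacitive channel at given frequencies
#'
#' Complex voltage-divider gain `H(f) = Z_in / (Z_in + Z_tot(2*pi*f))` with
#' `Z_tot` the series sum of the layer LC impedances. At DC the layer
#' capacitances block entirely, so `H(0) = 0` whenever at least one layer
#' is present.
#'
#' @param channel a [capacitive_channel()].
#' @param freqs_hz numeric vector of frequencies.
#' @return complex vector of gains, same length as `freqs_hz`.
#' @export
channel_gain <- function(channel, freqs_hz) {
  stopifnot(inherits(channel, "capacitive_channel"))
  if (!length(channel$layers)) return(rep(complex(real = 1), length(freqs_hz)))
  w <- 2 * pi * freqs_hz
  ztot <- rep(complex(real = 0), length(w))
  for (ly in channel$layers) {
    L <- ly[[1]]; C <- ly[[2]]
    zi <- complex(imaginary = w * L)
    nz <- w != 0
    zi[nz] <- zi[nz] + 1 / complex(imaginary = w[nz] * C)
    zi[!nz] <- complex(real = Inf)
    ztot <- ztot + zi
  }
  h <- channel$z_in / (channel$z_in + ztot)
  h[!is.finite(Re(h)) | !is.finite(Im(h))] <- 0
  h[freqs_hz == 0 & length(channel$layers) > 0] <-
    complex(real = 0)
  h
}

#' Degrade a trace through the capacitive coupling channel
#'
#' Applies the layer-impedance voltage divider in the frequency domain
#' (FFT multiply by the divider gain, Hermitian-symmetric so the output is
#' real), then adds 50 Hz mains hum and seeded Poisson-timed biphasic
#' spikes. A channel with zero layers and zero noise is exactly the
#' identity. With all noise amplitudes zero the operator is linear in the
#' input.
#'
#' @param trace a non-empty [signal_trace()].
#' @param channel a [capacitive_channel()].
#' @return A degraded [signal_trace()] with the same length and metadata.
#' @export
apply_capacitive_channel <- function(trace, channel) {
  stopifnot(inherits(trace, "signal_trace"), inherits(channel, "capacitive_channel"))
  n <- length(trace)
  if (n == 0L) stop("`trace` must be non-empty", call. = FALSE)
  x <- trace$samples
  if (length(channel$layers)) {
    freqs <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)] *
      trace$fs / n
    h <- channel_gain(channel, abs(freqs))
    # Hermitian symmetry: negative-frequency bins take the conjugate gain
    # so the filtered signal stays real with the correct amplitude.
    neg <- freqs < 0
    h[neg] <- Conj(h[neg])
    x <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
  }
  if (channel$mains_amp > 0 || (channel$spike_rate > 0 && channel$spike_amp > 0)) {
    t <- (seq_len(n) - 1) / trace$fs
    x <- x + with_seed(channel$seed, {
      noise <- numeric(n)
      if (channel$mains_amp > 0) {
        noise <- noise + channel$mains_amp *
          sin(2 * pi * channel$mains_hz * t + stats::runif(1, 0, 2 * pi))
      }
      if (channel$spike_rate > 0 && channel$spike_amp > 0) {
        n_spk <- stats::rpois(1, channel$spike_rate * n / trace$fs)
        if (n_spk > 0) {
          pos <- sort(sample.int(n, min(n_spk, n)))
          amp <- channel$spike_amp * stats::runif(length(pos), 0.5, 1)
          for (i in seq_along(pos)) {
            # biphasic: sharp positive lobe then negative lobe, ~4 ms each
            w <- max(1L, round(0.004 * trace$fs))
            idx1 <- pos[i]:min(n, pos[i] + w - 1)
            noise[idx1] <- noise[idx1] + amp[i]
            idx2 <- min(n, pos[i] + w):min(n, pos[i] + 2 * w - 1)
            noise[idx2] <- noise[idx2] - amp[i]
          }
        }
      }
      noise
    })
  }
  trace_with(trace, x)
}
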