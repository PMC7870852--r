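# Shared fixtures, built in code.

# noiseless multi-channel sinusoid series on a 1 Hz axis
sinusoid_series <- function(f = 1 / 480, n = 3600, lags = c(a = 0, b = 0),
                            amp = 1) {
  t <- seq_len(n) - 1
  ch <- vapply(lags, function(l) amp * sin(2 * pi * f * t + l), numeric(n))
  chromophore_ts(t, ch)
}

# quadrature demodulation: phase of a sinusoidal channel at frequency f,
# independent of the wavelet path
quadrature_phase <- function(x, t, f) {
  Arg(sum((x - mean(x)) * exp(-2i * pi * f * t)))
}

# circular difference wrapped to (-pi, pi]
wrap_phase <- function(d) Arg(exp(1i * d))

# spec used across generator tests
clean_spec <- function(f = 1 / 480, jitter = 0, noise = 0, seed = 1,
                       duration = 3600) {
  oscillation_spec(base_frequency = f,
                   amplitude = c(oxCCO = 1, HbO2 = 1, HHb = 1),
                   phase_lag = c(oxCCO = 0, HbO2 = 0, HHb = 0),
                   period_jitter_sd = jitter, noise_sd = noise,
                   duration = duration, sampling_rate = 1, seed = seed)
}

# hand-rollable spectrum object for closed-form metric checks
toy_spectrum <- function(magnitude, df = 1e-5) {
  structure(list(frequency = (seq_along(magnitude) - 1) * df,
                 magnitude = magnitude, source_channel = "toy",
                 resolution = df, zero_padding_factor = 1L),
            class = "nirs_spectrum")
}
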