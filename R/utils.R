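# Seed substreams and small FFT helpers shared across modules.

# Deterministic 32-bit seed for a named substream. All randomness in the
# package flows from one master seed through these; identical master seed and
# labels give identical streams, distinct labels give (practically)
# independent ones.
substream_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% 2147483647
  as.integer(max(1, h))
}

with_substream <- function(seed, ..., code) {
  withr::with_seed(substream_seed(seed, ...), code)
}

# One-sided FFT (bins 0 .. Nyquist).
rfft <- function(x) {
  stats::fft(x)[seq_len(length(x) %/% 2 + 1)]
}

rfft_freq <- function(n, rate) {
  seq(0, by = rate / n, length.out = n %/% 2 + 1)
}

# Inverse of rfft: real signal of length n from its one-sided spectrum.
irfft <- function(spec, n) {
  nf <- length(spec)
  stopifnot(nf == n %/% 2 + 1)
  spec[1] <- complex(real = Re(spec[1]), imaginary = 0)
  if (n %% 2 == 0) spec[nf] <- complex(real = Re(spec[nf]), imaginary = 0)
  tail_idx <- if (n %% 2 == 0) seq(nf - 1, 2) else seq(nf, 2)
  full <- c(spec, Conj(spec[tail_idx]))
  Re(stats::fft(full, inverse = TRUE)) / n
}

# Gaussian noise with a 1/f power spectrum (high-passed at 0.5 Hz), unit sd.
pink_noise <- function(n, rate) {
  nf <- n %/% 2 + 1
  f <- rfft_freq(n, rate)
  amp <- ifelse(f < 0.5, 0, 1 / sqrt(f))
  spec <- amp * complex(real = rnorm(nf), imaginary = rnorm(nf))
  x <- irfft(spec, n)
  s <- sd(x)
  if (s == 0) return(numeric(n))
  (x - mean(x)) / s
}

# Band-limited Gaussian noise centered at `center` Hz, unit sd.
narrowband_noise <- function(n, rate, center, bw = 2) {
  nf <- n %/% 2 + 1
  f <- rfft_freq(n, rate)
  sel <- as.numeric(f >= center - bw / 2 & f <= center + bw / 2)
  spec <- sel * complex(real = rnorm(nf), imaginary = rnorm(nf))
  x <- irfft(spec, n)
  s <- sd(x)
  if (s == 0) return(numeric(n))
  (x - mean(x)) / s
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(paste0(what, " contains non-finite values"),
          class = "dyadsync_input_error")
  }
  invisible(x)
}

phase_factor <- function(x, levels = phase_levels()) {
  factor(as.character(x), levels = levels)
}
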