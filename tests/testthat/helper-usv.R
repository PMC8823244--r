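# tiny model configuration used for fast structural tests
tiny_model_config <- function(seed = 7L) {
  model_config(bands = 12L, context = 3L, conv1d_kernel = 3L,
               conv1d_channels = 2L, conv2d_kernel = c(3L, 3L),
               conv2d_channels = 2L, hidden = 4L, seed = seed)
}

# random dB-scaled feature map
random_map <- function(bands = 12L, frames = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(bands * frames, -60, 15), bands, frames)
}

# a small synthetic clip corpus (1-s clips); cached per session
tiny_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_corpus(10, 3, target_snr = 3, seed = 400)
    cache
  }
})

# full-band (124) model kept small enough for fast training tests
tiny_big_config <- function(seed = 2L) {
  model_config(conv1d_channels = 2L, conv2d_channels = 2L, hidden = 8L,
               seed = seed)
}

# unwrapped analytic-signal phase (Hilbert via FFT), for instantaneous
# frequency oracles
unwrap_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  half <- floor(n / 2)
  h[2:half] <- 2
  if (n %% 2 == 0) h[half + 1] <- 1
  z <- stats::fft(X * h, inverse = TRUE) / n
  ph <- Arg(z)
  dp <- diff(ph)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(ph[1], dp))
}
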