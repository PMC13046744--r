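# Shared fixture builders. Everything is generated in code; nothing binary.

T0 <- as.POSIXct("2015-03-02 00:00:00", tz = "UTC")

# Minute-level epoch tibble from a numeric vector.
mk_series <- function(y, epoch_s = 60, subject_id = "t1") {
  tibble::tibble(
    subject_id = subject_id,
    timestamp = T0 + (seq_along(y) - 1) * epoch_s,
    enmo_mg = y, wear = TRUE)
}

# Noise-free cosinor series sampled every minute.
mk_cosinor <- function(mesor, amplitude, acrophase, days = 3,
                      period = 24, noise_sd = 0) {
  t <- (seq_len(days * 1440) - 1) / 60
  y <- mesor + amplitude * cos(2 * pi * (t - acrophase) / period)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  mk_series(y)
}

# Independent brute-force cosinor oracle: grid over the acrophase at
# `res` hours; MESOR and amplitude by 2-parameter least squares per phase.
cosinor_grid_oracle <- function(series, res = 0.01, period = 24) {
  t <- as.numeric(difftime(series$timestamp, T0, units = "hours"))
  y <- series$enmo_mg
  phases <- seq(0, period - res, by = res)
  best <- list(sse = Inf)
  n <- length(y)
  sy <- sum(y)
  for (ph in phases) {
    cc <- cos(2 * pi * (t - ph) / period)
    sc <- sum(cc); scc <- sum(cc^2); scy <- sum(cc * y)
    det <- n * scc - sc^2
    A <- (n * scy - sc * sy) / det
    M <- (sy - A * sc) / n
    sse <- sum((y - M - A * cc)^2)
    if (sse < best$sse) best <- list(sse = sse, mesor = M, amplitude = A,
                                     acrophase = ph)
  }
  if (best$amplitude < 0) {
    best$amplitude <- -best$amplitude
    best$acrophase <- (best$acrophase + period / 2) %% period
  }
  best
}

# A cached small synthetic cohort shared by several test files.
shared_cohort <- local({
  env <- new.env()
  function() {
    if (is.null(env$co)) {
      env$co <- simulate_cohort(generator_config(n_subjects = 40, seed = 303))
    }
    env$co
  }
})
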