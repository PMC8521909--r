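# Independent brute-force oracles used to pin expected values.
# These deliberately re-derive quantities from first principles (explicit
# DFT summation, numerical quadrature) rather than calling package code.

# spectral features of one frame via explicit DFT summation (O(n^2))
oracle_spectral <- function(frame, fs, prev_frame = NULL) {
  n <- length(frame)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  mags <- function(x) {
    xw <- x * w
    ks <- 0:(n %/% 2)
    vapply(ks, function(k) {
      Mod(sum(xw * exp(-2i * pi * k * (0:(n - 1)) / n)))
    }, numeric(1))
  }
  mag <- mags(frame)
  power <- mag^2
  freqs <- (0:(n %/% 2)) * fs / n
  tot <- sum(power)
  centroid <- sum(freqs * power) / tot
  spread <- sqrt(sum((freqs - centroid)^2 * power) / tot)
  rolloff <- freqs[which(cumsum(power) >= 0.85 * tot)[1]]
  p <- power / tot
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  density <- mean(power / (fs * sum(w^2)))
  flux <- 0
  if (!is.null(prev_frame)) {
    m1 <- mags(prev_frame)
    flux <- sum((mag / sum(mag) - m1 / sum(m1))^2)
  }
  c(spectral_centroid = centroid, spectral_spread = spread,
    spectral_rolloff = rolloff, spectral_entropy = entropy,
    spectral_flux = flux, spectral_density = density)
}

# upper-tail Student-t probability by numerical quadrature of the density
oracle_t_tail <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, t, Inf, rel.tol = 1e-12)$value
}

# excess kurtosis
excess_kurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2 - 3
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
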