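# Independent reference implementations used as oracles in the tests.
# These are deliberately naive (direct transcription of the definitions)
# and stay independent of the package's implementations.

# Naive O(N^2) sample entropy: explicit template matrices, Chebyshev
# distance, strict < r, self-matches excluded, shared denominator N - m.
naiveSampen <- function(x, m = 2, rCoeff = 0.15) {
  N <- length(x)
  r <- rCoeff * sd(x)
  count <- function(mm) {
    nt <- N - m                       # same template count for mm and mm+1
    tot <- 0L
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) < r) tot <- tot + 1L
      }
    }
    tot
  }
  B <- count(m)
  A <- count(m + 1)
  if (B == 0) return(NaN)
  if (A == 0) return(Inf)
  -log(A / B)
}

# Phase difference oracle via R's fft-based analytic signal, written
# independently of the package helper (different construction: explicit
# Hilbert transform through a quadrature filter in the frequency domain).
oraclePhase <- function(x) {
  n <- length(x)
  X <- fft(x)
  f <- seq_len(n) - 1
  sgn <- ifelse(f == 0 | (n %% 2 == 0 & f == n / 2), 0,
                ifelse(f < n / 2, -1, 1))
  hx <- Re(fft(X * (1i * sgn), inverse = TRUE) / n)
  Arg(complex(real = x, imaginary = hx))
}

# Simple sinusoid helper
tone <- function(freq, fs, dur, phase = 0, amp = 1) {
  amp * sin(2 * pi * freq * (0:(round(fs * dur) - 1)) / fs + phase)
}

# Build a tiny EEGRecording fixture from a channels x samples matrix
makeRecording <- function(data, fs = 250, group = "HC", id = "S1",
                          channels = paste0("ch", seq_len(nrow(data)))) {
  EEGRecording(id, group, fs, data, channels = channels)
}
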