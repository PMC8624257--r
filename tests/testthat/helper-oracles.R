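# Independent direct-formula oracles for the time-domain features.
# Deliberately written as plain loops straight from the printed formulas,
# sharing no code with the package implementation.

oracle_feature <- function(x, name, threshold = 0, order = 2,
                           log_eps = 1e-12) {
  N <- length(x)
  switch(
    name,
    IEMG = { s <- 0; for (i in 1:N) s <- s + abs(x[i]); s },
    MAV = { s <- 0; for (i in 1:N) s <- s + abs(x[i]); s / N },
    MAV1 = {
      s <- 0
      for (i in 1:N) {
        w <- if (i >= 0.25 * N && i <= 0.75 * N) 1 else 0.5
        s <- s + w * abs(x[i])
      }
      s / N
    },
    MAV2 = {
      s <- 0
      for (i in 1:N) {
        w <- if (i >= 0.25 * N && i <= 0.75 * N) 1
             else if (i < 0.25 * N) 4 * i / N
             else 4 * (i - N) / N
        s <- s + w * abs(x[i])
      }
      s / N
    },
    SSI = { s <- 0; for (i in 1:N) s <- s + x[i]^2; s },
    VAR = { s <- 0; for (i in 1:N) s <- s + x[i]^2; s / (N - 1) },
    TM3 = { s <- 0; for (i in 1:N) s <- s + x[i]^3; abs(s / N) },
    TM4 = { s <- 0; for (i in 1:N) s <- s + x[i]^4; s / N },
    TM5 = { s <- 0; for (i in 1:N) s <- s + x[i]^5; abs(s / N) },
    RMS = { s <- 0; for (i in 1:N) s <- s + x[i]^2; sqrt(s / N) },
    LOG = {
      s <- 0
      for (i in 1:N) s <- s + log(max(abs(x[i]), log_eps))
      exp(s / N)
    },
    WL = { s <- 0; for (i in 1:(N - 1)) s <- s + abs(x[i + 1] - x[i]); s },
    AAC = { s <- 0; for (i in 1:(N - 1)) s <- s + abs(x[i + 1] - x[i]); s / N },
    DASDV = {
      s <- 0
      for (i in 1:(N - 1)) s <- s + (x[i + 1] - x[i])^2
      sqrt(s / (N - 1))
    },
    ZC = {
      s <- 0
      for (i in 1:(N - 1))
        if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= threshold)
          s <- s + 1
      s
    },
    WAMP = {
      s <- 0
      for (i in 1:(N - 1)) if (abs(x[i] - x[i + 1]) >= threshold) s <- s + 1
      s
    },
    MYOP = {
      s <- 0
      for (i in 1:N) if (abs(x[i]) >= threshold) s <- s + 1
      s / N
    },
    SSC = {
      s <- 0
      for (i in 2:(N - 1))
        if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) >= threshold) s <- s + 1
      s
    },
    AR = oracle_yule_walker(x, order),
    CC = oracle_cepstrum_fft(oracle_yule_walker(x, order)),
    stop("no oracle for ", name)
  )
}

# Yule-Walker AR coefficients by explicitly building and solving the
# Toeplitz normal equations with biased (1/N) autocovariances, no mean
# removal; independent of the Levinson-Durbin recursion.
oracle_yule_walker <- function(x, p) {
  N <- length(x)
  r <- numeric(p + 1)
  for (j in 0:p) {
    s <- 0
    for (i in 1:(N - j)) s <- s + x[i] * x[i + j]
    r[j + 1] <- s / N
  }
  Rm <- matrix(0, p, p)
  for (a in 1:p) for (b in 1:p) Rm[a, b] <- r[abs(a - b) + 1]
  as.numeric(solve(Rm, r[2:(p + 1)]))
}

# Cepstrum oracle: numeric inverse Fourier coefficients of
# -log(1 + sum_k a_k e^{-i w k}) on a dense grid; independent of the
# package's recursion.
oracle_cepstrum_fft <- function(a, M = 8192) {
  p <- length(a)
  w <- 2 * pi * (0:(M - 1)) / M
  A <- 1 + 0i
  for (k in seq_len(p)) A <- A + a[k] * exp(-1i * w * k)
  ln <- -log(A)
  vapply(seq_len(p), function(n)
    Re(mean(ln * exp(1i * w * n))), numeric(1))
}

# Second, structurally different implementation of the cepstral recursion
# (top-down recursive function with memo-free evaluation), for
# cross-checking the package's iterative form on arbitrary coefficients.
oracle_cepstrum_recursion <- function(a) {
  cep <- function(n) {
    if (n == 1) return(-a[1])
    s <- 0
    for (l in seq_len(n - 1)) s <- s + (1 - l / n) * a[l] * cep(n - l)
    -a[n] - s
  }
  vapply(seq_along(a), cep, numeric(1))
}

# Reference Pearson r written out from the definition.
oracle_pearson <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
}
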