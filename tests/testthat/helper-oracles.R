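# Independent oracles used to cross-check the package implementations.
# Each is written as directly (and naively) as possible so it shares no code
# path with the functions it checks.

# Plug-in mutual information of two discrete vectors, in bits, by explicit
# joint-histogram loops; optional Miller-Madow correction.
oracle_mi <- function(X, Y, correct = TRUE) {
  xs <- sort(unique(X)); ys <- sort(unique(Y))
  n <- length(X)
  mi <- 0
  kxy <- 0
  for (a in xs) {
    for (b in ys) {
      nab <- sum(X == a & Y == b)
      if (nab > 0) {
        kxy <- kxy + 1
        pab <- nab / n
        pa <- sum(X == a) / n
        pb <- sum(Y == b) / n
        mi <- mi + pab * log(pab / (pa * pb))
      }
    }
  }
  if (correct) {
    mi <- mi + ((length(xs) - 1) + (length(ys) - 1) - (kxy - 1)) / (2 * n)
  }
  max(mi / log(2), 0)
}

# Brute-force Shi-Tomasi score: min eigenvalue of the windowed gradient
# structure tensor at every interior pixel (per-pixel average), via loops.
oracle_min_eig <- function(img, window) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 2:(nc - 1)) gx[i, j] <- (img[i, j + 1] - img[i, j - 1]) / 2
  for (i in 2:(nr - 1)) for (j in 1:nc) gy[i, j] <- (img[i + 1, j] - img[i - 1, j]) / 2
  h <- (window - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  for (i in (h + 1):(nr - h)) {
    for (j in (h + 1):(nc - h)) {
      wi <- (i - h):(i + h); wj <- (j - h):(j + h)
      sxx <- sum(gx[wi, wj]^2); syy <- sum(gy[wi, wj]^2)
      sxy <- sum(gx[wi, wj] * gy[wi, wj])
      ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2), symmetric = TRUE,
                  only.values = TRUE)$values
      out[i, j] <- min(ev) / window^2
    }
  }
  out
}

# Integer circular shift: content moves by +dx columns / +dy rows.
roll_image <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[((0:(nr - 1) - dy) %% nr) + 1, ((0:(nc - 1) - dx) %% nc) + 1]
}

# Spectral (Fourier phase-ramp) shift: content moves by (+dx, +dy) pixels,
# supports sub-pixel amounts; periodic boundary.
spectral_shift <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  kx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  ky <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  ph <- exp(-2i * pi * (outer(ky, rep(1, nc)) * dy / nr +
                          outer(rep(1, nr), kx) * dx / nc))
  Re(fft(fft(m) * ph, inverse = TRUE)) / (nr * nc)
}

# Phase-correlation displacement estimate (independent of Lucas-Kanade):
# cross-power-spectrum peak with 3-point parabolic sub-pixel refinement.
# Returns c(dx, dy), same sign convention as the tracker.
phase_corr_shift <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  Fa <- fft(a - mean(a)); Fb <- fft(b - mean(b))
  R <- Fb * Conj(Fa)
  R <- R / pmax(Mod(R), 1e-12)
  corr <- Re(fft(R, inverse = TRUE)) / (nr * nc)
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  parab <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < 1e-12) 0 else 0.5 * (cm - cp) / den
  }
  i <- pk[1]; j <- pk[2]
  im <- ((i - 2) %% nr) + 1; ip <- (i %% nr) + 1
  jm <- ((j - 2) %% nc) + 1; jp <- (j %% nc) + 1
  dy <- wrap(i, nr) + parab(corr[im, j], corr[i, j], corr[ip, j])
  dx <- wrap(j, nc) + parab(corr[i, jm], corr[i, j], corr[i, jp])
  c(dx = unname(dx), dy = unname(dy))
}

# Quantized speckle texture for tracking tests.
make_texture <- function(nr = 96, nc = 96, grain = 1.5, seed = 1) {
  set.seed(seed)
  base <- usifi:::gaussian_smooth_fft(matrix(rnorm(nr * nc), nr, nc), grain)
  base <- 0.5 + 0.16 * (base - mean(base)) / sd(base)
  usifi:::quantize_8bit(base)
}

# Interior features of a texture (margin keeps LK windows in-bounds after
# circular shifts up to a few pixels).
interior_features <- function(img, margin = 14, max_count = 60) {
  f <- select_features(img, max_count = max_count)
  f[f$x > margin & f$x < ncol(img) - 1 - margin &
      f$y > margin & f$y < nrow(img) - 1 - margin, ]
}

# Exhaustive optimal 2-partition of 1-D data (minimum within-class sum of
# squares over all sorted split points).
oracle_2partition <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- NULL
  best_ss <- Inf
  for (k in 1:(n - 1)) {
    a <- xs[1:k]; b <- xs[(k + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- list(centres = c(mean(a), mean(b)), fractions = c(k, n - k) / n)
    }
  }
  best
}
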