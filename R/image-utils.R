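# Image helpers shared by the speckle generator and the tracker.
#
# Coordinate convention (used everywhere in this package): origin at the
# centre of the top-left pixel, x = column index (rightward), y = row index
# (downward), both 0-based; matrix element img[i, j] sits at (x, y) =
# (j - 1, i - 1).

# Bilinear sampling of `img` at 0-based coordinates (x, y); coordinates are
# clamped to the image border (edge extension). x, y are equal-length vectors.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(x0, nc - 2); y0 <- pmin(y0, nr - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * nr          # linear index of (row y0+1, col x0+1)
  v00 <- img[i00]
  v10 <- img[i00 + nr]             # x0+1
  v01 <- img[i00 + 1]              # y0+1
  v11 <- img[i00 + nr + 1]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

# Gaussian low-pass filter via circular FFT convolution; sigma in pixels.
gaussian_smooth_fft <- function(img, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  ky <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  kx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  gy <- exp(-ky^2 / (2 * sigma^2))
  gx <- exp(-kx^2 / (2 * sigma^2))
  kern <- outer(gy / sum(gy), gx / sum(gx))
  Re(fft(fft(img) * fft(kern), inverse = TRUE)) / (nr * nc)
}

# Central-difference gradients; borders set to 0.
image_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  list(gx = gx, gy = gy)
}

# Windowed sums of a matrix over a centred square window of odd side `w`,
# computed with an integral image. Entries whose window leaves the image are
# returned as NA.
window_sums <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  h <- (w - 1L) / 2L
  ii <- rbind(0, apply(m, 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))   # (nr+1) x (nc+1) integral image
  out <- matrix(NA_real_, nr, nc)
  rows <- (h + 1L):(nr - h)
  cols <- (h + 1L):(nc - h)
  r0 <- rows - h; r1 <- rows + h
  c0 <- cols - h; c1 <- cols + h
  out[rows, cols] <- ii[r1 + 1L, c1 + 1L, drop = FALSE] -
    ii[r0, c1 + 1L, drop = FALSE] -
    ii[r1 + 1L, c0, drop = FALSE] +
    ii[r0, c0, drop = FALSE]
  out
}

# Quantize intensities to 8-bit levels on [0, 1].
quantize_8bit <- function(img) {
  round(pmin(pmax(img, 0), 1) * 255) / 255
}
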