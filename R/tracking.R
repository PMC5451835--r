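#' Select trackable features (Shi-Tomasi minimum-eigenvalue corners)
#'
#' Scores every pixel by the smaller eigenvalue of the structure tensor of
#' the local intensity gradients, summed over a `window` x `window`
#' neighbourhood and normalized per pixel. High scores mark regions whose
#' position can be re-identified reliably in the next frame. Local maxima of
#' the score above `min_quality_ratio` times the image maximum are kept
#' greedily in descending quality, enforcing a pairwise separation of at
#' least `min_separation` pixels, up to `max_count` features.
#'
#' @param image Numeric matrix (grayscale frame, any intensity scale).
#' @param max_count Maximum number of features returned.
#' @param window Odd window side in pixels for the structure tensor.
#' @param min_quality_ratio Keep only features whose quality is at least this
#'   fraction of the best quality in the image.
#' @param min_separation Minimum pairwise distance between features (pixels).
#' @return A tibble with columns `x`, `y` (0-based pixel coordinates,
#'   x = column, y = row) and `quality` (min-eigenvalue score,
#'   intensity^2/pixel^2), sorted by descending quality. A flat image yields
#'   zero rows.
#' @export
#' @examples
#' img <- matrix(0, 64, 64); img[30:34, 30:34] <- 1
#' select_features(img, max_count = 5)
select_features <- function(image, max_count = 200, window = 15,
                            min_quality_ratio = 0.05, min_separation = 8) {
  stopifnot(is.matrix(image), window %% 2 == 1)
  if (nrow(image) < window || ncol(image) < window) {
    abort("`image` must be at least `window` x `window`.")
  }
  g <- image_gradients(image)
  sxx <- window_sums(g$gx * g$gx, window)
  syy <- window_sums(g$gy * g$gy, window)
  sxy <- window_sums(g$gx * g$gy, window)
  lam <- 0.5 * (sxx + syy - sqrt((sxx - syy)^2 + 4 * sxy^2)) / window^2
  qmax <- suppressWarnings(max(lam, na.rm = TRUE))
  empty <- tibble(x = numeric(), y = numeric(), quality = numeric())
  if (!is.finite(qmax) || qmax <= 0) return(empty)

  ok <- !is.na(lam) & lam >= min_quality_ratio * qmax & local_maxima(lam)
  idx <- which(ok)
  if (!length(idx)) return(empty)
  nr <- nrow(image)
  cand <- tibble(
    x = ((idx - 1L) %/% nr),      # 0-based column
    y = ((idx - 1L) %% nr),       # 0-based row
    quality = lam[idx]
  )
  cand <- cand[order(-cand$quality), , drop = FALSE]

  # greedy acceptance with a bucket grid so separation checks stay local
  cell <- max(min_separation, 1)
  keyx <- cand$x %/% cell
  keyy <- cand$y %/% cell
  accepted <- integer(0)
  buckets <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cand))) {
    ok_i <- TRUE
    for (bx in (keyx[i] - 1):(keyx[i] + 1)) {
      for (by in (keyy[i] - 1):(keyy[i] + 1)) {
        key <- paste0(bx, ",", by)
        js <- buckets[[key]]
        if (!is.null(js)) {
          if (any((cand$x[js] - cand$x[i])^2 + (cand$y[js] - cand$y[i])^2 <
            min_separation^2)) {
            ok_i <- FALSE
            break
          }
        }
      }
      if (!ok_i) break
    }
    if (ok_i) {
      accepted <- c(accepted, i)
      key <- paste0(keyx[i], ",", keyy[i])
      buckets[[key]] <- c(buckets[[key]], i)
      if (length(accepted) >= max_count) break
    }
  }
  cand[accepted, , drop = FALSE]
}

# TRUE where a matrix entry is >= all its 8 neighbours (NA-safe, borders FALSE)
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  if (nr < 3 || nc < 3) return(out)
  ctr <- m[2:(nr - 1), 2:(nc - 1)]
  res <- !is.na(ctr)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- m[(2 + di):(nr - 1 + di), (2 + dj):(nc - 1 + dj)]
      res <- res & (is.na(nb) | ctr >= nb)
    }
  }
  out[2:(nr - 1), 2:(nc - 1)] <- res
  out
}

#' Track features between two frames (Lucas-Kanade)
#'
#' Estimates the displacement of each feature from `frame_a` to `frame_b` by
#' iterative least squares on the windowed image gradients (the classic
#' single-level Lucas-Kanade normal equations): at each step the update
#' `G^-1 b` is applied, where `G` is the 2x2 gradient structure tensor over
#' the feature window and `b` accumulates the intensity residual against the
#' displaced window in `frame_b`. Iteration stops when the update falls
#' below `convergence_tol` or after `max_iterations`.
#'
#' Features are dropped (and reflected in `tracked_fraction`) when their
#' structure tensor is near-singular, their displaced window leaves the
#' image, or their displacement exceeds `max_displacement`.
#'
#' @param frame_a,frame_b Numeric matrices of identical size.
#' @param features Tibble with columns `x`, `y` as from [select_features()].
#' @param window Odd window side (pixels).
#' @param max_iterations Iteration cap per feature.
#' @param convergence_tol Stop when the update norm falls below this (pixels).
#' @param max_displacement Drop features displaced further than this (pixels).
#' @param pyramid_levels Number of pyramid levels; 1 (the default) is plain
#'   single-level tracking, suited to the small inter-frame movements of
#'   twitches. Higher values first estimate the displacement on 2x-decimated
#'   frames, extending the convergence basin beyond the texture correlation
#'   length.
#' @return A `motion_field`: tibble with columns `x`, `y`, `dx`, `dy`
#'   (pixels; `dx, dy` = position in `frame_b` minus position in `frame_a`),
#'   with attributes `tracked_fraction` and `image_size`.
#' @export
track_features <- function(frame_a, frame_b, features, window = 15,
                           max_iterations = 30, convergence_tol = 0.01,
                           max_displacement = 5, pyramid_levels = 1) {
  stopifnot(is.matrix(frame_a), is.matrix(frame_b),
            all(dim(frame_a) == dim(frame_b)), window %% 2 == 1,
            pyramid_levels >= 1)
  n_in <- nrow(features)
  if (n_in == 0L) {
    return(new_motion_field(tibble(x = numeric(), y = numeric(),
                                   dx = numeric(), dy = numeric()),
                            tracked_fraction = 0, image_size = dim(frame_a)))
  }
  init <- matrix(0, n_in, 2)
  if (pyramid_levels > 1) {
    a2 <- halve_image(frame_a); b2 <- halve_image(frame_b)
    coarse_feats <- features
    coarse_feats$x <- features$x / 2
    coarse_feats$y <- features$y / 2
    coarse <- track_features(a2, b2, coarse_feats, window,
                             max_iterations, convergence_tol,
                             max_displacement / 2, pyramid_levels - 1)
    # map the coarse estimates back onto the original feature list
    key <- paste(coarse_feats$x, coarse_feats$y)
    hit <- match(key, paste(coarse$x, coarse$y))
    ok <- !is.na(hit)
    init[ok, 1] <- 2 * coarse$dx[hit[ok]]
    init[ok, 2] <- 2 * coarse$dy[hit[ok]]
  }
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  h <- (window - 1) / 2
  off <- expand.grid(u = -h:h, v = -h:h)
  x0 <- features$x; y0 <- features$y
  Xw <- outer(x0, off$u, "+")     # n x w^2 sample coordinates
  Yw <- outer(y0, off$v, "+")

  inside <- function(X, Y) {
    X >= 0 & X <= nc - 1 & Y >= 0 & Y <= nr - 1
  }
  valid <- rowSums(!inside(Xw, Yw)) == 0

  g <- image_gradients(frame_a)
  tmpl <- matrix(bilinear_sample(frame_a, Xw, Yw), n_in)
  gxw <- matrix(bilinear_sample(g$gx, Xw, Yw), n_in)
  gyw <- matrix(bilinear_sample(g$gy, Xw, Yw), n_in)
  gxx <- rowSums(gxw * gxw)
  gyy <- rowSums(gyw * gyw)
  gxy <- rowSums(gxw * gyw)
  det <- gxx * gyy - gxy^2
  lam_min <- 0.5 * (gxx + gyy - sqrt((gxx - gyy)^2 + 4 * gxy^2))
  valid <- valid & det > .Machine$double.eps & lam_min > 1e-10

  dx <- init[, 1]; dy <- init[, 2]
  active <- valid
  for (iter in seq_len(max_iterations)) {
    if (!any(active)) break
    ia <- which(active)
    Xa <- Xw[ia, , drop = FALSE] + dx[ia]
    Ya <- Yw[ia, , drop = FALSE] + dy[ia]
    oob <- rowSums(!inside(Xa, Ya)) > 0
    if (any(oob)) {
      valid[ia[oob]] <- FALSE
      active[ia[oob]] <- FALSE
      ia <- ia[!oob]
      if (!length(ia)) break
      Xa <- Xa[!oob, , drop = FALSE]; Ya <- Ya[!oob, , drop = FALSE]
    }
    B <- matrix(bilinear_sample(frame_b, Xa, Ya), length(ia))
    r <- tmpl[ia, , drop = FALSE] - B
    bx <- rowSums(r * gxw[ia, , drop = FALSE])
    by <- rowSums(r * gyw[ia, , drop = FALSE])
    ddx <- (gyy[ia] * bx - gxy[ia] * by) / det[ia]
    ddy <- (gxx[ia] * by - gxy[ia] * bx) / det[ia]
    dx[ia] <- dx[ia] + ddx
    dy[ia] <- dy[ia] + ddy
    over <- dx[ia]^2 + dy[ia]^2 > max_displacement^2
    if (any(over)) {
      valid[ia[over]] <- FALSE
      active[ia[over]] <- FALSE
    }
    done <- ddx^2 + ddy^2 < convergence_tol^2
    active[ia[done]] <- FALSE
  }
  valid <- valid & is.finite(dx) & is.finite(dy)

  out <- tibble(
    x = x0[valid], y = y0[valid], dx = dx[valid], dy = dy[valid]
  )
  new_motion_field(out, tracked_fraction = sum(valid) / n_in,
                   image_size = c(nr, nc))
}

# 2x decimation by block averaging (odd trailing row/column dropped)
halve_image <- function(m) {
  nr <- 2L * (nrow(m) %/% 2L); nc <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(nr), seq_len(nc)]
  (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
     m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

new_motion_field <- function(tbl, tracked_fraction, image_size) {
  attr(tbl, "tracked_fraction") <- tracked_fraction
  attr(tbl, "image_size") <- image_size
  class(tbl) <- unique(c("motion_field", class(tbl)))
  tbl
}

#' Track a whole image sequence
#'
#' Runs [select_features()] and [track_features()] on every consecutive frame
#' pair. Features are re-selected for each transition (no chaining), so
#' selection errors do not accumulate across the sequence.
#'
#' @param frames List of numeric matrices, or a `speckle_sequence` from
#'   [generate_speckle_sequence()] (its frames are used).
#' @param max_count,window,min_quality_ratio,min_separation Passed to
#'   [select_features()].
#' @param max_iterations,convergence_tol,max_displacement Passed to
#'   [track_features()].
#' @return A tibble with columns `transition_index` (0-based), `x`, `y`,
#'   `dx`, `dy` — one row per tracked vector — with attributes `image_size`
#'   and `transitions` (a tibble of `transition_index`, `n_features`,
#'   `n_tracked`, `tracked_fraction`).
#' @export
track_sequence <- function(frames, max_count = 200, window = 15,
                           min_quality_ratio = 0.05, min_separation = 8,
                           max_iterations = 30, convergence_tol = 0.01,
                           max_displacement = 5) {
  if (inherits(frames, "speckle_sequence")) frames <- frames$frames
  if (!is.list(frames) || length(frames) < 2L) {
    abort("`frames` must be a list of at least 2 frames.")
  }
  n <- length(frames)
  fields <- vector("list", n - 1L)
  meta <- vector("list", n - 1L)
  feats <- select_features(frames[[1]], max_count, window,
                           min_quality_ratio, min_separation)
  for (k in seq_len(n - 1L)) {
    mf <- track_features(frames[[k]], frames[[k + 1L]], feats, window,
                         max_iterations, convergence_tol, max_displacement)
    fields[[k]] <- dplyr::mutate(as_tibble(mf), transition_index = k - 1L,
                                 .before = 1)
    meta[[k]] <- tibble(
      transition_index = k - 1L,
      n_features = nrow(feats),
      n_tracked = nrow(mf),
      tracked_fraction = attr(mf, "tracked_fraction")
    )
    if (k < n - 1L) {
      feats <- select_features(frames[[k + 1L]], max_count, window,
                               min_quality_ratio, min_separation)
    }
  }
  out <- dplyr::bind_rows(fields)
  attr(out, "image_size") <- dim(frames[[1]])
  attr(out, "transitions") <- dplyr::bind_rows(meta)
  out
}
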