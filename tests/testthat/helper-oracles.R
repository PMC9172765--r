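# Brute-force reference implementations used as independent oracles.
# These deliberately use plain loops and index clamping, not the package's
# code paths.

clampi <- function(i, lo, hi) pmin(pmax(i, lo), hi)

# box mean over (kx, ky, kt) with replicate padding, direct triple loop
oracle_box3d <- function(arr, kx, ky, kt) {
  d <- dim(arr)
  out <- array(0, d)
  rx <- (kx - 1) / 2
  ry <- (ky - 1) / 2
  rt <- (kt - 1) / 2
  for (t in seq_len(d[3])) {
    for (x in seq_len(d[2])) {
      for (y in seq_len(d[1])) {
        s <- 0
        for (dt in -rt:rt) {
          for (dx in -rx:rx) {
            for (dy in -ry:ry) {
              s <- s + arr[clampi(y + dy, 1, d[1]), clampi(x + dx, 1, d[2]),
                           clampi(t + dt, 1, d[3])]
            }
          }
        }
        out[y, x, t] <- s / (kx * ky * kt)
      }
    }
  }
  out
}

# per-pixel disc min/max contrast enhancement
oracle_contrast <- function(frame, k, eps = 1e-6) {
  h <- nrow(frame)
  w <- ncol(frame)
  r <- (k - 1) / 2
  out <- matrix(0, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      vals <- c()
      for (dy in -r:r) {
        for (dx in -r:r) {
          if (dx^2 + dy^2 <= r^2) {
            yy <- y + dy
            xx <- x + dx
            if (yy >= 1 && yy <= h && xx >= 1 && xx <= w) {
              vals <- c(vals, frame[yy, xx])
            }
          }
        }
      }
      rng <- max(vals) - min(vals)
      out[y, x] <- if (rng < eps) 0 else (frame[y, x] - min(vals)) / rng
    }
  }
  out
}

# per-pixel sliding-window min/max normalization along t
oracle_window_norm <- function(arr, L, eps = 1e-6) {
  d <- dim(arr)
  out <- array(0, d)
  lo_off <- floor((L - 1) / 2)
  hi_off <- floor(L / 2)
  for (y in seq_len(d[1])) {
    for (x in seq_len(d[2])) {
      for (t in seq_len(d[3])) {
        idx <- max(1, t - lo_off):min(d[3], t + hi_off)
        vals <- arr[y, x, idx]
        rng <- max(vals) - min(vals)
        out[y, x, t] <- if (rng < eps) 0 else (arr[y, x, t] - min(vals)) / rng
      }
    }
  }
  out
}

oracle_epe <- function(est, tru, mask = NULL) {
  d <- dim(est)
  total <- 0
  n <- 0
  for (y in seq_len(d[1])) {
    for (x in seq_len(d[2])) {
      if (!is.null(mask) && !mask[y, x]) next
      total <- total + sqrt((est[y, x, 1] - tru[y, x, 1])^2 +
                            (est[y, x, 2] - tru[y, x, 2])^2)
      n <- n + 1
    }
  }
  total / n
}

# analytic band-limited test image and its exact translate
sinusoid_frame <- function(h, w, dx = 0, dy = 0) {
  xg <- matrix(rep(0:(w - 1), each = h), h, w) - dx
  yg <- matrix(rep(0:(h - 1), times = w), h, w) - dy
  0.5 + 0.18 * sin(2 * pi * xg / 13) + 0.14 * cos(2 * pi * yg / 17) +
    0.1 * sin(2 * pi * (xg + yg) / 23) + 0.05 * cos(2 * pi * (xg - 2 * yg) / 29)
}

interior <- function(m, b = 16) {
  m[(b + 1):(nrow(m) - b), (b + 1):(ncol(m) - b)]
}

# small fast synthetic scene for unit tests
small_scene <- function(f = -0.05, sigma = 0, seed = 5L) {
  syntheticScene(
    width = 48L, height = 48L,
    wave = waveModel(speed = 0.5, period = 60, upstroke = 3, decay = 12),
    deformation = deformationModel(amplitude = 2.5, tauEm = 6, sigmaD = 6),
    f = f, sigma = sigma, duration = 90L, seed = seed
  )
}
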