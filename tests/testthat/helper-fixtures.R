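# Shared fixture builders: everything is generated in code at test time.

# tiny calibrated stack with deterministic values
tiny_sequence <- function(n_frames = 3, n = 8, value = 0,
                          pixel_size_um = 1, frame_interval_s = 1) {
  frames <- array(value, c(n_frames, n, n))
  image_sequence(frames, pixel_size_um, frame_interval_s)
}

# i.i.d. Gaussian-noise movie for the 2*sigma^2 structure-function anchor
noise_movie <- function(n_frames, n, sigma, seed, pixel_size_um = 0.25,
                        frame_interval_s = 1, mean_level = 100) {
  set.seed(seed)
  frames <- array(stats::rnorm(n_frames * n * n, mean_level, sigma),
                  c(n_frames, n, n))
  image_sequence(frames, pixel_size_um, frame_interval_s)
}

# independent brute-force structure function: double loop over start times
# and lags on the raw FFTs, same normalization as the package
brute_force_sf <- function(seq, max_lag, max_pairs = Inf) {
  fr <- seq$frames
  nf <- dim(fr)[1]; n <- dim(fr)[2]
  px <- seq$pixel_size_um; L <- n * px
  ffts <- lapply(seq_len(nf), function(t) stats::fft(fr[t, , ]))
  f_cyc <- (seq_len(n) - 1) / n
  f_cyc[f_cyc >= 0.5] <- f_cyc[f_cyc >= 0.5] - 1
  qx <- 2 * pi * f_cyc / px
  qmag <- sqrt(outer(qx^2, qx^2, `+`))
  dq <- 2 * pi / L
  bin <- as.integer(round(qmag / dq))
  keep <- bin > 0
  bins <- sort(unique(bin[keep]))
  vals <- matrix(NA_real_, length(bins), max_lag)
  for (k in seq_len(max_lag)) {
    starts <- seq_len(nf - k)
    if (length(starts) > max_pairs)
      starts <- starts[unique(round(seq(1, length(starts),
                                        length.out = max_pairs)))]
    acc <- matrix(0, n, n)
    for (s in starts) acc <- acc + Mod(ffts[[s + k]] - ffts[[s]])^2
    acc <- acc / (length(starts) * n * n)
    for (bi in seq_along(bins))
      vals[bi, k] <- mean(acc[keep & bin == bins[bi]])
  }
  list(q_grid = bins * dq, values = vals)
}

# independent flood-fill component counter (BFS), 4-connectivity
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        r <- p[1] + d[1]; c <- p[2] + d[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}

# exhaustive Mann-Whitney U null enumeration for tiny groups: returns the
# two-sided p-value of the observed U under all C(n+m, n) labellings
enumerate_mw <- function(a, b) {
  u_stat <- function(x, y) sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  obs <- u_stat(a, b)
  pool <- c(a, b)
  idx <- utils::combn(length(pool), length(a))
  us <- apply(idx, 2, function(ii) u_stat(pool[ii], pool[-ii]))
  mu <- length(a) * length(b) / 2
  list(U = obs, p = mean(abs(us - mu) >= abs(obs - mu) - 1e-12))
}
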