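# Shared fixtures, built in code at test time.

# Noise-free optics for exact-recovery tests.
quiet_optics <- function(shape = c(64L, 64L), psf_sigma = 2,
                         amplitude = 100, background = 10) {
  optics_model(psf_sigma = psf_sigma, amplitude = amplitude,
               background = background, read_noise_sigma = 0,
               poisson_noise = FALSE, image_shape = shape)
}

# Render a single frame containing the given spots (tibble x, y).
render_test_frame <- function(spots, optics = quiet_optics(), seed = NULL) {
  truth <- tibble::tibble(particle_id = seq_len(nrow(spots)), frame = 0L,
                          x = spots$x, y = spots$y,
                          visible = TRUE, in_field = TRUE)
  if (!is.null(seed)) set.seed(seed)
  vesitrack:::stack_frame(render_movie(truth, optics), 1)
}

# Independent brute-force MSD oracle: explicit double loop over all pairs
# of observed frames, no vectorization shared with the implementation.
msd_oracle <- function(track) {
  f <- track$frame; x <- track$x; y <- track$y
  n <- length(f)
  sums <- list(); counts <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      tau <- f[j] - f[i]
      if (tau <= 0) next
      key <- as.character(tau)
      d2 <- (x[j] - x[i])^2 + (y[j] - y[i])^2
      sums[[key]] <- (if (is.null(sums[[key]])) 0 else sums[[key]]) + d2
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  lags <- sort(as.integer(names(sums)))
  tibble::tibble(lag = lags,
                 msd = unname(vapply(as.character(lags),
                                     function(k) sums[[k]] / counts[[k]], 0)),
                 n_pairs = unname(vapply(as.character(lags),
                                         function(k) counts[[k]], 0L)))
}

# Random synthetic track, possibly with gaps, for oracle comparisons.
random_track <- function(n_obs, with_gaps = TRUE) {
  frames <- if (with_gaps && n_obs > 3) {
    sort(sample(0:(n_obs * 2), n_obs))
  } else 0:(n_obs - 1)
  tibble::tibble(frame = frames,
                 x = cumsum(rnorm(n_obs)), y = cumsum(rnorm(n_obs)))
}

# Match detections to true positions within `radius`; greedy by distance.
match_detections <- function(det, truth, radius = 2) {
  if (nrow(det) == 0 || nrow(truth) == 0) {
    return(list(tp = 0L, fp = nrow(det), fn = nrow(truth), err = numeric(0)))
  }
  d2 <- outer(det$x, truth$x, "-")^2 + outer(det$y, truth$y, "-")^2
  ok <- which(d2 <= radius^2, arr.ind = TRUE)
  err <- numeric(0)
  if (nrow(ok)) {
    ord <- order(d2[ok])
    used_d <- rep(FALSE, nrow(det)); used_t <- rep(FALSE, nrow(truth))
    for (k in ord) {
      i <- ok[k, 1]; j <- ok[k, 2]
      if (used_d[i] || used_t[j]) next
      used_d[i] <- TRUE; used_t[j] <- TRUE
      err <- c(err, sqrt(d2[i, j]))
    }
  }
  tp <- length(err)
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(truth) - tp, err = err)
}
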