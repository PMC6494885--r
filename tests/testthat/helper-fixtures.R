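# shared fixture builders: everything is generated in code at test time

# small movie config used across rendering tests
tiny_movie_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, image_shape = c(2L, 192L, 192L),
             n_timepoints = 5L, n_cells = 3L, noise_sd_au = 2, ...)
}

# projection with gaussian blobs at given centres (um), for segmentation
blob_projection <- function(centres_um, sigma_um = 3, amplitude = 100,
                            shape = c(128L, 128L), pixel_size = 0.5,
                            timepoint_h = 24) {
  ny <- shape[1]; nx <- shape[2]
  xs <- (seq_len(nx) - 0.5) * pixel_size
  ys <- (seq_len(ny) - 0.5) * pixel_size
  img <- matrix(0, ny, nx)
  for (i in seq_len(nrow(centres_um))) {
    gx <- exp(-(xs - centres_um[i, 1])^2 / (2 * sigma_um^2))
    gy <- exp(-(ys - centres_um[i, 2])^2 / (2 * sigma_um^2))
    img <- img + amplitude * outer(gy, gx)
  }
  projection(img, pixel_size = c(pixel_size, pixel_size),
             timepoint_h = timepoint_h, channel = "morphology")
}

# circular-shift a matrix (wraparound), used to construct known shifts
circshift <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

# random detection frame in a box (um)
random_frame <- function(n, box = 200, timepoint_h = 24) {
  data.frame(timepoint_h = timepoint_h, label = seq_len(n),
             x_um = runif(n, 0, box), y_um = runif(n, 0, box))
}

# independent all-pairs nearest-neighbour oracle for the tracker
nn_oracle <- function(prev, nxt, d_max, init = Inf) {
  out <- data.frame(cell_id = rep(NA_integer_, nrow(nxt)),
                    distance_um = rep(NA_real_, nrow(nxt)))
  for (j in seq_len(nrow(nxt))) {
    best <- NA_integer_; bd <- init
    for (i in seq_len(nrow(prev))) {
      d <- sqrt((nxt$x_um[j] - prev$x_um[i])^2 +
                (nxt$y_um[j] - prev$y_um[i])^2)
      if (d < bd) { bd <- d; best <- prev$cell_id[i] }
    }
    if (!is.na(best) && bd <= d_max) {
      out$cell_id[j] <- best; out$distance_um[j] <- bd
    }
  }
  out
}
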