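GEOM <- screen_geometry()

quick_scanpath <- function(x, y, dur = 200, onset = NULL, ...) {
  n <- length(x)
  if (is.null(onset)) onset <- (seq_len(n) - 1) * 300
  scanpath(data.frame(onset_ms = onset, duration_ms = rep_len(dur, n),
                      x_px = x, y_px = y), ...)
}

# random scanpath with cluster structure so recurrence is neither absent nor
# saturated: positions drawn around a handful of centres with jitter
random_clustered_scanpath <- function(n, n_centers = 4, jitter = 60,
                                      geometry = GEOM) {
  cx <- runif(n_centers, 200, geometry$width_px - 200)
  cy <- runif(n_centers, 200, geometry$height_px - 200)
  pick <- sample.int(n_centers, n, replace = TRUE)
  x <- pmin(pmax(cx[pick] + rnorm(n, 0, jitter), 0), geometry$width_px - 1)
  y <- pmin(pmax(cy[pick] + rnorm(n, 0, jitter), 0), geometry$height_px - 1)
  quick_scanpath(x, y, dur = round(runif(n, 120, 450)), geometry = geometry)
}

random_vectors <- function(k) {
  data.frame(dx = runif(k, -500, 500), dy = runif(k, -300, 300),
             start_x = runif(k, 100, 1400), start_y = runif(k, 100, 700),
             duration_ms = runif(k, 100, 500))
}
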