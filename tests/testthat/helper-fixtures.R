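# Shared fixtures, computed once per test run.

# Repulsion placement is a few seconds of work; cache the default centre set.
.centres_cache <- new.env(parent = emptyenv())
default_centres <- function() {
  if (is.null(.centres_cache$ctr)) {
    .centres_cache$ctr <- place_stimulus_centres(seed = 2)
  }
  .centres_cache$ctr
}

# Noiseless trace drawn exactly from the piecewise-sinusoid model class.
model_trace <- function(c1, c2, c3, offsets, isi_bounds, rate = 60) {
  t <- seq(0, max(isi_bounds) - 1 / rate, by = 1 / rate)
  k <- findInterval(t, isi_bounds[-length(isi_bounds)])
  angle <- -c1 * cos(c2 * t + c3) + offsets[k]
  eye_trace(t, angle)
}

# Minimum pairwise great-circle distance of a centre table, degrees.
min_pairwise <- function(ctr) {
  min(vapply(seq_len(nrow(ctr)), function(i) {
    min(great_circle_angle(ctr$azimuth[i], ctr$elevation[i],
                           ctr$azimuth[-i], ctr$elevation[-i]))
  }, numeric(1)))
}

# Spherical quadrature of a gain surface minus its offset, via
# Gauss-Legendre nodes in sin(elevation) and a uniform azimuth grid.
integrate_vmf_excess <- function(model, n_el = 120, n_az = 240) {
  gl <- okrsphere:::gauss_legendre(n_el, -1, 1)
  az <- seq(-180, 180, length.out = n_az + 1)[-(n_az + 1)]
  total <- 0
  for (i in seq_along(gl$x)) {
    el <- asin(gl$x[i]) * 180 / pi
    vals <- vmf_sum_eval(model, az, rep(el, n_az)) - model$C3
    total <- total + gl$w[i] * mean(vals) * 2 * pi
  }
  total
}
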