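# Shared fixtures: tiny hand-constructed terminals with known geometry.

# axis-aligned square terminal, side `side` nm, corner at origin
square_terminal <- function(side = 1000, scale = 1, vesicles = NULL,
                            psd = list(), glial = list(),
                            condition = "unstimulated", id = "sq1",
                            strict = FALSE) {
  per <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)) / scale
  if (is.null(vesicles)) vesicles <- rbind(c(side / 2, side / 2)) / scale
  suppressWarnings(terminal_annotation(
    terminal_id = id, condition = condition, perimeter = per,
    psd = psd, glial = glial, vesicles = vesicles, scale = scale,
    strict = strict))
}

# a random open polyline with modest turning angles
random_polyline <- function(n_pts = 8, step_mean = 30) {
  ang <- cumsum(c(stats::runif(1, 0, 2 * pi),
                  stats::runif(n_pts - 2, -0.8, 0.8)))
  steps <- stats::runif(n_pts - 1, 0.3, 1.7) * step_mean
  pts <- apply(rbind(c(0, 0), cbind(cos(ang), sin(ang)) * steps), 2, cumsum)
  em_trace(pts, closed = FALSE)
}

# brute-force nearest distance via dense resampling of the trace
dense_oracle_distance <- function(p, trace, res = 0.01) {
  s <- resample_trace(trace, res)
  sqrt(min((s[, 1] - p[1])^2 + (s[, 2] - p[2])^2))
}

# small JSON bundle on disk, returns the path
write_demo_bundle <- function(path = tempfile(fileext = ".json"),
                              scale = 1.0) {
  bundle <- list(list(
    id = "demo1", condition = "low_freq", scale_nm_per_px = scale,
    perimeter = list(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
    psd = list(list(c(20, -10), c(80, -10))),
    glial = list(list(c(110, 20), c(110, 80))),
    vesicles = list(c(30, 30), c(50, 50), c(70, 20))))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  path
}

expect_no_na <- function(x) expect_false(anyNA(x))
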