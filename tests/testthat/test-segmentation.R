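square_with_appositions <- function(side = 1000, gap = 6) {
  # PSD under the bottom edge (cleft 20 nm), glial along the right edge
  psd <- rbind(c(300, -20), c(700, -20))
  glial <- rbind(c(side + gap, 200), c(side + gap, 800))
  square_terminal(side = side, psd = list(psd), glial = list(glial),
                  vesicles = rbind(c(500, 40), c(500, 500)))
}

test_that("no appositions means no compartments", {
  ann <- square_terminal(vesicles = rbind(c(500, 500)))
  seg <- classify_membrane(ann)
  expect_true(all(seg$labels == "other"))
  expect_equal(seg$active_zone_length, 0)
  expect_equal(glial_coverage_fraction(seg), 0)
  expect_equal(nrow(midpoint_gap_distances(ann, seg)), 0L)
  vd <- vesicle_distances(ann, seg)
  expect_true(is.na(vd$d_active_zone[1L]))
  expect_true(is.na(vd$d_glial[1L]))
})

test_that("a fully ensheathed perimeter has coverage 1", {
  side <- 500
  ring <- rbind(c(-5, -5), c(side + 5, -5), c(side + 5, side + 5),
                c(-5, side + 5), c(-5, -5))
  ann <- square_terminal(side = side, glial = list(ring),
                         vesicles = rbind(c(250, 250)))
  seg <- classify_membrane(ann)
  expect_equal(glial_coverage_fraction(seg), 1)
})

test_that("flat appositions label the facing membrane and nothing far away", {
  ann <- square_with_appositions()
  seg <- classify_membrane(ann)
  az <- seg$regions[seg$regions$compartment == "active_zone", ]
  gl <- seg$regions[seg$regions$compartment == "glial_facing", ]
  expect_equal(nrow(az), 1L)
  expect_equal(nrow(gl), 1L)
  # PSD spans x in [300, 700] at 20 nm: facing membrane 400 nm plus
  # at most sqrt(tau^2 - 20^2) ~ 22 nm past each end
  expect_gte(az$arc_length_nm, 400 - 2)
  expect_lte(az$arc_length_nm, 400 + 2 * 23)
  # glial trace spans y in [200, 800] at 6 nm
  expect_gte(gl$arc_length_nm, 600 - 2)
  expect_lte(gl$arc_length_nm, 600 + 2 * 30)

  vd <- vesicle_distances(ann, seg)
  # vesicle at (500, 40): 40 nm above the bottom edge, inside the AZ span
  expect_equal(vd$d_membrane[1L], 40)
  expect_equal(vd$d_active_zone[1L], 40, tolerance = 0.51)
})

test_that("midpoint gaps reproduce parallel, touching and curved geometry", {
  ann <- square_with_appositions(gap = 6)
  seg <- classify_membrane(ann)
  gp <- midpoint_gap_distances(ann, seg)
  expect_equal(nrow(gp), 1L)
  expect_equal(gp$midpoint_gap_nm, 6, tolerance = 0.02)

  # glial trace lying on the membrane: gap 0
  touch <- square_terminal(glial = list(rbind(c(1000, 400), c(1000, 600))),
                           vesicles = rbind(c(500, 500)))
  segt <- classify_membrane(touch)
  expect_equal(midpoint_gap_distances(touch, segt)$midpoint_gap_nm, 0,
               tolerance = 1e-9)

  # curved apposition on a synthetic terminal vs dense-resampling oracle
  set.seed(11)
  g <- generate_terminal(synthetic_config(vesicle_count_mean = 10,
                                          vesicle_count_fixed = TRUE), "t")
  segc <- classify_membrane(g$annotation)
  gpc <- midpoint_gap_distances(g$annotation, segc)
  k <- nrow(segc$samples)
  reg <- segc$regions[segc$regions$compartment == "glial_facing", ]
  for (i in seq_len(nrow(reg))) {
    mid_idx <- ((reg$start[i] - 1L + ceiling(reg$len[i] / 2) - 1L) %% k) + 1L
    p <- segc$samples[mid_idx, ]
    oracle <- min(vapply(g$annotation$glial,
                         function(tr) dense_oracle_distance(p, tr), 0))
    expect_equal(gpc$midpoint_gap_nm[i], oracle, tolerance = 0.1)
  }
})

test_that("generator ground truth is recovered by the classifier", {
  set.seed(23)
  cfg <- synthetic_config(vesicle_count_mean = 20, vesicle_count_fixed = TRUE)
  n3 <- 0L
  for (i in 1:6) {
    g <- generate_terminal(cfg, paste0("t", i))
    seg <- classify_membrane(g$annotation)
    # AZ extent within 2*step + 2*tau_az of the configured arc
    expect_lt(abs(seg$active_zone_length - g$truth$az_arc_length),
              2 * 1 + 2 * 30)
    # one glial region per configured arc
    expect_equal(sum(seg$regions$compartment == "glial_facing"),
                 nrow(g$truth$glial_arcs))
    n3 <- n3 + (nrow(g$truth$glial_arcs) == 3L)
    # coverage within 0.05 of the configured total arc fraction
    expect_lt(abs(glial_coverage_fraction(seg) -
                    g$truth$glial_arc_length_total / g$truth$perimeter_length),
              0.05)
  }
  expect_gte(n3, 1L)  # both 2- and 3-region terminals occur
})

test_that("vesicle compartment distances equal the brute-force sample minimum", {
  set.seed(41)
  g <- generate_terminal(synthetic_config(vesicle_count_mean = 30,
                                          vesicle_count_fixed = TRUE), "t")
  seg <- classify_membrane(g$annotation)
  vd <- vesicle_distances(g$annotation, seg)
  v <- g$annotation$vesicles
  az <- seg$samples[seg$labels == "active_zone", , drop = FALSE]
  gl <- seg$samples[seg$labels == "glial_facing", , drop = FALSE]
  for (i in sample(nrow(v), 10L)) {
    expect_equal(vd$d_active_zone[i],
                 sqrt(min((az[, 1] - v[i, 1])^2 + (az[, 2] - v[i, 2])^2)))
    expect_equal(vd$d_glial[i],
                 sqrt(min((gl[, 1] - v[i, 1])^2 + (gl[, 2] - v[i, 2])^2)))
  }
  # compartments are perimeter subsets: compartment distance >= membrane
  expect_true(all(vd$d_active_zone >= vd$d_membrane - 1e-9, na.rm = TRUE))
  expect_true(all(vd$d_glial >= vd$d_membrane - 1e-9, na.rm = TRUE))
})

test_that("compartment lengths partition the perimeter", {
  set.seed(53)
  g <- generate_terminal(synthetic_config(vesicle_count_mean = 10,
                                          vesicle_count_fixed = TRUE), "t")
  for (step in c(2, 1, 0.5)) {
    seg <- classify_membrane(g$annotation, step = step)
    total <- seg$active_zone_length + seg$glial_facing_length +
      seg$other_length
    expect_equal(total, nrow(seg$samples) * step)
    expect_lt(abs(total - seg$perimeter_length), step)
    expect_lte(seg$active_zone_length + seg$glial_facing_length,
               seg$perimeter_length)
  }
})

test_that("halving the resample step barely moves pooled distances", {
  set.seed(67)
  g <- generate_terminal(synthetic_config(vesicle_count_mean = 150,
                                          vesicle_count_fixed = TRUE), "t")
  d2 <- vesicle_distances(g$annotation,
                          classify_membrane(g$annotation, step = 2))
  d05 <- vesicle_distances(g$annotation,
                           classify_membrane(g$annotation, step = 0.5))
  expect_lt(abs(mean(d2$d_active_zone) - mean(d05$d_active_zone)), 1)
  expect_lt(abs(mean(d2$d_glial) - mean(d05$d_glial)), 1)
})

test_that("explicit arc extents bypass the threshold classifier", {
  ann <- square_terminal(vesicles = rbind(c(500, 500)))
  seg <- classify_membrane(ann, az_arcs_nm = list(c(100, 300)),
                           glial_arcs_nm = list(c(3900, 4100)))  # wraps
  expect_equal(seg$active_zone_length, 201, tolerance = 2)
  expect_equal(seg$glial_facing_length, 201, tolerance = 2)
  expect_equal(sum(seg$regions$compartment == "glial_facing"), 1L)
})
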