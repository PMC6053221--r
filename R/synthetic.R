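#' Configuration for the synthetic terminal generator
#'
#' Describes one stimulation condition's worth of synthetic terminals.
#' Geometry defaults emulate parallel-fibre boutons as seen in single 70 nm
#' EM sections: a smooth Fourier-perturbed ellipse of mean radius 450 nm,
#' one active-zone arc (12% of the perimeter) apposed to a PSD trace across
#' a 20 nm cleft, and 2-3 glial-facing arcs (13% of the perimeter each)
#' apposed to glial traces across a ~6 nm gap. Glial traces flare away from
#' the membrane over the last ~20 nm of each apposition, as withdrawing
#' processes do. Vesicle centres are placed by sampling a target
#' active-zone distance from a mixture of Gaussian pools (defaults at 32 nm
#' and 97 nm) plus a uniform background inside the terminal.
#'
#' @param n_terminals number of terminals.
#' @param condition condition label.
#' @param scale_nm_per_px pixel calibration used when emitting coordinates.
#' @param radius_nm mean perimeter radius.
#' @param radial_noise amplitude of the low-order radial perturbation
#'   (fraction of the radius).
#' @param n_vertices perimeter vertex count.
#' @param az_arc_fraction active-zone arc as a fraction of the perimeter.
#' @param cleft_nm PSD offset from the membrane.
#' @param glial_region_weights probability weights for 2 vs 3 glial regions.
#' @param glial_arc_fraction per-region glial arc fraction of the perimeter.
#' @param gap_mean_nm,gap_sd_nm terminal-to-glia gap distribution (nm).
#' @param vesicle_count_mean Poisson mean of vesicles per terminal; a fixed
#'   count when `vesicle_count_fixed = TRUE`.
#' @param vesicle_count_fixed use `vesicle_count_mean` as an exact count.
#' @param az_pools data frame with columns `weight`, `mean_nm`, `sd_nm`:
#'   the Gaussian pools of vesicle distance-to-active-zone.
#' @param background_weight weight of the uniform background component;
#'   pool weights plus background must sum to 1.
#' @param vesicle_diameter_nm nominal vesicle diameter.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_terminals = 10,
                             condition = "unstimulated",
                             scale_nm_per_px = 0.5,
                             radius_nm = 450,
                             radial_noise = 0.08,
                             n_vertices = 200,
                             az_arc_fraction = 0.12,
                             cleft_nm = 20,
                             glial_region_weights = c(`2` = 0.5, `3` = 0.5),
                             glial_arc_fraction = 0.13,
                             gap_mean_nm = 6,
                             gap_sd_nm = 1,
                             vesicle_count_mean = 57,
                             vesicle_count_fixed = FALSE,
                             az_pools = data.frame(
                               weight = c(0.30, 0.60),
                               mean_nm = c(32, 97),
                               sd_nm = c(12, 30)),
                             background_weight = 0.10,
                             vesicle_diameter_nm = 52.5) {
  cfg <- as.list(environment())
  wsum <- sum(az_pools$weight) + background_weight
  if (abs(wsum - 1) > 1e-9)
    stop("pool weights plus background_weight must sum to 1 (got ", wsum, ")")
  stopifnot(radius_nm > 0, n_vertices >= 16, az_arc_fraction > 0,
            az_arc_fraction + 3.5 * glial_arc_fraction < 0.95,
            gap_mean_nm > 0, gap_sd_nm >= 0, cleft_nm > 0,
            all(az_pools$sd_nm > 0), scale_nm_per_px > 0)
  class(cfg) <- "synthetic_config"
  cfg
}

# position and outward normal at arc position s of a closed CCW polyline
arc_frame <- function(pts, s) {
  n <- nrow(pts)
  p1 <- pts[c(2:n, 1L), , drop = FALSE]
  seglen <- sqrt(rowSums((p1 - pts)^2))
  L <- sum(seglen)
  cum <- c(0, cumsum(seglen))
  s <- s %% L
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > n] <- n
  frac <- (s - cum[idx]) / seglen[idx]
  dir <- (p1[idx, , drop = FALSE] - pts[idx, , drop = FALSE]) / seglen[idx]
  pos <- pts[idx, , drop = FALSE] + dir * frac
  normal <- cbind(dir[, 2L], -dir[, 1L])  # outward for CCW orientation
  list(pos = pos, normal = normal, L = L)
}

# open trace parallel to the perimeter over arc interval [s0, s1],
# offset outward by gap(s) (a function of distance to the nearer arc end)
offset_arc_trace <- function(pts, s0, s1, gap_fun, spacing = 5) {
  s <- seq(s0, s1, length.out = max(5L, ceiling((s1 - s0) / spacing) + 1L))
  fr <- arc_frame(pts, s)
  t_end <- pmin(s - s0, s1 - s)
  g <- gap_fun(t_end)
  em_trace(fr$pos + fr$normal * g, closed = FALSE)
}

#' Generate one synthetic terminal with ground truth
#'
#' Draws from the current RNG state (seed at the caller, or use
#' [generate_dataset()] which manages per-terminal seeds).
#'
#' @param config a [synthetic_config()].
#' @param terminal_id identifier for the emitted annotation.
#' @return list with `annotation` (a [terminal_annotation()], coordinates
#'   emitted in pixels at the configured scale) and `truth` (active-zone
#'   arc interval, glial arc intervals with their gap distances, and the
#'   per-vesicle pool membership with target and placed distances).
#' @export
generate_terminal <- function(config, terminal_id = "synth_1") {
  for (attempt in 1:5) {
    res <- try(generate_terminal_once(config, terminal_id), silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
  }
  stop("terminal generation failed after 5 attempts: ",
       attr(res, "condition")$message)
}

generate_terminal_once <- function(config, terminal_id) {
  # Fourier-perturbed ellipse, CCW
  th <- seq(0, 2 * pi, length.out = config$n_vertices + 1L)[-(config$n_vertices + 1L)]
  amp <- config$radial_noise * c(1, 0.6, 0.35) * stats::runif(3, 0.3, 1)
  ph <- stats::runif(3, 0, 2 * pi)
  r <- config$radius_nm *
    (1 + amp[1] * cos(2 * th + ph[1]) + amp[2] * cos(3 * th + ph[2]) +
       amp[3] * cos(4 * th + ph[3]))
  pts <- cbind(r * cos(th), r * sin(th))
  perim <- em_trace(pts, closed = TRUE)
  L <- trace_length(perim)

  # arc layout: the AZ arc with glial arcs flanking it on both sides
  # (perisynaptic processes ensheathe the synapse), a possible third
  # region further along, and a bare back side
  az_len <- config$az_arc_fraction * L
  s_az <- stats::runif(1, 0, L)
  n_g <- as.integer(sample(names(config$glial_region_weights), 1L,
                           prob = config$glial_region_weights))
  g_len <- config$glial_arc_fraction * L
  # bare membrane: narrow strips between AZ and flanking glia (processes
  # approach the cleft), a wider one between consecutive glial regions
  spacer <- c(stats::runif(2, 25, 70), stats::runif(1, 60, 150))[seq_len(n_g)]
  if (az_len + n_g * g_len + sum(spacer) + 100 >= L)
    stop("arc fractions too large for this perimeter")
  glial_arcs <- data.frame(start = numeric(n_g), end = numeric(n_g),
                           gap_nm = numeric(n_g))
  # one region after the AZ, one before it, a third after the first
  glial_arcs$start[1L] <- s_az + az_len + spacer[1L]
  glial_arcs$end[1L] <- glial_arcs$start[1L] + g_len
  if (n_g >= 2L) {
    glial_arcs$start[2L] <- s_az - spacer[2L] - g_len
    glial_arcs$end[2L] <- glial_arcs$start[2L] + g_len
  }
  if (n_g >= 3L) {
    glial_arcs$start[3L] <- glial_arcs$end[1L] + spacer[3L]
    glial_arcs$end[3L] <- glial_arcs$start[3L] + g_len
    if (glial_arcs$end[3L] > glial_arcs$start[2L] + L - 50)
      stop("glial arcs overlap on this perimeter")
  }
  glial_arcs$gap_nm <- pmax(1.5, stats::rnorm(n_g, config$gap_mean_nm,
                                              config$gap_sd_nm))

  # PSD parallel to the AZ arc across the cleft
  psd <- offset_arc_trace(pts, s_az, s_az + az_len,
                          function(t) rep(config$cleft_nm, length(t)))
  # glial processes: constant gap, flaring off over the last ~20 nm
  glial <- lapply(seq_len(n_g), function(i) {
    g0 <- glial_arcs$gap_nm[i]
    ramp <- min(20, 0.25 * g_len)
    offset_arc_trace(pts, glial_arcs$start[i], glial_arcs$end[i],
                     function(t) {
                       f <- pmax(0, 1 - t / ramp)
                       g0 + (45 - g0) * f
                     })
  })

  # reference AZ point set for placement distances (1 nm spacing)
  s_ref <- seq(s_az, s_az + az_len, by = 1)
  az_ref <- arc_frame(pts, s_ref)$pos

  n_v <- if (config$vesicle_count_fixed) config$vesicle_count_mean
         else stats::rpois(1, config$vesicle_count_mean)
  pools <- config$az_pools
  comp_prob <- c(pools$weight, config$background_weight)
  bbox <- apply(pts, 2L, range)
  ves <- matrix(NA_real_, nrow = n_v, ncol = 2L)
  truth_v <- data.frame(pool = integer(n_v),
                        target_nm = rep(NA_real_, n_v),
                        placed_nm = rep(NA_real_, n_v))
  place_background <- function() {
    repeat {
      cand <- c(stats::runif(1, bbox[1, 1], bbox[2, 1]),
                stats::runif(1, bbox[1, 2], bbox[2, 2]))
      if (points_in_polygon(cand, perim)) return(cand)
    }
  }
  az_dist <- function(p)
    sqrt(min((az_ref[, 1] - p[1])^2 + (az_ref[, 2] - p[2])^2))
  for (v in seq_len(n_v)) {
    comp <- sample.int(length(comp_prob), 1L, prob = comp_prob)
    if (comp > nrow(pools)) {        # uniform background
      p <- place_background()
      truth_v$pool[v] <- 0L
      truth_v$placed_nm[v] <- az_dist(p)
      ves[v, ] <- p
      next
    }
    placed <- FALSE
    for (try_t in 1:6) {
      t_target <- max(2, stats::rnorm(1, pools$mean_nm[comp], pools$sd_nm[comp]))
      for (try_s in 1:40) {
        s_star <- stats::runif(1, s_az, s_az + az_len)
        fr <- arc_frame(pts, s_star)
        cand <- as.numeric(fr$pos - fr$normal * t_target)
        if (!points_in_polygon(cand, perim)) next
        d <- az_dist(cand)
        if (abs(d - t_target) <= 2.5) {
          ves[v, ] <- cand
          truth_v$pool[v] <- comp
          truth_v$target_nm[v] <- t_target
          truth_v$placed_nm[v] <- d
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) stop("vesicle placement rejection budget exhausted")
  }

  sc <- config$scale_nm_per_px
  ann <- suppressWarnings(terminal_annotation(
    terminal_id = terminal_id, condition = config$condition,
    perimeter = pts / sc,
    psd = list(psd$points / sc),
    glial = lapply(glial, function(tr) tr$points / sc),
    vesicles = ves / sc,
    scale = sc,
    vesicle_diameter_nm = config$vesicle_diameter_nm))
  truth <- list(az_arc = c(s_az, s_az + az_len) %% L,
                az_arc_length = az_len,
                perimeter_length = L,
                glial_arcs = glial_arcs,
                glial_arc_length_total = n_g * g_len,
                vesicles = truth_v)
  list(annotation = ann, truth = truth)
}

#' Per-condition generator presets
#'
#' Default conditions for a three-arm synthetic dataset mirroring an
#' unstimulated / 0.033 Hz / 1 Hz design: per-condition terminal counts
#' (167/295/287), mean vesicle counts (57/59/56), apposition-gap means
#' (5.82/6.01/6.26 nm) and pool locations (32+97, 36+87, 31+81+117 nm).
#' These presets are synthetic study conditions, not measurements.
#'
#' @return named list of [synthetic_config()] objects.
#' @export
condition_presets <- function() {
  list(
    unstimulated = synthetic_config(
      n_terminals = 167, condition = "unstimulated",
      vesicle_count_mean = 57, gap_mean_nm = 5.82,
      az_pools = data.frame(weight = c(0.30, 0.60),
                            mean_nm = c(32, 97), sd_nm = c(12, 30)),
      background_weight = 0.10),
    low_freq = synthetic_config(
      n_terminals = 295, condition = "low_freq",
      vesicle_count_mean = 59, gap_mean_nm = 6.01,
      az_pools = data.frame(weight = c(0.28, 0.62),
                            mean_nm = c(36, 87), sd_nm = c(12, 30)),
      background_weight = 0.10),
    high_freq = synthetic_config(
      n_terminals = 287, condition = "high_freq",
      vesicle_count_mean = 56, gap_mean_nm = 6.26,
      az_pools = data.frame(weight = c(0.27, 0.45, 0.18),
                            mean_nm = c(31, 81, 117), sd_nm = c(12, 25, 20)),
      background_weight = 0.10))
}

#' Generate a multi-condition synthetic dataset
#'
#' One seeded generator per dataset spawns an independent seed per terminal
#' (recorded in the ground truth), so output is reproducible and
#' per-terminal regeneration is possible.
#'
#' @param configs named list of [synthetic_config()] (default:
#'   [condition_presets()]).
#' @param seed integer dataset seed.
#' @param out_dir if non-`NULL`, write one JSON annotation bundle per
#'   condition plus a `ground_truth.json` sidecar there.
#' @return list with `annotations` (named by condition) and `truth`.
#' @export
generate_dataset <- function(configs = condition_presets(), seed = 1,
                             out_dir = NULL) {
  set.seed(seed)
  out <- list(annotations = list(), truth = list())
  for (cond in names(configs)) {
    cfg <- configs[[cond]]
    term_seeds <- sample.int(.Machine$integer.max, cfg$n_terminals)
    anns <- vector("list", cfg$n_terminals)
    truths <- vector("list", cfg$n_terminals)
    for (i in seq_len(cfg$n_terminals)) {
      set.seed(term_seeds[i])
      g <- generate_terminal(cfg, sprintf("%s_%03d", cond, i))
      g$truth$seed <- term_seeds[i]
      anns[[i]] <- g$annotation
      truths[[i]] <- g$truth
    }
    out$annotations[[cond]] <- anns
    out$truth[[cond]] <- truths
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cond in names(out$annotations)) {
      write_annotation_bundle(out$annotations[[cond]],
                              file.path(out_dir, paste0(cond, ".json")))
    }
    truth_json <- lapply(out$truth, function(tt) lapply(tt, function(t) {
      t$glial_arcs <- as.list(t$glial_arcs)
      t$vesicles <- as.list(t$vesicles)
      t
    }))
    jsonlite::write_json(truth_json, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
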