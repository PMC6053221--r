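#' Membrane compartment classification
#'
#' Resamples the terminal perimeter at a fixed arc-length step and labels
#' each sample `active_zone` if it lies within `tau_az` of any postsynaptic
#' density trace, else `glial_facing` if within `tau_glial` of any glial
#' trace, else `other`. The active zone wins where both thresholds are met
#' (the PSD defines the synapse; glial processes do not overlie the cleft).
#' Label runs shorter than `min_run` are merged into the flanking label,
#' and maximal contiguous runs are collected into numbered regions per
#' compartment. Compartment lengths are `count of member samples x step`.
#'
#' Alternatively, explicit arc-length extents (nm intervals along the
#' perimeter, measured from the first perimeter vertex) may be supplied via
#' `az_arcs_nm` / `glial_arcs_nm`; these bypass the distance thresholds and
#' reproduce a manual demarcation.
#'
#' @param annotation a [terminal_annotation()].
#' @param tau_az nm threshold for active-zone apposition (default 30, the
#'   synaptic-cleft scale).
#' @param tau_glial nm threshold for glial apposition (default 30).
#' @param step resampling step in nm (default 1).
#' @param min_run minimum run extent in nm (default 10); shorter runs are
#'   absorbed by their flanks.
#' @param az_arcs_nm,glial_arcs_nm optional lists of `c(start, end)` arc
#'   intervals in nm (end may exceed the perimeter length to wrap).
#' @return object of class `membrane_segmentation`: samples, their arc
#'   positions and labels, a `regions` data frame (compartment, region,
#'   start index, n samples, arc length), and the compartment lengths.
#' @export
classify_membrane <- function(annotation, tau_az = 30, tau_glial = 30,
                              step = 1, min_run = 10,
                              az_arcs_nm = NULL, glial_arcs_nm = NULL) {
  samples <- resample_trace(annotation$perimeter, step)
  arc <- attr(samples, "arc")
  L <- attr(samples, "total_length")
  k <- nrow(samples)

  labels <- rep("other", k)
  if (!is.null(az_arcs_nm) || !is.null(glial_arcs_nm)) {
    in_arcs <- function(arcs) {
      hit <- rep(FALSE, k)
      for (a in arcs) {
        s0 <- a[1L] %% L; s1 <- s0 + (a[2L] - a[1L])
        hit <- hit | (arc >= s0 & arc <= s1) |
          (s1 > L & arc <= (s1 - L))
      }
      hit
    }
    if (!is.null(glial_arcs_nm)) labels[in_arcs(glial_arcs_nm)] <- "glial_facing"
    if (!is.null(az_arcs_nm)) labels[in_arcs(az_arcs_nm)] <- "active_zone"
  } else {
    min_dist_to <- function(traces) {
      if (length(traces) == 0L) return(rep(Inf, k))
      do.call(pmin, lapply(traces, function(tr) dist_to_trace(samples, tr)))
    }
    d_psd <- min_dist_to(annotation$psd)
    d_gli <- min_dist_to(annotation$glial)
    labels[d_gli <= tau_glial] <- "glial_facing"
    labels[d_psd <= tau_az] <- "active_zone"
  }

  runs <- circular_runs(labels)
  runs <- merge_short_runs(runs, k, step, min_run)
  labels <- labels_from_runs(runs, k)

  lengths_nm <- vapply(c("active_zone", "glial_facing", "other"),
                       function(lb) sum(runs$len[runs$label == lb]) * step,
                       0)
  regions <- runs[runs$label != "other", , drop = FALSE]
  if (nrow(regions)) {
    regions <- regions[order(regions$label, regions$start), , drop = FALSE]
    regions$region <- stats::ave(seq_len(nrow(regions)), regions$label,
                                 FUN = seq_along)
  } else {
    regions$region <- integer(0)
  }
  regions$arc_length_nm <- regions$len * step
  rownames(regions) <- NULL
  names(regions)[names(regions) == "label"] <- "compartment"

  structure(list(samples = samples, arc = arc, labels = labels,
                 regions = regions, step = step,
                 perimeter_length = L,
                 active_zone_length = lengths_nm[["active_zone"]],
                 glial_facing_length = lengths_nm[["glial_facing"]],
                 other_length = lengths_nm[["other"]]),
            class = "membrane_segmentation")
}

#' @export
print.membrane_segmentation <- function(x, ...) {
  cat(sprintf(
    "<membrane_segmentation: perimeter %.0f nm; AZ %.0f nm (%d region), glial %.0f nm (%d regions)>\n",
    x$perimeter_length, x$active_zone_length,
    sum(x$regions$compartment == "active_zone"),
    x$glial_facing_length,
    sum(x$regions$compartment == "glial_facing")))
  invisible(x)
}

# maximal runs of equal labels on a circular index 1..k
circular_runs <- function(labels) {
  r <- rle(labels)
  runs <- data.frame(label = r$values, len = r$lengths,
                     stringsAsFactors = FALSE)
  runs$start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  if (nrow(runs) > 1L && runs$label[1L] == runs$label[nrow(runs)]) {
    runs$start[1L] <- runs$start[nrow(runs)]
    runs$len[1L] <- runs$len[1L] + runs$len[nrow(runs)]
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  runs[, c("label", "start", "len")]
}

labels_from_runs <- function(runs, k) {
  labels <- character(k)
  for (i in seq_len(nrow(runs))) {
    idx <- ((runs$start[i] - 1L + seq_len(runs$len[i]) - 1L) %% k) + 1L
    labels[idx] <- runs$label[i]
  }
  labels
}

# absorb runs shorter than min_run into the longer flank, repeatedly
merge_short_runs <- function(runs, k, step, min_run) {
  repeat {
    if (nrow(runs) <= 1L) return(runs)
    short <- which(runs$len * step < min_run)
    if (length(short) == 0L) return(runs)
    i <- short[which.min(runs$len[short])]
    n <- nrow(runs)
    prev <- if (i == 1L) n else i - 1L
    nxt <- if (i == n) 1L else i + 1L
    donor <- if (runs$len[prev] >= runs$len[nxt]) prev else nxt
    runs$label[i] <- runs$label[donor]
    # re-coalesce adjacent equal labels
    labels <- labels_from_runs(runs, k)
    runs <- circular_runs(labels)
  }
}

#' Vesicle-to-compartment distances
#'
#' For every vesicle centre: the exact shortest Euclidean distance to the
#' perimeter trace (`d_membrane`), and the shortest distance to the
#' resampled sample points of the active-zone and glial-facing compartments
#' (`d_active_zone`, `d_glial`; `NA` when the compartment is empty).
#' Compartment distances use the discrete samples — nearest-sample
#' semantics with error bounded by step/2 — while the perimeter distance is
#' exact segment geometry.
#'
#' @param annotation a [terminal_annotation()].
#' @param seg the [classify_membrane()] output for the same annotation.
#' @return data frame: `terminal_id`, `vesicle`, `d_membrane`,
#'   `d_active_zone`, `d_glial` (nm).
#' @export
vesicle_distances <- function(annotation, seg) {
  v <- annotation$vesicles
  nv <- nrow(v)
  if (nv == 0L)
    return(data.frame(terminal_id = character(0), vesicle = integer(0),
                      d_membrane = numeric(0), d_active_zone = numeric(0),
                      d_glial = numeric(0)))
  d_mem <- dist_to_trace(v, annotation$perimeter)
  nearest <- function(label) {
    s <- seg$samples[seg$labels == label, , drop = FALSE]
    if (nrow(s) == 0L) return(rep(NA_real_, nv))
    d2 <- outer(v[, 1L], s[, 1L], "-")^2 + outer(v[, 2L], s[, 2L], "-")^2
    sqrt(apply(d2, 1L, min))
  }
  data.frame(terminal_id = annotation$terminal_id,
             vesicle = seq_len(nv),
             d_membrane = d_mem,
             d_active_zone = nearest("active_zone"),
             d_glial = nearest("glial_facing"))
}

#' Fraction of the perimeter covered by glial-facing membrane
#'
#' @param seg a [classify_membrane()] output.
#' @return `glial_facing_length / perimeter_length`, in `[0, 1]`.
#' @export
glial_coverage_fraction <- function(seg) {
  if (seg$perimeter_length <= 0) stop("zero perimeter length")
  min(1, seg$glial_facing_length / seg$perimeter_length)
}

#' Terminal-to-glia gap at each apposition midpoint
#'
#' For every glial-facing region, takes the sample at the arc-length
#' midpoint of the run and measures its exact distance to the nearest glial
#' trace.
#'
#' @param annotation a [terminal_annotation()].
#' @param seg the matching [classify_membrane()] output.
#' @return data frame: `terminal_id`, `region`, `arc_length_nm`,
#'   `midpoint_gap_nm`. Zero rows when there is no glial-facing membrane.
#' @export
midpoint_gap_distances <- function(annotation, seg) {
  reg <- seg$regions[seg$regions$compartment == "glial_facing", , drop = FALSE]
  k <- nrow(seg$samples)
  out <- data.frame(terminal_id = rep(annotation$terminal_id, nrow(reg)),
                    region = reg$region,
                    arc_length_nm = reg$arc_length_nm,
                    midpoint_gap_nm = rep(NA_real_, nrow(reg)))
  if (nrow(reg) == 0L || length(annotation$glial) == 0L)
    return(out[FALSE, , drop = FALSE])
  for (i in seq_len(nrow(reg))) {
    mid_off <- ceiling(reg$len[i] / 2) - 1L
    mid_idx <- ((reg$start[i] - 1L + mid_off) %% k) + 1L
    p <- seg$samples[mid_idx, ]
    out$midpoint_gap_nm[i] <- min(vapply(
      annotation$glial, function(tr) point_to_trace_distance(p, tr), 0))
  }
  out
}
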