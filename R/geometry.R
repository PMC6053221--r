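#' Polyline traces
#'
#' A trace is an ordered sequence of 2-D points (nm), open (postsynaptic
#' density, glial process) or closed (terminal perimeter; the implicit
#' segment from the last point back to the first is part of the trace).
#' Consecutive duplicate points are dropped at construction so that no
#' zero-length segment survives.
#'
#' @param points numeric matrix with two columns (x, y) in nm, or an object
#'   coercible to one.
#' @param closed logical; is the trace a closed curve?
#' @return An object of class `em_trace`: a list with elements `points`
#'   (n x 2 matrix) and `closed`.
#' @export
em_trace <- function(points, closed = FALSE) {
  pts <- as.matrix(points)
  if (is.null(dim(pts)) || ncol(pts) != 2L)
    stop("trace points must be an n x 2 matrix")
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts))) stop("trace contains non-finite coordinates")
  # drop consecutive duplicates (and the closing duplicate of a closed trace)
  if (nrow(pts) > 1L) {
    keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
    pts <- pts[keep, , drop = FALSE]
  }
  if (closed && nrow(pts) > 1L &&
      all(pts[nrow(pts), ] == pts[1L, ])) {
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  if (nrow(pts) < 2L) stop("trace must contain at least 2 distinct points")
  structure(list(points = pts, closed = isTRUE(closed)), class = "em_trace")
}

#' @export
print.em_trace <- function(x, ...) {
  cat(sprintf("<em_trace: %d points, %s, length %.1f nm>\n",
              nrow(x$points), if (x$closed) "closed" else "open",
              trace_length(x)))
  invisible(x)
}

# segment endpoints of a trace (closed traces wrap)
trace_segments <- function(trace) {
  pts <- trace$points
  n <- nrow(pts)
  if (trace$closed) {
    list(p0 = pts, p1 = pts[c(2:n, 1L), , drop = FALSE])
  } else {
    list(p0 = pts[-n, , drop = FALSE], p1 = pts[-1L, , drop = FALSE])
  }
}

#' Arc length of a trace
#'
#' @param trace an [em_trace()].
#' @return total length in nm (closed traces include the closing segment).
#' @export
trace_length <- function(trace) {
  seg <- trace_segments(trace)
  sum(sqrt(rowSums((seg$p1 - seg$p0)^2)))
}

#' Shortest Euclidean distance from points to a trace
#'
#' Exact minimum distance from each query point to the union of the trace's
#' segments (the whole polyline, not just its vertices).
#'
#' @param p numeric matrix of query points (n x 2, nm), or a length-2 vector.
#' @param trace an [em_trace()].
#' @return numeric vector of distances, one per query point.
#' @export
dist_to_trace <- function(p, trace) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  p <- as.matrix(p)
  seg <- trace_segments(trace)
  n <- nrow(p)
  best <- rep(Inf, n)
  for (i in seq_len(nrow(seg$p0))) {
    a <- seg$p0[i, ]; b <- seg$p1[i, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next  # defensive: duplicates removed at construction
    t <- ((p[, 1L] - a[1L]) * ab[1L] + (p[, 2L] - a[2L]) * ab[2L]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- a[1L] + t * ab[1L] - p[, 1L]
    dy <- a[2L] + t * ab[2L] - p[, 2L]
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

#' Shortest distance from one point to a trace
#'
#' Scalar convenience wrapper around [dist_to_trace()].
#'
#' @param p length-2 numeric (x, y) in nm.
#' @param trace an [em_trace()].
#' @return distance in nm.
#' @export
point_to_trace_distance <- function(p, trace) {
  dist_to_trace(matrix(p, ncol = 2L), trace)[1L]
}

#' Resample a trace at fixed arc-length step
#'
#' Places points along the trace at arc-length positions 0, step, 2*step, ...
#' For open traces the final vertex is appended if it does not coincide with
#' the last sample; for closed traces samples wrap around the curve and the
#' start point is not repeated. Consecutive samples are at most `step` apart
#' and every original vertex lies within `step`/2 (in arc length) of a sample.
#'
#' @param trace an [em_trace()].
#' @param step arc-length spacing in nm (> 0).
#' @return matrix of sample points (k x 2). Attribute `arc` carries the
#'   arc-length position of each sample along the trace.
#' @export
resample_trace <- function(trace, step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a single positive number")
  seg <- trace_segments(trace)
  seglen <- sqrt(rowSums((seg$p1 - seg$p0)^2))
  L <- sum(seglen)
  if (L == 0) stop("degenerate trace: zero total length")
  s <- seq(0, L, by = step)
  if (trace$closed) {
    # drop a final sample that would coincide with the start
    if (length(s) > 1L && (L - s[length(s)]) < 1e-9) s <- s[-length(s)]
  } else {
    if ((L - s[length(s)]) > 1e-9) s <- c(s, L)
  }
  cum <- c(0, cumsum(seglen))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > length(seglen)] <- length(seglen)
  frac <- (s - cum[idx]) / seglen[idx]
  out <- seg$p0[idx, , drop = FALSE] +
    (seg$p1[idx, , drop = FALSE] - seg$p0[idx, , drop = FALSE]) * frac
  attr(out, "arc") <- s
  attr(out, "total_length") <- L
  out
}

#' Signed area of a closed trace (shoelace)
#'
#' Positive for counter-clockwise orientation in a y-up frame.
#'
#' @param trace a closed [em_trace()].
#' @return signed area in nm^2.
#' @export
polygon_signed_area <- function(trace) {
  if (!trace$closed) stop("area is defined for closed traces only")
  p <- trace$points
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) / 2
}

#' Test whether points lie inside a closed trace
#'
#' Even-odd ray casting. Points exactly on the boundary may fall on either
#' side; callers that care use [dist_to_trace()] with a tolerance.
#'
#' @param p matrix of query points (n x 2) or a length-2 vector.
#' @param trace a closed [em_trace()].
#' @return logical vector.
#' @export
points_in_polygon <- function(p, trace) {
  if (!trace$closed) stop("point-in-polygon requires a closed trace")
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  p <- as.matrix(p)
  poly <- trace$points
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(p))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > p[, 2L]) != (yj > p[, 2L])) &
      (p[, 1L] < (xj - xi) * (p[, 2L] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
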