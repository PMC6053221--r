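#' Terminal annotation
#'
#' The canonical unit of analysis: one presynaptic terminal traced on a
#' transmission-EM image. Holds the closed perimeter trace, any postsynaptic
#' density (PSD) and glial-process traces, the marked vesicle centre points,
#' the pixel calibration and the stimulation condition. All coordinates are
#' stored in nm; conversion from pixel coordinates happens once, here.
#'
#' Vesicle centres further than one vesicle radius (default 26.25 nm, half
#' the 52.5 nm population diameter) outside the perimeter polygon trigger a
#' warning; with `strict = TRUE` they are dropped instead of retained.
#'
#' @param terminal_id character identifier.
#' @param condition one of `"unstimulated"`, `"low_freq"`, `"high_freq"`
#'   (unstimulated / 0.033 Hz / 1 Hz stimulation).
#' @param perimeter closed [em_trace()] or point matrix, in px.
#' @param psd list of open traces/matrices (0 or more), in px.
#' @param glial list of open traces/matrices (0 or more), in px.
#' @param vesicles matrix of vesicle centre points (m x 2), in px.
#' @param scale nm per pixel (> 0); all coordinates are multiplied by it.
#' @param vesicle_diameter_nm nominal vesicle diameter used for the
#'   outside-perimeter tolerance.
#' @param strict drop out-of-perimeter vesicles instead of keeping them.
#' @return object of class `terminal_annotation`.
#' @export
terminal_annotation <- function(terminal_id, condition, perimeter,
                                psd = list(), glial = list(),
                                vesicles = matrix(numeric(0), ncol = 2L),
                                scale = 1,
                                vesicle_diameter_nm = 52.5,
                                strict = FALSE) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale (nm per pixel) must be a single positive number")
  condition <- match.arg(condition,
                         c("unstimulated", "low_freq", "high_freq"))
  as_nm <- function(x, closed) {
    tr <- if (inherits(x, "em_trace")) x else em_trace(x, closed = closed)
    em_trace(tr$points * scale, closed = closed)
  }
  perimeter <- as_nm(perimeter, closed = TRUE)
  if (abs(polygon_signed_area(perimeter)) <= 0)
    stop("perimeter trace must enclose positive area")
  psd <- lapply(psd, as_nm, closed = FALSE)
  glial <- lapply(glial, as_nm, closed = FALSE)
  ves <- as.matrix(vesicles)
  if (length(ves) == 0L) ves <- matrix(numeric(0), ncol = 2L)
  if (ncol(ves) != 2L) stop("vesicles must be an m x 2 matrix")
  storage.mode(ves) <- "double"
  ves <- ves * scale
  if (nrow(ves) == 0L) {
    warning(sprintf("terminal '%s': empty vesicle list", terminal_id))
  } else {
    inside <- points_in_polygon(ves, perimeter)
    tol <- vesicle_diameter_nm / 2
    bad <- !inside & dist_to_trace(ves, perimeter) > tol
    if (any(bad)) {
      if (strict) {
        warning(sprintf(
          "terminal '%s': excluding %d vesicle(s) > %.1f nm outside the perimeter",
          terminal_id, sum(bad), tol))
        ves <- ves[!bad, , drop = FALSE]
      } else {
        warning(sprintf(
          "terminal '%s': %d vesicle(s) > %.1f nm outside the perimeter (retained)",
          terminal_id, sum(bad), tol))
      }
    }
  }
  structure(list(terminal_id = as.character(terminal_id),
                 condition = condition,
                 perimeter = perimeter, psd = psd, glial = glial,
                 vesicles = ves, scale = scale),
            class = "terminal_annotation")
}

#' @export
print.terminal_annotation <- function(x, ...) {
  cat(sprintf(
    "<terminal_annotation '%s' (%s): perimeter %.0f nm, %d PSD, %d glial, %d vesicles>\n",
    x$terminal_id, x$condition, trace_length(x$perimeter),
    length(x$psd), length(x$glial), nrow(x$vesicles)))
  invisible(x)
}

trace_to_list <- function(tr) unname(split(tr$points, row(tr$points)[, 1L]))

annotation_to_record <- function(ann) {
  un <- function(tr) unname(lapply(seq_len(nrow(tr$points)),
                                   function(i) tr$points[i, ] / ann$scale))
  list(id = ann$terminal_id,
       condition = ann$condition,
       scale_nm_per_px = ann$scale,
       perimeter = un(ann$perimeter),
       psd = lapply(ann$psd, un),
       glial = lapply(ann$glial, un),
       vesicles = unname(lapply(seq_len(nrow(ann$vesicles)),
                                function(i) ann$vesicles[i, ] / ann$scale)))
}

coord_matrix <- function(x, what, id) {
  if (length(x) == 0L) return(matrix(numeric(0), ncol = 2L))
  m <- try(do.call(rbind, lapply(x, function(p) as.numeric(unlist(p)))),
           silent = TRUE)
  if (inherits(m, "try-error") || ncol(m) != 2L)
    stop(sprintf("terminal '%s': malformed %s coordinates", id, what))
  m
}

#' Read an annotation bundle
#'
#' Reads traced-annotation coordinates into a list of
#' [terminal_annotation()] objects. Two on-disk forms are supported:
#'
#' * a JSON bundle: a top-level array of terminals, each
#'   `{"id", "condition", "scale_nm_per_px", "perimeter": [[x,y],...],
#'   "psd": [[[x,y],...],...], "glial": [[[x,y],...],...],
#'   "vesicles": [[x,y],...]}`, coordinates in pixels;
#' * a directory of two-column whitespace-separated XY text files (the
#'   ImageJ "Save XY Coordinates" dialect), named
#'   `<terminal_id>__<role>[_<index>].txt` with roles `perimeter`, `psd`,
#'   `glial`, `vesicles`.
#'
#' @param path JSON file or directory.
#' @param scale nm per pixel. Required for the directory form; for the JSON
#'   form it overrides the per-terminal `scale_nm_per_px` when given.
#' @param condition condition assigned to terminals that do not carry one
#'   (directory form).
#' @param strict passed to [terminal_annotation()].
#' @return list of `terminal_annotation`.
#' @export
read_annotation_bundle <- function(path, scale = NULL,
                                   condition = "unstimulated",
                                   strict = FALSE) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    return(read_xy_directory(path, scale = scale, condition = condition,
                             strict = strict))
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(rec) {
    id <- as.character(rec$id)
    sc <- if (!is.null(scale)) scale else rec$scale_nm_per_px
    if (is.null(sc)) stop(sprintf("terminal '%s': no scale given", id))
    if (is.null(rec$perimeter) || length(rec$perimeter) < 3L)
      stop(sprintf("terminal '%s': missing or degenerate perimeter trace", id))
    terminal_annotation(
      terminal_id = id,
      condition = if (is.null(rec$condition)) condition else rec$condition,
      perimeter = coord_matrix(rec$perimeter, "perimeter", id),
      psd = lapply(rec$psd, coord_matrix, "psd", id),
      glial = lapply(rec$glial, coord_matrix, "glial", id),
      vesicles = coord_matrix(rec$vesicles, "vesicle", id),
      scale = as.numeric(sc), strict = strict)
  })
}

read_xy_file <- function(f) {
  lines <- readLines(f, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- matrix(NA_real_, nrow = length(lines), ncol = 2L)
  for (i in seq_along(lines)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    if (length(v) != 2L || anyNA(v))
      stop(sprintf("unparseable line %d in %s: '%s'", i, f, lines[i]))
    out[i, ] <- v
  }
  out
}

read_xy_directory <- function(path, scale, condition, strict) {
  if (is.null(scale))
    stop("scale (nm per pixel) is required for XY-coordinate directories")
  files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0L) stop("no .txt coordinate files in ", path)
  base <- sub("\\.txt$", "", basename(files))
  parts <- regmatches(base, regexec(
    "^(.+)__(perimeter|psd|glial|vesicles)(?:_([0-9]+))?$", base))
  ok <- lengths(parts) == 4L
  if (any(!ok))
    stop("file name(s) not matching <id>__<role>[_<n>].txt: ",
         paste(basename(files)[!ok], collapse = ", "))
  ids <- vapply(parts, `[`, "", 2L)
  roles <- vapply(parts, `[`, "", 3L)
  lapply(unique(ids), function(id) {
    sel <- ids == id
    role_files <- split(files[sel], roles[sel])
    if (is.null(role_files$perimeter))
      stop(sprintf("terminal '%s': missing perimeter trace", id))
    ves <- if (is.null(role_files$vesicles)) matrix(numeric(0), ncol = 2L)
           else do.call(rbind, lapply(role_files$vesicles, read_xy_file))
    terminal_annotation(
      terminal_id = id, condition = condition,
      perimeter = read_xy_file(role_files$perimeter[[1L]]),
      psd = lapply(role_files$psd, read_xy_file),
      glial = lapply(role_files$glial, read_xy_file),
      vesicles = ves, scale = scale, strict = strict)
  })
}

#' Write annotations as a JSON bundle
#'
#' Inverse of the JSON form of [read_annotation_bundle()]: coordinates are
#' divided by each terminal's scale back to pixels.
#'
#' @param annotations list of [terminal_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_bundle <- function(annotations, path) {
  recs <- lapply(annotations, annotation_to_record)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
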