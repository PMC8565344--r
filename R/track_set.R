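#' Track set container
#'
#' A `track_set` bundles the localization table of many trajectories with the
#' acquisition metadata that every downstream analysis needs: the frame
#' interval `dt` (seconds), the camera pixel size (micrometre per pixel), a
#' free-text condition label and a provenance string.  Coordinates are always
#' stored in micrometres; frames are 0-based integers and the time of frame
#' `k` is `k * dt`.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x`, `y` and
#'   optionally `intensity` (micrometre coordinates).
#' @param dt frame interval in seconds (> 0).
#' @param pixel_size camera pixel size in micrometre per pixel (> 0).
#' @param condition free-text condition label.
#' @param source provenance string (file the data came from, or a simulator
#'   description).
#'
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks, dt, pixel_size = 0.106,
                      condition = "default", source = "in-memory") {
  stopifnot(is.data.frame(tracks))
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(tracks))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds)", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0", call. = FALSE)
  if (any(!is.finite(tracks$x)) || any(!is.finite(tracks$y)))
    stop("non-finite coordinates", call. = FALSE)
  if (any(tracks$frame < 0))
    stop("negative frame index", call. = FALSE)

  tracks$track_id <- as.character(tracks$track_id)
  ord <- order(tracks$track_id, tracks$frame)
  tracks <- tracks[ord, , drop = FALSE]
  rownames(tracks) <- NULL

  # frames strictly increasing within every track, >= 2 points per track
  for (id in unique(tracks$track_id)) {
    fr <- tracks$frame[tracks$track_id == id]
    if (length(fr) < 2L)
      stop("track '", id, "' has fewer than 2 localizations", call. = FALSE)
    if (any(diff(fr) <= 0))
      stop("non-monotone frames in track '", id, "'", call. = FALSE)
  }

  structure(
    list(tracks = tracks, dt = dt, pixel_size = pixel_size,
         condition = condition, source = source),
    class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat("Track set:", n_tracks(x), "tracks,", nrow(x$tracks),
      "localizations\n")
  cat("  dt =", x$dt, "s, pixel size =", x$pixel_size, "um/px\n")
  cat("  condition:", x$condition, "| source:", x$source, "\n")
  invisible(x)
}

#' Number of tracks in a track set
#' @param ts a `track_set`.
#' @return integer count.
#' @export
n_tracks <- function(ts) length(unique(ts$tracks$track_id))

# split localization table into per-track data.frames (ordered by frame)
split_tracks <- function(ts) {
  split(ts$tracks, ts$tracks$track_id)
}

#' Read trajectories from delimited text
#'
#' Reads a track table written by an upstream tracker.  The `generic_csv`
#' dialect expects a header `track_id,frame,x,y[,intensity]`; the
#' `utrack_export` dialect accepts the common export header
#' `id,frame,x,y[,amp]` and maps it onto the same fields.  Coordinates may be
#' given in micrometres (`units = "um"`) or in camera pixels
#' (`units = "px"`), in which case they are multiplied by `pixel_size`.
#'
#' @param path file to read.
#' @param dialect `"generic_csv"` or `"utrack_export"`.
#' @param pixel_size camera pixel size, micrometre per pixel.
#' @param dt frame interval in seconds.
#' @param units `"um"` (default) or `"px"`.
#' @param condition condition label to attach.
#' @param sep field separator (default comma).
#' @return a [track_set()].
#' @export
read_tracks <- function(path, dialect = c("generic_csv", "utrack_export"),
                        pixel_size = 0.106, dt = 0.04,
                        units = c("um", "px"), condition = "default",
                        sep = ",") {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  map <- switch(dialect,
    generic_csv = c(track_id = "track_id", frame = "frame", x = "x", y = "y",
                    intensity = "intensity"),
    utrack_export = c(track_id = "id", frame = "frame", x = "x", y = "y",
                      intensity = "amp"))
  need <- map[c("track_id", "frame", "x", "y")]
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         " for dialect '", dialect, "'", call. = FALSE)
  tracks <- data.frame(track_id = as.character(raw[[map["track_id"]]]),
                       frame = as.integer(raw[[map["frame"]]]),
                       x = as.numeric(raw[[map["x"]]]),
                       y = as.numeric(raw[[map["y"]]]),
                       stringsAsFactors = FALSE)
  if (map["intensity"] %in% names(raw))
    tracks$intensity <- as.numeric(raw[[map["intensity"]]])
  # frames must already be ordered within each track as stored in the file
  for (id in unique(tracks$track_id)) {
    fr <- tracks$frame[tracks$track_id == id]
    if (any(diff(fr) <= 0))
      stop("validation error: non-monotone frames in track '", id, "'",
           call. = FALSE)
  }
  if (units == "px") {
    tracks$x <- tracks$x * pixel_size
    tracks$y <- tracks$y * pixel_size
  }
  track_set(tracks, dt = dt, pixel_size = pixel_size, condition = condition,
            source = normalizePath(path))
}

#' Write trajectories to delimited text
#'
#' Writes the canonical `track_id,frame,x,y[,intensity]` table (micrometre
#' coordinates) at full precision, so that `read_tracks()` round-trips all
#' numeric fields exactly.
#'
#' @param ts a `track_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  df <- ts$tracks
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop short tracks
#'
#' Retains tracks with at least `min_steps` displacements, i.e. at least
#' `min_steps + 1` localizations.  Very short tracks produce artefactual
#' statistics, so analyses conventionally use a five-step minimum.
#'
#' @param ts a `track_set`.
#' @param min_steps minimum number of steps (displacements) per track.
#' @return filtered `track_set` (track order preserved).
#' @export
filter_min_steps <- function(ts, min_steps = 5L) {
  stopifnot(inherits(ts, "track_set"))
  if (min_steps < 1L) stop("min_steps must be >= 1", call. = FALSE)
  n_by <- table(ts$tracks$track_id)
  keep <- names(n_by)[n_by >= min_steps + 1L]
  out <- ts
  out$tracks <- ts$tracks[ts$tracks$track_id %in% keep, , drop = FALSE]
  rownames(out$tracks) <- NULL
  out
}
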