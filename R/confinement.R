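#' Detect confined motion within a track
#'
#' Scans windows of consecutive localizations: a window is confined when
#' every point lies within `radius` of the window centroid.  Maximal
#' confined windows spanning at least `min_steps` steps are reported, with
#' overlapping windows merged.  The defaults follow the common convention of
#' eight steps within one camera pixel (106 nm, about 2.5 times the
#' localization error).
#'
#' @param track per-track localization data.frame (`frame`, `x`, `y`), or a
#'   `track_set` (then every track is annotated).
#' @param radius confinement radius in micrometre.
#' @param min_steps minimum number of steps a confined window must span.
#' @return for a single track, a `confinement_annotation`: list with
#'   `track_id`, `segments` (data.frame `start_frame`, `end_frame`,
#'   `start_idx`, `end_idx`), and `label` in confined/free/mixed (confined
#'   when segments cover the whole track, free when there are none).  For a
#'   `track_set`, a list of annotations, one per track.
#' @export
detect_confinement <- function(track, radius = 0.106, min_steps = 8L) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (min_steps < 2L) stop("min_steps must be >= 2", call. = FALSE)
  if (inherits(track, "track_set")) {
    per <- split_tracks(track)
    out <- lapply(per, detect_confinement, radius = radius,
                  min_steps = min_steps)
    names(out) <- names(per)
    return(out)
  }
  n <- nrow(track)
  x <- track$x; y <- track$y
  wins <- list()
  i <- 1L
  while (i <= n - min_steps) {
    # greedy extension: longest confined window starting at i
    j_end <- NA_integer_
    cx <- x[i]; cy <- y[i]
    for (j in (i + 1L):n) {
      m <- j - i + 1L
      cx <- cx + (x[j] - cx) / m
      cy <- cy + (y[j] - cy) / m
      if (max((x[i:j] - cx)^2 + (y[i:j] - cy)^2) > radius^2) break
      j_end <- j
    }
    if (!is.na(j_end) && (j_end - i) >= min_steps) {
      wins[[length(wins) + 1L]] <- c(i, j_end)
      i <- i + 1L
    } else i <- i + 1L
  }
  segments <- .merge_windows(wins)
  label <- if (length(segments) == 0L) "free"
           else if (length(segments) == 1L && segments[[1L]][1L] == 1L &&
                    segments[[1L]][2L] == n) "confined"
           else "mixed"
  seg_df <- if (length(segments) == 0L)
    data.frame(start_frame = integer(0), end_frame = integer(0),
               start_idx = integer(0), end_idx = integer(0))
  else data.frame(
    start_frame = vapply(segments, function(s) track$frame[s[1L]], numeric(1)),
    end_frame = vapply(segments, function(s) track$frame[s[2L]], numeric(1)),
    start_idx = vapply(segments, `[`, integer(1), 1L),
    end_idx = vapply(segments, `[`, integer(1), 2L))
  structure(list(track_id = as.character(track$track_id[1L]),
                 segments = seg_df, label = label, n_points = n),
            class = "confinement_annotation")
}

# merge overlapping/touching index windows
.merge_windows <- function(wins) {
  if (length(wins) == 0L) return(list())
  wins <- wins[order(vapply(wins, `[`, integer(1), 1L))]
  out <- list(wins[[1L]])
  for (w in wins[-1L]) {
    last <- out[[length(out)]]
    if (w[1L] <= last[2L]) out[[length(out)]] <- c(last[1L], max(last[2L], w[2L]))
    else out[[length(out) + 1L]] <- w
  }
  out
}

#' Summarize confinement labels over a track set
#'
#' @param annotations result of [detect_confinement()] on a `track_set`.
#' @return data.frame with one row per track (`track_id`, `label`,
#'   `n_segments`) plus an attribute `counts` with the label tally.
#' @export
confinement_summary <- function(annotations) {
  df <- data.frame(
    track_id = vapply(annotations, `[[`, "", "track_id"),
    label = vapply(annotations, `[[`, "", "label"),
    n_segments = vapply(annotations, function(a) nrow(a$segments), integer(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "counts") <- table(factor(df$label,
                                     levels = c("confined", "free", "mixed")))
  df
}
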