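#' Clip sampling specification
#'
#' Parameters of clip extraction: `n` clips per recording, `k` frames per
#' clip, sampled every `s` parent frames. The effective length
#' `l = k * s` is the number of parent-video frames a clip spans; with the
#' defaults (`k = 12`, `s = 1`) a clip covers about one neonatal heartbeat.
#'
#' @param n clips per recording (default 10).
#' @param k frames per clip (default 12).
#' @param s sampling interval (default 1).
#' @return A list of class `clip_spec` with derived element `l = k * s`.
#' @export
clip_spec <- function(n = 10, k = 12, s = 1) {
  stopifnot(n >= 1, k >= 1, s >= 1)
  structure(list(n = as.integer(n), k = as.integer(k), s = as.integer(s),
                 l = as.integer(k) * as.integer(s)),
            class = "clip_spec")
}

#' Relative ventricle area per frame
#'
#' Fraction of frame pixels segmented as ventricle (LV union RV): the count
#' of mask pixels divided by the total number of pixels, per frame. Its
#' minima over a recording mark systole, its maxima diastole.
#'
#' @param masks a [mask_sequence()] or binary `T x H x W` array.
#' @return Numeric vector of length `T` with values in `[0, 1]`.
#' @export
relative_ventricle_area <- function(masks) {
  m <- if (inherits(masks, "mask_sequence")) masks$masks else masks
  d <- dim(m)
  if (is.null(d) || length(d) != 3L || d[1] < 1) {
    stop("masks must be a nonempty T x H x W stack", call. = FALSE)
  }
  apply(m, 1, sum) / (d[2] * d[3])
}

#' Select extreme-expansion frames by relative ventricle area
#'
#' Returns the `ceiling(fraction * T)` frame indices with the smallest
#' (`mode = "min"`, systole) or largest (`mode = "max"`, diastole) relative
#' ventricle area. Ties are broken toward the earlier frame; the default
#' 10% tail corresponds to roughly 10-12 frames of a typical ~122-frame
#' recording.
#'
#' @param areas per-frame area fractions.
#' @param mode `"min"` or `"max"`.
#' @param fraction tail size in `(0, 1]` (default 0.10).
#' @return Sorted 0-based frame indices.
#' @export
select_extreme_frames <- function(areas, mode = c("min", "max"),
                                  fraction = 0.10) {
  mode <- match.arg(mode)
  if (length(areas) == 0) stop("areas must be nonempty", call. = FALSE)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  m <- ceiling(fraction * length(areas))
  key <- if (mode == "min") areas else -areas
  ord <- order(key, seq_along(areas))   # ties -> ascending frame index
  sort(ord[seq_len(m)] - 1L)
}

#' Select random frames from a recording
#'
#' Draws `n` distinct frame indices uniformly without replacement from the
#' current RNG stream.
#'
#' @param video an [echo_video()] (or an integer frame count).
#' @param n number of frames; at most `T`.
#' @return 0-based frame indices, in draw order.
#' @export
select_random_frames <- function(video, n) {
  tt <- if (inherits(video, "echo_video")) dim(video$frames)[1]
        else as.integer(video)
  if (n > tt) {
    stop(sprintf("cannot draw %d distinct frames from a %d-frame video",
                 n, tt), call. = FALSE)
  }
  sample.int(tt, n) - 1L
}

#' Extract random clips from a recording
#'
#' Draws `spec$n` clips of `k` frames sampled every `s` frames, each start
#' frame drawn uniformly (with replacement across clips) from the valid
#' range `[0, T - (k - 1) s - 1]`. Frame `i` of a clip is parent frame
#' `start + i * s`.
#'
#' @param video an [echo_video()].
#' @param spec a [clip_spec()].
#' @return List of clips; each has `frames` (`k x H x W`), `start` (0-based),
#'   `spec`, `subject_id` and `view`.
#' @export
extract_clips <- function(video, spec = clip_spec()) {
  d <- dim(video$frames)
  need <- (spec$k - 1L) * spec$s + 1L
  if (d[1] < need) {
    stop(sprintf("video too short for clips: %d frames < required %d (k=%d, s=%d)",
                 d[1], need, spec$k, spec$s), call. = FALSE)
  }
  max_start <- d[1] - need           # 0-based
  starts <- sample.int(max_start + 1L, spec$n, replace = TRUE) - 1L
  lapply(starts, function(s0) {
    idx <- s0 + spec$s * (0:(spec$k - 1L)) + 1L
    structure(list(frames = video$frames[idx, , , drop = FALSE],
                   start = s0, spec = spec,
                   subject_id = video$subject_id, view = video$view),
              class = "echo_clip")
  })
}

#' @export
print.echo_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<echo_clip> subject %s view %s: %d frames %dx%d starting at %d (s=%d, l=%d)\n",
              x$subject_id, x$view, d[1], d[2], d[3], x$start,
              x$spec$s, x$spec$l))
  invisible(x)
}
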