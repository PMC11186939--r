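#' @useDynLib neoecho, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgamma sd quantile
NULL

#' Standard echocardiographic views
#'
#' The five standard neonatal transthoracic views handled by the package:
#' parasternal short axis at the papillary-muscle level (PSAX-P), parasternal
#' long axis (PLAX), apical four chamber (A4C), parasternal short axis at the
#' semilunar valves (PSAX-S), and apical short axis (PSAX-A).
#'
#' @return Character vector of the five view codes.
#' @export
echo_views <- function() {
  c("PSAX-P", "PLAX", "A4C", "PSAX-S", "PSAX-A")
}

#' Construct an echo video object
#'
#' An `echo_video` holds one view's grayscale frame stack together with its
#' acquisition and label metadata. Frames are stored as a `T x H x W` array of
#' 8-bit intensities (0-255); frame and pixel indices are 0-based in all
#' user-facing index arguments, with the row axis pointing down.
#'
#' @param frames numeric or integer array of dimension `c(T, H, W)` with
#'   values in 0-255. A `T x H x W x 3` color array is reduced to a single
#'   luminance channel (ITU-R BT.601 weights).
#' @param fps frames per second, positive scalar.
#' @param view one of [echo_views()].
#' @param subject_id opaque subject identifier.
#' @param label optional severity grade: 0 = no PH, 1 = mild PH,
#'   2 = moderate-to-severe PH, or `NA`.
#' @return An object of class `echo_video`.
#' @export
echo_video <- function(frames, fps = 25, view = "PSAX-P", subject_id = "anon",
                       label = NA) {
  if (length(dim(frames)) == 4L && dim(frames)[4] == 3L) {
    frames <- rgb_to_luminance(frames)
  }
  v <- structure(
    list(
      frames = frames, fps = as.numeric(fps), view = as.character(view),
      subject_id = as.character(subject_id),
      label = if (is.na(label)) NA_integer_ else as.integer(label)
    ),
    class = "echo_video"
  )
  validate_echo_video(v)
  v
}

rgb_to_luminance <- function(x) {
  y <- 0.299 * x[, , , 1] + 0.587 * x[, , , 2] + 0.114 * x[, , , 3]
  round(array(y, dim(x)[1:3]))
}

validate_echo_video <- function(v) {
  d <- dim(v$frames)
  if (is.null(d) || length(d) != 3L) {
    stop("frames must be a T x H x W array", call. = FALSE)
  }
  if (d[1] < 1L) stop("video must contain at least one frame", call. = FALSE)
  if (d[2] < 8L || d[3] < 8L) {
    stop("frame size must be at least 8 x 8 pixels", call. = FALSE)
  }
  rng <- range(v$frames)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!v$view %in% echo_views()) {
    stop(sprintf("unknown view '%s'; expected one of %s", v$view,
                 paste(echo_views(), collapse = ", ")), call. = FALSE)
  }
  if (!is.na(v$fps) && v$fps <= 0) stop("fps must be positive", call. = FALSE)
  if (!is.na(v$label) && !v$label %in% 0:2) {
    stop("label must be 0 (none), 1 (mild) or 2 (moderate-severe)",
         call. = FALSE)
  }
  invisible(v)
}

#' @export
print.echo_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<echo_video> subject %s, view %s, %d frames %dx%d @ %g fps, label %s\n",
              x$subject_id, x$view, d[1], d[2], d[3], x$fps,
              ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

#' @export
dim.echo_video <- function(x) dim(x$frames)

#' Construct a ventricle mask sequence
#'
#' Binary per-frame segmentation masks marking ventricle pixels (union of
#' left and right ventricle). The stack must match its parent video's shape.
#' Masks may come from an external segmentation model or from the simulator.
#'
#' @param masks array of dimension `c(T, H, W)` with values in `{0, 1}`.
#' @param source `"external"` or `"synthetic"`.
#' @return An object of class `mask_sequence`.
#' @export
mask_sequence <- function(masks, source = c("external", "synthetic")) {
  source <- match.arg(source)
  d <- dim(masks)
  if (is.null(d) || length(d) != 3L) {
    stop("masks must be a T x H x W array", call. = FALSE)
  }
  if (!all(masks %in% c(0, 1))) {
    stop("mask values must be 0 or 1", call. = FALSE)
  }
  structure(list(masks = masks, source = source), class = "mask_sequence")
}

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<mask_sequence> %d frames %dx%d (%s), mean coverage %.3f\n",
              d[1], d[2], d[3], x$source, mean(x$masks)))
  invisible(x)
}

#' @export
dim.mask_sequence <- function(x) dim(x$masks)

check_same_shape <- function(video, masks) {
  if (!identical(dim(video$frames), dim(masks$masks))) {
    stop("mask stack shape does not match video shape", call. = FALSE)
  }
  invisible(TRUE)
}
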