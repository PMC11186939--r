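# Bilinear sampling of img (H x W matrix) at continuous 1-based coordinates
# (ys, xs). outside = "clamp" replicates the border (used by resize);
# outside = "zero" fills out-of-frame samples with 0 (used by affine warps).
bilinear_sample <- function(img, ys, xs, outside = c("clamp", "zero")) {
  outside <- match.arg(outside)
  h <- nrow(img); w <- ncol(img)
  inside <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
  yc <- pmin(pmax(ys, 1), h)
  xc <- pmin(pmax(xs, 1), w)
  y0 <- pmin(floor(yc), h - 1); x0 <- pmin(floor(xc), w - 1)
  fy <- yc - y0; fx <- xc - x0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  v00 <- img[i00]
  v01 <- img[cbind(i00[, 1], i00[, 2] + 1)]
  v10 <- img[cbind(i00[, 1] + 1, i00[, 2])]
  v11 <- img[cbind(i00[, 1] + 1, i00[, 2] + 1)]
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out <- matrix(out, nrow(ys), ncol(ys))
  if (outside == "zero") out[!inside] <- 0
  out
}

#' Estimate the scanning-sector mask of a recording
#'
#' The ultrasound sector is recovered by thresholding the temporal-maximum
#' image and keeping its largest connected component; everything outside
#' (burned-in text, signal traces) is background. Supply a manual mask to
#' [apply_sector()] instead when the estimate is unsatisfactory.
#'
#' @param video an [echo_video()].
#' @param threshold intensity above which a pixel ever being lit counts as
#'   inside the sector (default 0).
#' @return Binary `H x W` matrix (1 = inside the sector).
#' @export
estimate_sector_mask <- function(video, threshold = 0) {
  mx <- apply(video$frames, c(2, 3), max)
  bw <- (mx > threshold) * 1
  lab <- EBImage::bwlabel(bw)
  if (max(lab) == 0) stop("no sector found: video is entirely black",
                          call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) * 1
}

#' Mask a video to its scanning sector and crop
#'
#' Sets all pixels outside the sector mask to 0 and crops every frame to
#' the mask's bounding box, removing annotation margins around the fan.
#'
#' @param video an [echo_video()].
#' @param mask binary `H x W` matrix matching the frame shape; must be
#'   nonempty.
#' @return The masked, cropped [echo_video()].
#' @export
apply_sector <- function(video, mask) {
  d <- dim(video$frames)
  if (!identical(dim(mask), d[2:3])) {
    stop("sector mask shape does not match frame shape", call. = FALSE)
  }
  if (sum(mask) == 0) stop("sector mask is empty", call. = FALSE)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  out <- array(0, c(d[1], diff(rows) + 1, diff(cols) + 1))
  sub <- mask[rows[1]:rows[2], cols[1]:cols[2]]
  for (t in seq_len(d[1])) {
    f <- video$frames[t, rows[1]:rows[2], cols[1]:cols[2]]
    out[t, , ] <- f * sub
  }
  v <- video; v$frames <- out
  validate_echo_video(v)
  v
}

#' Resize video frames by bilinear interpolation
#'
#' Frames are resampled to `size` with the half-pixel center convention
#' (`src = (dst + 0.5) * scale - 0.5`), which makes downsampling an
#' averaging-consistent operation and a same-size resize the identity.
#' Intensities are rounded back to, and clipped at, 8-bit range.
#'
#' @param video an [echo_video()].
#' @param size target `c(H, W)` (a single number is used for both); both at
#'   least 8.
#' @return The resized [echo_video()].
#' @export
resize_frames <- function(video, size) {
  if (length(size) == 1) size <- c(size, size)
  if (any(size < 8)) stop("target size must be at least 8", call. = FALSE)
  d <- dim(video$frames)
  hh <- size[1]; ww <- size[2]
  ys <- matrix(rep((seq_len(hh) - 0.5) * d[2] / hh + 0.5, times = ww), hh, ww)
  xs <- matrix(rep((seq_len(ww) - 0.5) * d[3] / ww + 0.5, each = hh), hh, ww)
  out <- array(0, c(d[1], hh, ww))
  for (t in seq_len(d[1])) {
    out[t, , ] <- pmin(255, pmax(0, round(
      bilinear_sample(video$frames[t, , ], ys, xs, outside = "clamp")
    )))
  }
  v <- video; v$frames <- out
  v
}

#' Per-frame global histogram equalization
#'
#' Spreads the in-sector intensity distribution of every frame across the
#' full 8-bit range through the standard CDF mapping
#' `out = round(255 * cdf(v))`, computed over in-mask pixels only.
#' Out-of-mask pixels remain 0. The mapping is monotone, so the intensity
#' rank order inside the sector is preserved.
#'
#' @param video an [echo_video()].
#' @param mask optional binary `H x W` sector mask; `NULL` equalizes over
#'   the whole frame.
#' @return The equalized [echo_video()].
#' @export
equalize_histogram <- function(video, mask = NULL) {
  d <- dim(video$frames)
  if (!is.null(mask) && !identical(dim(mask), d[2:3])) {
    stop("mask shape does not match frame shape", call. = FALSE)
  }
  out <- video$frames
  sel <- if (is.null(mask)) rep(TRUE, d[2] * d[3]) else mask == 1
  for (t in seq_len(d[1])) {
    f <- video$frames[t, , ]
    v <- f[sel]
    counts <- tabulate(v + 1L, nbins = 256L)
    cdf <- cumsum(counts) / length(v)
    mapped <- round(255 * cdf)
    g <- f
    g[sel] <- mapped[v + 1L]
    if (!is.null(mask)) g[!sel] <- 0
    out[t, , ] <- g
  }
  vd <- video; vd$frames <- out
  vd
}

#' Scale and standardize frames for the classifier
#'
#' Maps 8-bit intensities to `[0, 1]` and standardizes with the dataset
#' mean and standard deviation recorded in the training configuration
#' (computed on the training split only). Optionally replicates the single
#' gray channel, as needed by backbones expecting 3-channel input.
#'
#' @param x an [echo_video()], a `T x H x W` (or `H x W`) array of 8-bit
#'   intensities, or a clip.
#' @param mean,std normalization statistics on the `[0, 1]` scale.
#' @param channels 1 to keep grayscale, 3 to replicate.
#' @return A real-valued array; with `channels = 3` a trailing channel axis
#'   is appended.
#' @export
normalize_for_model <- function(x, mean = 0, std = 1, channels = 1) {
  if (std <= 0) stop("std must be positive", call. = FALSE)
  arr <- if (inherits(x, "echo_video")) x$frames else x
  out <- (arr / 255 - mean) / std
  if (channels == 3) {
    out <- array(rep(out, 3), c(dim(out), 3))
  }
  out
}

#' Standard preprocessing pipeline
#'
#' Sector masking, cropping, bilinear resize and in-sector histogram
#' equalization, in that order.
#'
#' @param video an [echo_video()].
#' @param size target square size (default 224).
#' @param sector optional precomputed sector mask; `NULL` estimates one.
#' @return The preprocessed [echo_video()].
#' @export
preprocess_video <- function(video, size = 224, sector = NULL) {
  if (is.null(sector)) sector <- estimate_sector_mask(video)
  v <- apply_sector(video, sector)
  v <- resize_frames(v, size)
  equalize_histogram(v)
}
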