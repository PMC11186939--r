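#' Augmentation configuration
#'
#' Parameter ranges of the training-time augmentation suite: five intensity
#' transforms (sharpness, brightness, gamma, gaussian/salt-and-pepper noise,
#' speckle) and the spatial transforms (rotation with translation, and
#' re-scaling). A whole sample is augmented with probability `p_sample`;
#' each transform then fires independently with probability `p_transform`.
#' Parameters are drawn once per sequence and shared by all its frames so
#' the temporal signal is not destroyed by per-frame jitter.
#'
#' @param p_transform per-transform gate probability (default 0.5).
#' @param p_sample whole-sample gate probability (default 0.9).
#' @param blur_range blur branch of the sharpness factor, `f < 1`.
#' @param sharpen_range sharpen branch, up to 8x.
#' @param brightness_range brightness factor range.
#' @param gamma_range gamma-correction exponent range.
#' @param sp_threshold salt-and-pepper per-tail corruption probability
#'   (default 0.005).
#' @param gaussian_sigma_range additive gaussian noise SD range in intensity
#'   units (default up to 12.75, i.e. 5% of range).
#' @param speckle_range multiplicative speckle SD range.
#' @param rotation_range rotation in degrees.
#' @param translation_max maximum translation as a fraction of the side.
#' @param scale_range re-scaling factor range.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(p_transform = 0.5, p_sample = 0.9,
                           blur_range = c(0, 0.9999),
                           sharpen_range = c(1, 8),
                           brightness_range = c(0.5, 1.2),
                           gamma_range = c(0.25, 2.0),
                           sp_threshold = 0.005,
                           gaussian_sigma_range = c(0, 12.75),
                           speckle_range = c(0, 0.2),
                           rotation_range = c(-15, 15),
                           translation_max = 0.1,
                           scale_range = c(0.8, 1.2)) {
  stopifnot(p_transform >= 0, p_transform <= 1, p_sample >= 0, p_sample <= 1)
  structure(as.list(environment()), class = "augment_config")
}

clip8 <- function(x) pmin(pmax(round(x), 0), 255)  # array first: keeps dim

#' Gamma correction
#'
#' `I_out = 255 * (I_in / 255)^gamma`, rounded and clipped to 8-bit range.
#' `gamma < 1` brightens mid-tones, `gamma > 1` darkens them, `gamma = 1`
#' is the identity.
#'
#' @param image 8-bit frame (matrix) or frame stack.
#' @param gamma positive exponent.
#' @return Transformed image of the same shape.
#' @export
gamma_correct <- function(image, gamma) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  clip8(255 * (image / 255)^gamma)
}

#' Brightness adjustment
#'
#' Multiplies intensities by `b` (rounded, clipped): `b < 1` darkens,
#' `b > 1` brightens, `b = 1` is the identity.
#'
#' @param image 8-bit frame or stack.
#' @param b nonnegative factor.
#' @return Transformed image.
#' @export
adjust_brightness <- function(image, b) {
  if (b < 0) stop("brightness factor must be nonnegative", call. = FALSE)
  clip8(b * image)
}

# 3x3 smoothing used as the blur anchor of the sharpness blend; border
# pixels are left untouched so the operator is well defined at the edge.
smooth3 <- function(image) {
  k <- matrix(c(1, 1, 1, 1, 5, 1, 1, 1, 1), 3, 3) / 13
  h <- nrow(image); w <- ncol(image)
  out <- image
  if (h < 3 || w < 3) return(out)
  acc <- matrix(0, h - 2, w - 2)
  for (dy in 0:2) for (dx in 0:2) {
    acc <- acc + k[dy + 1, dx + 1] *
      image[(1 + dy):(h - 2 + dy), (1 + dx):(w - 2 + dx)]
  }
  out[2:(h - 1), 2:(w - 1)] <- acc
  out
}

#' Sharpness adjustment
#'
#' Linear blend between a 3x3-smoothed copy and the original:
#' `out = smoothed + f * (original - smoothed)`. `f = 0` gives the fully
#' blurred image, `f = 1` the original, and `f > 1` (up to 8) extrapolates
#' beyond it, enhancing edges. Border pixels are not smoothed.
#'
#' @param image 8-bit frame.
#' @param f nonnegative sharpness factor.
#' @return Transformed image.
#' @export
adjust_sharpness <- function(image, f) {
  if (f < 0) stop("sharpness factor must be nonnegative", call. = FALSE)
  sm <- smooth3(image)
  clip8(sm + f * (image - sm))
}

#' Add pixel noise
#'
#' Salt-and-pepper noise sets each pixel to 0 with probability `theta` and
#' to 255 with probability `theta`; gaussian noise adds `N(0, sigma^2)` in
#' intensity units; speckle multiplies by `1 + e` with
#' `e ~ N(0, strength^2)`. Draws come from the current RNG stream.
#'
#' @param image 8-bit frame.
#' @param kind one of `"salt_pepper"`, `"gaussian"`, `"speckle"`.
#' @param theta per-tail salt-and-pepper probability.
#' @param sigma gaussian SD (intensity units).
#' @param strength speckle SD.
#' @return Noisy image.
#' @export
add_noise <- function(image, kind = c("salt_pepper", "gaussian", "speckle"),
                      theta = 0.005, sigma = 5, strength = 0.1) {
  kind <- tryCatch(match.arg(kind), error = function(e) {
    stop(sprintf("unknown noise kind '%s'", kind[1]), call. = FALSE)
  })
  n <- length(image)
  switch(kind,
    salt_pepper = {
      u <- array(runif(n), dim(image))
      out <- image
      out[u < theta] <- 0
      out[u > 1 - theta] <- 255
      out
    },
    gaussian = clip8(image + array(rnorm(n, 0, sigma), dim(image))),
    speckle = clip8(image * (1 + array(rnorm(n, 0, strength), dim(image))))
  )
}

#' Affine warp of a frame
#'
#' Rotation about the image center, translation (as a fraction of the side)
#' and isotropic scaling, applied in a single bilinear resampling pass with
#' out-of-frame samples filled with 0. A forward point maps as
#' `p_out = scale * R(angle) * (p_in - center) + center + t`.
#'
#' @param image 8-bit frame.
#' @param angle rotation in degrees (counter-clockwise in row/col space).
#' @param tx,ty translation along columns and rows, as a fraction of the
#'   respective side.
#' @param scale isotropic zoom factor.
#' @return Warped image of the same shape.
#' @export
affine_transform <- function(image, angle = 0, tx = 0, ty = 0, scale = 1) {
  h <- nrow(image); w <- ncol(image)
  if (angle == 0 && tx == 0 && ty == 0 && scale == 1) return(image)
  a <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  # inverse map: undo translation, then rotation/scale about the center
  xd <- xs - cx - tx * w
  yd <- ys - cy - ty * h
  ca <- cos(a); sa <- sin(a)
  xsrc <- (ca * xd + sa * yd) / scale + cx
  ysrc <- (-sa * xd + ca * yd) / scale + cy
  clip8(bilinear_sample(image, ysrc, xsrc, outside = "zero"))
}

#' Randomly augment a sequence
#'
#' With probability `1 - p_sample` the input is returned unchanged.
#' Otherwise each of the eight transforms is gated independently at
#' `p_transform`, its parameters are drawn once, and the identical
#' transform is applied to every frame of the sequence (noise fields
#' included), in the fixed order: sharpness, brightness, gamma, gaussian
#' noise, salt-and-pepper, speckle, rotation + translation, scale. The
#' sharpen-vs-blur branch of the sharpness transform is chosen uniformly.
#' All randomness comes from the current RNG stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param frames `T x H x W` 8-bit stack (a single `H x W` frame is treated
#'   as a 1-frame stack) or an [echo_video()].
#' @param config an [augment_config()].
#' @param return_info also report which gates fired: returns a list with
#'   `frames`, `augmented` (sample gate) and `gates` (logical vector over
#'   the eight transforms).
#' @return Augmented stack of the same shape (or [echo_video()]); a list
#'   when `return_info = TRUE`.
#' @export
augment_clip <- function(frames, config = augment_config(),
                         return_info = FALSE) {
  if (inherits(frames, "echo_video")) {
    v <- frames
    v$frames <- augment_clip(frames$frames, config)
    return(v)
  }
  single <- length(dim(frames)) == 2L
  x <- if (single) array(frames, c(1, dim(frames))) else frames
  if (runif(1) > config$p_sample) {
    out <- if (single) frames else x
    if (return_info) {
      return(list(frames = out, augmented = FALSE,
                  gates = rep(FALSE, 8)))
    }
    return(out)
  }
  gates <- runif(8) < config$p_transform
  d <- dim(x)
  runif2 <- function(r) runif(1, r[1], r[2])

  par <- list(
    sharp = if (gates[1]) {
      if (runif(1) < 0.5) runif2(config$blur_range) else runif2(config$sharpen_range)
    },
    bright = if (gates[2]) runif2(config$brightness_range),
    gamma = if (gates[3]) runif2(config$gamma_range),
    gsigma = if (gates[4]) runif2(config$gaussian_sigma_range),
    sp = gates[5],
    speckle = if (gates[6]) runif2(config$speckle_range),
    rot = if (gates[7]) list(angle = runif2(config$rotation_range),
                             tx = runif(1, -config$translation_max,
                                        config$translation_max),
                             ty = runif(1, -config$translation_max,
                                        config$translation_max)),
    scale = if (gates[8]) runif2(config$scale_range)
  )
  # shared per-sequence noise fields: the same realization on every frame
  gnoise <- if (gates[4]) matrix(rnorm(d[2] * d[3], 0, par$gsigma), d[2], d[3])
  spu <- if (gates[5]) matrix(runif(d[2] * d[3]), d[2], d[3])
  snoise <- if (gates[6]) matrix(rnorm(d[2] * d[3], 0, par$speckle), d[2], d[3])

  for (t in seq_len(d[1])) {
    f <- x[t, , ]
    if (gates[1]) f <- adjust_sharpness(f, par$sharp)
    if (gates[2]) f <- adjust_brightness(f, par$bright)
    if (gates[3]) f <- gamma_correct(f, par$gamma)
    if (gates[4]) f <- clip8(f + gnoise)
    if (gates[5]) {
      f[spu < config$sp_threshold] <- 0
      f[spu > 1 - config$sp_threshold] <- 255
    }
    if (gates[6]) f <- clip8(f * (1 + snoise))
    if (gates[7]) f <- affine_transform(f, angle = par$rot$angle,
                                        tx = par$rot$tx, ty = par$rot$ty)
    if (gates[8]) f <- affine_transform(f, scale = par$scale)
    x[t, , ] <- f
  }
  out <- if (single) x[1, , ] else x
  if (return_info) {
    return(list(frames = out, augmented = TRUE, gates = gates))
  }
  out
}
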