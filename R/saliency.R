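# linear interpolation of a T' x H x W volume along time to length k
interp_time <- function(vol, k) {
  tin <- dim(vol)[1]
  if (tin == k) return(vol)
  pos <- (seq_len(k) - 0.5) * tin / k + 0.5
  pos <- pmin(pmax(pos, 1), tin)
  lo <- pmin(floor(pos), tin - 1)
  fr <- pos - lo
  out <- array(0, c(k, dim(vol)[2], dim(vol)[3]))
  for (t in seq_len(k)) {
    out[t, , ] <- (1 - fr[t]) * vol[lo[t], , ] + fr[t] * vol[lo[t] + 1, , ]
  }
  out
}

upsample_trilinear <- function(vol, k, h, w) {
  tin <- dim(vol)[1]
  ys <- matrix(rep((seq_len(h) - 0.5) * dim(vol)[2] / h + 0.5, times = w), h, w)
  xs <- matrix(rep((seq_len(w) - 0.5) * dim(vol)[3] / w + 0.5, each = h), h, w)
  sp <- array(0, c(tin, h, w))
  for (t in seq_len(tin)) {
    sp[t, , ] <- bilinear_sample(vol[t, , ], ys, xs, outside = "clamp")
  }
  interp_time(sp, k)
}

#' Grad-CAM saliency for spatio-temporal clips
#'
#' Extends gradient-weighted class activation mapping to 3D inputs: the
#' gradient of the target-class logit is backpropagated to a convolutional
#' feature map `A`, each channel receives the weight
#' `alpha_c = mean_(t,h,w) dy/dA_c`, and the relevance volume is
#' `ReLU(sum_c alpha_c A_c)`, upsampled trilinearly to the clip's
#' `k x H x W` shape and min-max normalized to `[0, 1]` per volume (a
#' constant raw map yields all zeros). The default target layer is the
#' output of the last convolutional block.
#'
#' @param model a trained [build_model()] classifier.
#' @param clip `k x H x W` 8-bit stack or `echo_clip`.
#' @param target_class class index in `0 .. num_classes - 1`.
#' @param layer 1-based index into the model's layer stack; `NULL` selects
#'   the last block.
#' @return A `saliency_volume`: list with `map` (`k x H x W` in `[0, 1]`),
#'   `target_class`, `layer` and the unnormalized `raw` map.
#' @export
gradcam3d <- function(model, clip, target_class, layer = NULL) {
  frames <- clip_frames(clip)
  d <- dim(frames)
  if (is.null(layer)) layer <- length(model$layers)
  if (layer < 1 || layer > length(model$layers)) {
    stop(sprintf("layer must be in 1..%d", length(model$layers)),
         call. = FALSE)
  }
  x <- make_batch(list(frames), model$norm)
  fwd <- net_forward(model, x, train = FALSE, keep_acts = TRUE)
  onehot <- matrix(0, model$num_classes, 1)
  onehot[target_class + 1, 1] <- 1
  bwd <- net_backward(model, fwd, onehot, stop_at = layer)
  A <- fwd$acts[[layer]]          # (W', H', T', C, 1)
  dA <- bwd$d_at_stop
  da <- dim(A)
  nc <- da[4]
  alpha <- vapply(seq_len(nc), function(c) mean(dA[, , , c, 1]), numeric(1))
  raw <- array(0, da[1:3])
  for (c in seq_len(nc)) raw <- raw + alpha[c] * A[, , , c, 1]
  raw <- pmax(raw, 0)
  vol <- aperm(raw, c(3, 2, 1))   # -> (T', H', W')
  up <- upsample_trilinear(vol, d[1], d[2], d[3])
  rng <- range(up)
  map <- if (rng[2] - rng[1] < 1e-12) array(0, dim(up)) else
    (up - rng[1]) / (rng[2] - rng[1])
  structure(list(map = map, target_class = target_class, layer = layer,
                 raw = up),
            class = "saliency_volume")
}

#' @export
print.saliency_volume <- function(x, ...) {
  d <- dim(x$map)
  cat(sprintf("<saliency_volume> %d x %d x %d, class %d, layer %d, mass %.3f\n",
              d[1], d[2], d[3], x$target_class, x$layer, mean(x$map)))
  invisible(x)
}

#' Render a saliency overlay on a clip
#'
#' Alpha-blends a heatmap of the saliency volume over the grayscale frames:
#' the per-pixel blend weight is `alpha * saliency`, so zero saliency
#' reproduces the grayscale frame exactly.
#'
#' @param clip `k x H x W` 8-bit stack or `echo_clip`.
#' @param saliency a `saliency_volume` (or bare `[0, 1]` array of matching
#'   shape).
#' @param alpha maximum heat opacity (default 0.45).
#' @param colors colormap anchor colors, low to high.
#' @return `k x H x W x 3` array of 8-bit RGB frames.
#' @export
render_overlay <- function(clip, saliency, alpha = 0.45,
                           colors = c("blue", "cyan", "yellow", "red")) {
  frames <- clip_frames(clip)
  s <- if (inherits(saliency, "saliency_volume")) saliency$map else saliency
  if (!identical(dim(frames), dim(s))) {
    stop("saliency shape does not match clip shape", call. = FALSE)
  }
  ramp <- grDevices::colorRamp(colors)
  heat <- ramp(as.numeric(s))     # N x 3 in 0..255
  d <- dim(frames)
  out <- array(0, c(d, 3))
  wgt <- alpha * as.numeric(s)
  for (ch in 1:3) {
    out[, , , ch] <- round((1 - wgt) * as.numeric(frames) +
                             wgt * heat[, ch])
  }
  out
}

#' Write an RGB overlay as a multi-page TIFF
#'
#' @param overlay `k x H x W x 3` array from [render_overlay()].
#' @param path destination `.tif` file.
#' @return `path`, invisibly.
#' @export
write_overlay_video <- function(overlay, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("overlay export requires the 'tiff' package", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(overlay)[1]), function(t) {
    overlay[t, , , ] / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "deflate")
  invisible(path)
}

#' Model-randomization sanity check for saliency
#'
#' Saliency methods that behave like edge detectors keep producing the same
#' maps when the model's learned weights are destroyed. This check
#' re-initialises the final block and classification head with fresh random
#' weights, recomputes the Grad-CAM volume, and reports the Spearman rank
#' correlation with the original map. A sensitive method yields low
#' correlation; a correlation involving a constant map is reported as 0 by
#' convention.
#'
#' @param model a trained [build_model()] classifier.
#' @param clip `k x H x W` stack or `echo_clip`.
#' @param target_class class index.
#' @param layer target layer as in [gradcam3d()].
#' @return Spearman correlation in `[-1, 1]` (0 for degenerate maps).
#' @export
randomization_sanity <- function(model, clip, target_class, layer = NULL) {
  orig <- gradcam3d(model, clip, target_class, layer)
  rand <- model
  li <- length(rand$layers)
  rand$layers[[li]] <- reinit_layer(rand$layers[[li]])
  rand$fc$W <- matrix(rnorm(length(rand$fc$W), 0,
                            sqrt(2 / ncol(rand$fc$W))),
                      nrow(rand$fc$W), ncol(rand$fc$W))
  rand$fc$b <- rep(0, length(rand$fc$b))
  perturbed <- gradcam3d(rand, clip, target_class, layer)
  a <- as.numeric(orig$map); b <- as.numeric(perturbed$map)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
  stats::cor(a, b, method = "spearman")
}

reinit_layer <- function(layer) {
  if (layer$type == "conv") {
    fan_in <- prod(dim(layer$W)[1:4])
    layer$W <- he_init(dim(layer$W), fan_in)
    layer$b <- rep(0, length(layer$b))
  } else if (layer$type == "bn") {
    layer$gamma <- rep(1, length(layer$gamma))
    layer$beta <- rep(0, length(layer$beta))
  } else if (layer$type == "block") {
    for (nm in c("conv1", "bn1", "conv2", "bn2", "proj_conv", "proj_bn")) {
      if (!is.null(layer[[nm]])) layer[[nm]] <- reinit_layer(layer[[nm]])
    }
  }
  layer
}
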