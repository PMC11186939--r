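#' Training configuration
#'
#' Optimisation settings for the classifiers: Adam minimising categorical
#' cross-entropy with learning rate and weight decay both 0.001, no
#' learning-rate schedule. The reference setting trains for around 150
#' epochs with batch size 8 for clip models and 64 for frame models;
#' CPU-scale experiments in this package use 10-30 epochs.
#'
#' @param lr learning rate (default 0.001).
#' @param weight_decay L2 penalty applied through the Adam update
#'   (default 0.001).
#' @param epochs training epochs (default 20).
#' @param batch_size samples per optimisation step (default 8).
#' @param seed integer seed making the run reproducible; `NULL` uses the
#'   current RNG stream.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 0.001, weight_decay = 0.001, epochs = 20,
                         batch_size = 8, seed = NULL) {
  stopifnot(lr > 0, weight_decay >= 0, epochs >= 1, batch_size >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed),
            class = "train_config")
}

#' Inverse-class-frequency sample weights
#'
#' Weight `w_i = 1 / count(class(i))` for every sample, so that drawing
#' with replacement with these weights shows the model approximately equal
#' numbers of samples from each class per epoch.
#'
#' @param labels per-sample class labels (every class present at least
#'   once).
#' @return Numeric weight vector, one entry per sample.
#' @export
compute_sample_weights <- function(labels) {
  if (length(labels) == 0) stop("labels must be nonempty", call. = FALSE)
  counts <- table(labels)
  as.numeric(1 / counts[as.character(labels)])
}

# assemble a (W, H, T, C, N) batch from a list of k x H x W 8-bit stacks,
# augmenting and normalizing each sample
make_batch <- function(samples, norm, augment_cfg = NULL) {
  n <- length(samples)
  first <- samples[[1]]
  d <- dim(first)
  x <- array(0, c(d[3], d[2], d[1], 1, n))
  for (i in seq_len(n)) {
    f <- samples[[i]]
    if (!is.null(augment_cfg)) f <- augment_clip(f, augment_cfg)
    f <- (f / 255 - norm$mean) / norm$std
    x[, , , 1, i] <- aperm(f, c(3, 2, 1))
  }
  x
}

clip_frames <- function(s) {
  if (inherits(s, "echo_clip")) s$frames else s
}

#' Train a classifier
#'
#' Each epoch draws `length(samples)` samples with replacement using the
#' inverse-class-frequency weights of [compute_sample_weights()], augments
#' each drawn sample with [augment_clip()] (when a config is given),
#' standardizes it, and optimises the categorical cross-entropy with Adam.
#' The per-epoch mean loss is recorded in the returned history; the run is
#' reproducible given `config$seed` (single-threaded BLAS assumed).
#'
#' @param model a [build_model()] classifier.
#' @param samples list of `k x H x W` 8-bit frame stacks (or `echo_clip`s;
#'   frame models take 1-frame stacks).
#' @param labels per-sample class labels in `0 .. num_classes - 1`; at
#'   least two classes must be present.
#' @param config a [train_config()].
#' @param augment_cfg optional [augment_config()]; `NULL` disables
#'   augmentation.
#' @param norm normalization statistics (on the `[0, 1]` intensity scale)
#'   recorded into the model for use at prediction time.
#' @return The trained model, with a `history` data.frame (`epoch`,
#'   `loss`) attached.
#' @export
train_classifier <- function(model, samples, labels, config = train_config(),
                             augment_cfg = NULL,
                             norm = list(mean = 0.5, std = 0.25)) {
  if (length(unique(labels)) < 2) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  if (length(samples) != length(labels)) {
    stop("samples and labels must have equal length", call. = FALSE)
  }
  samples <- lapply(samples, clip_frames)
  with_seed(config$seed, {
    weights <- compute_sample_weights(labels)
    n <- length(samples)
    opt <- list(lr = config$lr, wd = config$weight_decay,
                b1 = 0.9, b2 = 0.999, eps = 1e-8, t = 0)
    state <- list(layers = vector("list", length(model$layers)), fc = list())
    history <- numeric(config$epochs)
    onehot <- diag(model$num_classes)
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n, n, replace = TRUE, prob = weights)
      losses <- c()
      for (b0 in seq(1, n, by = config$batch_size)) {
        bi <- idx[b0:min(b0 + config$batch_size - 1, n)]
        x <- make_batch(samples[bi], norm, augment_cfg)
        y <- onehot[, labels[bi] + 1, drop = FALSE]
        fwd <- net_forward(model, x, train = TRUE)
        model <- fwd$model
        p <- softmax_cols(fwd$logits)
        losses <- c(losses, -mean(colSums(y * log(pmax(p, 1e-12)))))
        dlogits <- (p - y) / ncol(y)
        bwd <- net_backward(model, fwd, dlogits)
        opt$t <- opt$t + 1
        upd <- adam_step(model, bwd$grads, bwd$layer_grads, state, opt)
        model <- upd$model
        state <- upd$state
      }
      history[ep] <- mean(losses)
    }
    model$norm <- norm
    model$history <- data.frame(epoch = seq_len(config$epochs),
                                loss = history)
    model
  })
}

#' Predict class probabilities for clips or frames
#'
#' Runs the model in evaluation mode (batch-norm running statistics) and
#' applies a softmax to the logits. The predicted label is the argmax;
#' exact probability ties resolve toward the higher severity.
#'
#' @param model a trained [build_model()] classifier.
#' @param samples one `k x H x W` stack / `echo_clip`, or a list of them.
#' @return For one sample, a list with `prob` (named by class) and `label`;
#'   for a list, a list with `prob` (matrix, one row per sample) and
#'   `label` (vector).
#' @export
predict_classifier <- function(model, samples) {
  single <- !is.list(samples) || inherits(samples, "echo_clip")
  if (single) samples <- list(samples)
  samples <- lapply(samples, clip_frames)
  d1 <- dim(samples[[1]])
  if (any(vapply(samples, function(s) !identical(dim(s), d1), logical(1)))) {
    stop("all samples in a batch must share one shape", call. = FALSE)
  }
  probs <- matrix(0, length(samples), model$num_classes,
                  dimnames = list(NULL, 0:(model$num_classes - 1)))
  bs <- 16L
  for (b0 in seq(1, length(samples), by = bs)) {
    bi <- b0:min(b0 + bs - 1, length(samples))
    x <- make_batch(samples[bi], model$norm)
    fwd <- net_forward(model, x, train = FALSE)
    probs[bi, ] <- t(softmax_cols(fwd$logits))
  }
  labels <- apply(probs, 1, function(p) max(which(p == max(p))) - 1)
  if (single) {
    list(prob = probs[1, ], label = labels[1])
  } else {
    list(prob = probs, label = labels)
  }
}

#' Build a clip dataset from a cohort manifest
#'
#' Reads every recording referenced by the manifest, optionally applies the
#' standard preprocessing pipeline ([preprocess_video()]), and extracts
#' `spec$n` random clips per recording. Frame models are served by
#' `spec = clip_spec(n, k = 1)`.
#'
#' @param manifest a [load_manifest()] cohort manifest.
#' @param spec a [clip_spec()].
#' @param size preprocessing target size (pixels); `NULL` skips
#'   preprocessing and uses raw frames.
#' @param views optional view filter.
#' @return List with `clips` (list of `k x H x W` stacks), `labels`,
#'   `subjects`, `views` and `starts`, aligned by index.
#' @export
build_clip_dataset <- function(manifest, spec = clip_spec(), size = 32,
                               views = NULL) {
  rows <- if (is.null(views)) seq_len(nrow(manifest)) else
    which(manifest$view %in% views)
  clips <- list(); labels <- c(); subjects <- c(); vws <- c(); starts <- c()
  for (r in rows) {
    v <- read_echo_video(manifest$path[r], view = manifest$view[r],
                         subject_id = manifest$subject_id[r],
                         label = manifest$label[r])
    if (!is.null(size)) v <- preprocess_video(v, size = size)
    cl <- extract_clips(v, spec)
    for (ci in cl) {
      clips[[length(clips) + 1]] <- ci$frames
      starts <- c(starts, ci$start)
    }
    labels <- c(labels, rep(manifest$label[r], spec$n))
    subjects <- c(subjects, rep(manifest$subject_id[r], spec$n))
    vws <- c(vws, rep(manifest$view[r], spec$n))
  }
  list(clips = clips, labels = labels, subjects = subjects, views = vws,
       starts = starts)
}
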