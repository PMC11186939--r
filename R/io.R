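#' Write an echo video to disk
#'
#' The lossless path writes the package's archive format: a gzip-compressed
#' stream of raw 8-bit frame bytes (frame-major, row-major within a frame)
#' plus a JSON metadata sidecar at `<path>.json` carrying the dimensions,
#' frame rate, view, subject id and label. The archive is bit-exact, which
#' lossy playback codecs cannot guarantee, and is the canonical format used
#' throughout the package. With `lossless = FALSE` a standard multi-page
#' grayscale TIFF is written instead for interchange with viewers; MP4/AVI
#' export is not provided because no video codec is bundled.
#'
#' @param video an [echo_video()].
#' @param path destination file (conventionally `.nev` for the archive,
#'   `.tif` for TIFF export).
#' @param lossless write the exact archive (default) or a TIFF stack.
#' @return `path`, invisibly.
#' @export
write_echo_video <- function(video, path, lossless = TRUE) {
  validate_echo_video(video)
  if (!dir.exists(dirname(path))) {
    stop(sprintf("cannot write '%s': directory does not exist", path),
         call. = FALSE)
  }
  if (!lossless) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("TIFF export requires the 'tiff' package", call. = FALSE)
    }
    d <- dim(video$frames)
    pages <- lapply(seq_len(d[1]), function(t) {
      matrix(video$frames[t, , ], d[2], d[3]) / 255
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "deflate")
    return(invisible(path))
  }
  d <- dim(video$frames)
  meta <- list(
    format = "neoecho-video", version = 1L,
    T = d[1], H = d[2], W = d[3], fps = video$fps, view = video$view,
    subject_id = video$subject_id
  )
  if (!is.na(video$label)) meta$label <- video$label
  # frame-major layout: aperm so that bytes run W fastest, then H, then T
  bytes <- as.raw(as.integer(aperm(video$frames, c(3, 2, 1))))
  con <- gzfile(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(bytes, con)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read an echo video from disk
#'
#' Reads the lossless archive written by [write_echo_video()] (recognised by
#' its JSON sidecar) or a grayscale/RGB TIFF stack. Color input is reduced to
#' a single luminance channel. Metadata arguments override whatever the
#' container carries; a TIFF stack has no echo metadata, so `view` (and
#' usually `fps`) must be supplied for it.
#'
#' @param path file written by [write_echo_video()] or a TIFF stack.
#' @param view,subject_id,label,fps optional metadata overrides.
#' @return An [echo_video()].
#' @export
read_echo_video <- function(path, view = NULL, subject_id = NULL,
                            label = NULL, fps = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    n <- meta$T * meta$H * meta$W
    con <- gzfile(path, "rb")
    on.exit(close(con), add = TRUE)
    bytes <- readBin(con, "raw", n = n + 1L)
    if (length(bytes) != n) {
      stop(sprintf("corrupt archive '%s': expected %d pixels, found %d",
                   path, n, length(bytes)), call. = FALSE)
    }
    frames <- aperm(array(as.numeric(as.integer(bytes)),
                          c(meta$W, meta$H, meta$T)), c(3, 2, 1))
    return(echo_video(
      frames,
      fps = fps %||% meta$fps,
      view = view %||% meta$view,
      subject_id = subject_id %||% meta$subject_id,
      label = if (!is.null(label)) label else
        if (length(meta$label)) meta$label else NA
    ))
  }
  if (file.size(path) == 0) {
    stop(sprintf("empty file: '%s'", path), call. = FALSE)
  }
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("TIFF import requires the 'tiff' package", call. = FALSE)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      stop(sprintf("cannot decode '%s' as an echo archive or TIFF stack: %s",
                                   path, conditionMessage(e)), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop(sprintf("no frames in '%s'", path), call. = FALSE)
  to_gray <- function(p) {
    if (length(dim(p)) == 3L) {
      p <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
    }
    round(p * 255)
  }
  gray <- lapply(pages, to_gray)
  d <- dim(gray[[1]])
  frames <- array(0, c(length(gray), d[1], d[2]))
  for (t in seq_along(gray)) frames[t, , ] <- gray[[t]]
  echo_video(frames, fps = fps %||% 25, view = view %||% "PSAX-P",
             subject_id = subject_id %||% "anon",
             label = if (is.null(label)) NA else label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a ventricle mask archive
#'
#' Mask stacks use the same gzip + JSON-sidecar archive as videos, with
#' values restricted to `{0, 1}`.
#'
#' @param masks a [mask_sequence()].
#' @param path destination file (conventionally `.msk`).
#' @return `path` invisibly for the writer; a [mask_sequence()] for the reader.
#' @export
write_mask_sequence <- function(masks, path) {
  d <- dim(masks$masks)
  meta <- list(format = "neoecho-mask", version = 1L,
               T = d[1], H = d[2], W = d[3], source = masks$source)
  bytes <- as.raw(as.integer(aperm(masks$masks, c(3, 2, 1))))
  con <- gzfile(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(bytes, con)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_sequence
#' @export
read_mask_sequence <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!identical(meta$format, "neoecho-mask")) {
    stop(sprintf("'%s' is not a mask archive", path), call. = FALSE)
  }
  n <- meta$T * meta$H * meta$W
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  bytes <- readBin(con, "raw", n = n + 1L)
  if (length(bytes) != n) {
    stop(sprintf("corrupt mask archive '%s'", path), call. = FALSE)
  }
  m <- aperm(array(as.integer(bytes), c(meta$W, meta$H, meta$T)), c(3, 2, 1))
  mask_sequence(m, source = meta$source)
}

#' Load and validate a cohort manifest
#'
#' The manifest is a CSV with header `subject_id,view,path,label[,split]`
#' binding each recording to its subject, view, file and 3-level severity
#' label. Relative paths are resolved against the manifest's directory.
#'
#' @param path CSV file.
#' @param check_paths verify that every referenced file exists (default TRUE).
#' @return A `data.frame` of class `cohort_manifest` with columns
#'   `subject_id`, `view`, `path`, `label` and optionally `split`.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("subject_id", "view", "path", "label")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("manifest missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad_view <- which(!df$view %in% echo_views())
  if (length(bad_view)) {
    stop(sprintf("unknown view(s) in manifest row(s) %s: %s",
                 paste(bad_view, collapse = ", "),
                 paste(unique(df$view[bad_view]), collapse = ", ")),
         call. = FALSE)
  }
  lab <- suppressWarnings(as.integer(df$label))
  bad_lab <- which(!(df$label == "" | (!is.na(lab) & lab %in% 0:2)))
  if (length(bad_lab)) {
    stop(sprintf("unparsable label(s) in manifest row(s) %s",
                 paste(bad_lab, collapse = ", ")), call. = FALSE)
  }
  df$label <- ifelse(df$label == "", NA_integer_, lab)
  key <- paste(df$subject_id, df$view, df$path, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate manifest row(s): %s",
                 paste(which(duplicated(key)), collapse = ", ")),
         call. = FALSE)
  }
  key2 <- paste(df$subject_id, df$view, sep = "\r")
  if (anyDuplicated(key2)) {
    stop("each (subject_id, view) pair may appear only once", call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(normalizePath(path)), df$path[rel])
  if (check_paths) {
    gone <- which(!file.exists(df$path))
    if (length(gone)) {
      stop(sprintf("manifest references missing file(s) in row(s) %s",
                   paste(gone, collapse = ", ")), call. = FALSE)
    }
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Save a cohort manifest
#'
#' @param manifest a `cohort_manifest` (or plain data.frame with the same
#'   columns).
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  df$label <- ifelse(is.na(df$label), "", as.character(df$label))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
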