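# Small in-code fixtures shared across test files.

tiny_frames <- function(T = 3, H = 8, W = 8, value = NULL, seed = 1) {
  if (!is.null(value)) return(array(value, c(T, H, W)))
  set.seed(seed)
  array(as.numeric(sample(0:255, T * H * W, replace = TRUE)), c(T, H, W))
}

tiny_video <- function(T = 3, H = 8, W = 8, value = NULL, seed = 1, ...) {
  echo_video(tiny_frames(T, H, W, value, seed), ...)
}

# one rendered recording at test scale, memoised per (severity, seed)
render_small <- local({
  cache <- list()
  function(severity = 0, seed = 1, T = 20, size = 32, view = "PSAX-P") {
    key <- paste(severity, seed, T, size, view)
    if (is.null(cache[[key]])) {
      cfg <- synth_config(T = T, H = size, W = size, severity = severity,
                          seed = seed)
      cache[[key]] <<- render_subject(cfg, view)
    }
    cache[[key]]
  }
})
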