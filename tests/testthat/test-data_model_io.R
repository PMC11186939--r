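test_that("echo_video validates its invariants", {
  expect_s3_class(tiny_video(), "echo_video")
  expect_error(echo_video(array(0, c(3, 8, 8)), view = "PSAXP"),
               "unknown view")
  expect_error(echo_video(array(-1, c(3, 8, 8))), "\\[0, 255\\]")
  expect_error(echo_video(array(0, c(3, 4, 8))), "at least 8 x 8")
  expect_error(echo_video(array(0, c(3, 8, 8)), label = 5), "label")
  expect_error(echo_video(matrix(0, 8, 8)), "T x H x W")
})

test_that("color input is reduced to a luminance channel", {
  col <- array(0, c(2, 8, 8, 3))
  col[, , , 1] <- 255   # pure red
  v <- echo_video(col)
  expect_identical(dim(v$frames), c(2L, 8L, 8L))
  expect_true(all(v$frames == round(0.299 * 255)))
})

test_that("lossless archive round-trips bit for bit", {
  dir <- withr::local_tempdir()
  set.seed(42)
  for (i in 1:5) {
    v <- tiny_video(T = sample(1:6, 1), H = 8 + i, W = 8 + 2 * i, seed = i,
                    fps = 25, view = sample(echo_views(), 1),
                    subject_id = paste0("S", i), label = sample(0:2, 1))
    p <- file.path(dir, sprintf("v%d.nev", i))
    write_echo_video(v, p)
    r <- read_echo_video(p)
    expect_identical(r$frames, v$frames)
    expect_identical(r$fps, v$fps)
    expect_identical(r$view, v$view)
    expect_identical(r$subject_id, v$subject_id)
    expect_identical(r$label, v$label)
  }
  # all-zero frames survive too
  z <- tiny_video(value = 0)
  p <- file.path(dir, "zero.nev")
  write_echo_video(z, p)
  expect_true(all(read_echo_video(p)$frames == 0))
})

test_that("archive duration metadata is consistent with fps", {
  dir <- withr::local_tempdir()
  v <- tiny_video(T = 122, H = 8, W = 8, value = 7, fps = 25)
  p <- file.path(dir, "dur.nev")
  write_echo_video(v, p)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(meta$T / meta$fps, 4.88)
})

test_that("read errors are informative", {
  expect_error(read_echo_video("/nonexistent/file.nev"), "not found")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "empty.nev")
  file.create(p)
  expect_error(read_echo_video(p), "empty file")
})

test_that("TIFF stacks import with luminance reduction", {
  skip_if_not_installed("tiff")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rgb.tif")
  pages <- lapply(1:3, function(i) {
    a <- array(0, c(8, 8, 3)); a[, , 2] <- i / 10; a
  })
  tiff::writeTIFF(pages, p, bits.per.sample = 8L)
  v <- read_echo_video(p, view = "A4C", fps = 30)
  expect_identical(dim(v$frames), c(3L, 8L, 8L))
  expect_equal(v$view, "A4C")
  # luminance of pure green at 0.1 -> round(0.587 * round(0.1*255))
  expect_true(all(v$frames[1, , ] == round(0.587 * round(0.1 * 255) / 255 * 255)))
})

test_that("mask archives round-trip and validate", {
  dir <- withr::local_tempdir()
  set.seed(9)
  m <- mask_sequence(array(rbinom(3 * 8 * 8, 1, 0.3), c(3, 8, 8)),
                     source = "synthetic")
  p <- file.path(dir, "m.msk")
  write_mask_sequence(m, p)
  r <- read_mask_sequence(p)
  expect_identical(r$masks, m$masks)
  expect_identical(r$source, "synthetic")
  expect_error(mask_sequence(array(2, c(2, 4, 4))), "0 or 1")
})

test_that("manifest load validates and round-trips", {
  dir <- withr::local_tempdir()
  for (i in 1:3) {
    write_echo_video(tiny_video(seed = i), file.path(dir, sprintf("v%d.nev", i)))
  }
  df <- data.frame(subject_id = c("a", "b", "c"),
                   view = c("PSAX-P", "PLAX", "A4C"),
                   path = sprintf("v%d.nev", 1:3),
                   label = c(0, 1, 2))
  p <- file.path(dir, "manifest.csv")
  save_manifest(df, p)
  m <- load_manifest(p)
  expect_equal(nrow(m), 3)
  expect_equal(length(unique(m$subject_id)), 3)
  expect_identical(m$label, c(0L, 1L, 2L))
  # idempotent through save/load
  p2 <- file.path(dir, "again.csv")
  m2 <- m; m2$path <- basename(m2$path)
  save_manifest(m2, p2)
  expect_identical(as.data.frame(load_manifest(p2))[, 1:4],
                   as.data.frame(m)[, 1:4])

  bad <- df; bad$view[2] <- "PSAXP"
  save_manifest(bad, p)
  expect_error(load_manifest(p), "unknown view")
  dup <- rbind(df, df[1, ])
  save_manifest(dup, p)
  expect_error(load_manifest(p), "duplicate")
  badlab <- df; badlab$label <- c("0", "seven", "2")
  save_manifest(badlab, p)
  expect_error(load_manifest(p), "label")
})

test_that("clinical pressure estimates follow the screening formulas", {
  expect_equal(estimate_spap(0, 5), 5)
  expect_equal(estimate_spap(3.0, 5), 41)
  expect_equal(estimate_spap(2.5, 10), 35)
  expect_equal(estimate_mpap(0), 2)
  expect_equal(estimate_mpap(30), 20.3)
  expect_equal(estimate_mpap(estimate_spap(3.0, 5)), 27.01)
  expect_error(estimate_spap(-1, 0), "TRV")
  expect_error(estimate_mpap(-0.1), "sPAP")
})

test_that("pressure estimates are monotone and bounded below", {
  trv <- seq(0, 5, by = 0.25)
  rap <- seq(0, 20, by = 2.5)
  grid <- expand.grid(trv = trv, rap = rap)
  sp <- estimate_spap(grid$trv, grid$rap)
  expect_true(all(sp >= grid$rap))
  expect_true(all(diff(estimate_spap(trv, 5)) > 0))
  expect_true(all(diff(estimate_spap(2, rap)) > 0))
  expect_true(all(diff(estimate_mpap(seq(0, 100, 5))) > 0))
})
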