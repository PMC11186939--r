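test_that("rendered recordings have the configured shape and metadata", {
  cfg <- synth_config(T = 122, H = 64, W = 64, seed = 1)
  r <- render_subject(cfg, "PSAX-P")
  expect_identical(dim(r$video$frames), c(122L, 64L, 64L))
  expect_identical(dim(r$masks$masks), dim(r$video$frames))
  expect_equal(r$video$fps, 25)
  expect_equal(r$video$label, 0L)
  expect_length(r$phase, 122)
  expect_true(all(r$phase >= 0 & r$phase < 1))
  expect_error(synth_config(severity = 3), "severity")
  expect_error(synth_config(T = 5, heartbeat_period = 10), "T must be")
})

test_that("identical seeds give identical recordings", {
  cfg <- synth_config(T = 15, H = 32, W = 32, severity = 1, seed = 99)
  a <- render_subject(cfg, "PLAX")
  b <- render_subject(cfg, "PLAX")
  expect_identical(a$video$frames, b$video$frames)
  expect_identical(a$masks$masks, b$masks$masks)
})

test_that("ventricle area is minimal exactly at generated systole", {
  r <- render_small(severity = 1, seed = 4, T = 30)
  areas <- relative_ventricle_area(r$masks)
  p <- 10  # heartbeat period
  for (cycle in 0:2) {
    idx <- cycle * p + seq_len(p)
    expect_equal(which.min(areas[idx]), 1)  # phase 0 frame of each cycle
    expect_equal(r$phase[idx[1]], 0)
  }
})

test_that("septal displacement flips sign between severity 0 and 2", {
  r0 <- render_small(severity = 0, seed = 7)
  r2 <- render_small(severity = 2, seed = 7)
  # at systole the severe LV loses its left (septal) side: the severity-2
  # LV starts strictly to the right of the severity-0 LV
  left_edge <- function(r) min(which(colSums(r$lv[1, , ]) > 0))
  expect_gt(left_edge(r2), left_edge(r0))
  # and the severe RV gains the room the LV lost
  expect_gt(sum(r2$rv[1, , ]), sum(r0$rv[1, , ]))
})

test_that("systolic LV circularity separates the three severities", {
  set.seed(5)
  circ <- sapply(0:2, function(sev) sapply(1:6, function(i) {
    cfg <- synth_config(T = 12, H = 64, W = 64, severity = sev,
                        seed = 31 * i + sev,
                        size_scale = runif(1, 0.92, 1.08),
                        rotation = runif(1, -5, 5),
                        brightness = runif(1, 0.9, 1.1),
                        center_dx = runif(1, -0.02, 0.02),
                        center_dy = runif(1, -0.02, 0.02))
    lv_circularity(render_subject(cfg, "PSAX-P")$lv)
  }))
  # perfect separation: ranges do not overlap, ordered none > mild > severe
  expect_gt(min(circ[, 1]), max(circ[, 2]))
  expect_gt(min(circ[, 2]), max(circ[, 3]))
})

test_that("generate_cohort writes archives, masks and a valid manifest", {
  dir <- withr::local_tempdir()
  man <- generate_cohort(dir, n_subjects = 12, class_counts = c(8, 2, 2),
                         seed = 3,
                         config = synth_config(T = 12, H = 32, W = 32))
  expect_equal(nrow(man), 12)
  expect_equal(length(unique(man$subject_id)), 12)
  expect_equal(sort(table(man$label)), sort(table(c(rep(0, 8), 1, 1, 2, 2))))
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(mask_path_for(man$path))))
  v <- read_echo_video(man$path[1])
  m <- read_mask_sequence(mask_path_for(man$path[1]))
  expect_identical(dim(v$frames), dim(m$masks))
  expect_error(generate_cohort(dir, 10, class_counts = c(5, 5, 5)),
               "sums to")
})

test_that("cohort generation is deterministic given the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- synth_config(T = 10, H = 32, W = 32)
  generate_cohort(d1, 3, c(1, 1, 1), seed = 11, config = cfg)
  generate_cohort(d2, 3, c(1, 1, 1), seed = 11, config = cfg)
  for (f in list.files(d1, pattern = "\\.nev$")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("default class counts reproduce the cohort prevalence", {
  counts <- neoecho:::largest_remainder(192, c(0.65, 0.17, 0.18))
  expect_equal(sum(counts), 192)
  # the 126/32/34 reference cohort prints as approximately 65/17/18%
  expect_true(all(abs(100 * c(126, 32, 34) / 192 - c(65, 17, 18)) < 1))
  expect_equal(round(100 * counts / 192), c(65, 17, 18))
})
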