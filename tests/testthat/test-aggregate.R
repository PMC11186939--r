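# independent count-and-argmax oracle with the same tie rules
oracle_vote <- function(labels) {
  best_lab <- -1; best_count <- -1
  for (lb in unique(labels)) {
    cnt <- sum(labels == lb)
    if (cnt > best_count || (cnt == best_count && lb > best_lab)) {
      best_lab <- lb; best_count <- cnt
    }
  }
  list(label = best_lab, count = best_count)
}

oracle_subject <- function(labs, confs) {
  counts <- sapply(sort(unique(labs)), function(lb) sum(labs == lb))
  names(counts) <- sort(unique(labs))
  tied <- as.numeric(names(counts)[counts == max(counts)])
  if (length(tied) == 1) return(tied)
  best <- sapply(tied, function(lb) max(confs[labs == lb]))
  cand <- tied[best == max(best)]
  max(cand)
}

test_that("majority vote matches hand-worked cases and tie rule", {
  expect_equal(majority_vote(c(0, 0, 1)), list(label = 0, count = 2L))
  expect_equal(majority_vote(c(2, 2, 2)), list(label = 2, count = 3L))
  expect_equal(majority_vote(c(0, 0, 2, 2)), list(label = 2, count = 2L))
  expect_error(majority_vote(c()), "nonempty")
})

test_that("view aggregation reports the confidence statistic exactly", {
  b <- aggregate_view(c(rep(1, 9), 0))
  expect_equal(b$label, 1)
  expect_equal(b$confidence, 0.9)
  expect_equal(aggregate_view(rep(2, 7))$confidence, 1.0)
  tie3 <- aggregate_view(c(0, 1, 2))
  expect_equal(tie3$label, 2)
  expect_equal(tie3$confidence, 1 / 3)
  # C is exactly the fraction of clips agreeing with the view label
  set.seed(31)
  for (i in 1:50) {
    labs <- sample(0:2, sample(1:15, 1), replace = TRUE)
    b <- aggregate_view(labs)
    expect_equal(b$confidence, mean(labs == b$label))
  }
})

test_that("subject aggregation follows the confidence tie-break", {
  mk <- function(lab, conf) {
    structure(list(label = lab, confidence = conf, modal_count = 1, n = 1),
              class = "prediction_bundle")
  }
  s <- aggregate_subject(list("PSAX-P" = mk(2, 0.9), "PLAX" = mk(0, 0.6),
                              "A4C" = mk(0, 0.7)))
  expect_equal(s$label, 0)    # 2 votes vs 1
  tie <- aggregate_subject(list(a = mk(1, 0.9), b = mk(1, 0.5),
                                c = mk(2, 0.8), d = mk(2, 0.7)))
  expect_equal(tie$label, 1)  # max confidence 0.9 backs label 1
  expect_equal(tie$confidence, 0.9)
  single <- aggregate_subject(list(PLAX = mk(1, 0.4)))
  expect_equal(single$label, 1)
  expect_equal(single$winning_view, "PLAX")
  exact <- aggregate_subject(list(a = mk(0, 0.8), b = mk(2, 0.8)))
  expect_equal(exact$label, 2) # exact confidence tie -> higher severity
})

test_that("aggregation agrees with the brute-force oracle", {
  set.seed(77)
  for (i in 1:1500) {
    labs <- sample(0:2, sample(1:12, 1), replace = TRUE)
    mv <- majority_vote(labs)
    ov <- oracle_vote(labs)
    expect_equal(mv$label, ov$label)
    expect_equal(mv$count, ov$count)

    nv <- sample(1:5, 1)
    vl <- sample(0:2, nv, replace = TRUE)
    vc <- round(runif(nv), 2)
    bundles <- lapply(seq_len(nv), function(j) {
      structure(list(label = vl[j], confidence = vc[j]),
                class = "prediction_bundle")
    })
    expect_equal(aggregate_subject(bundles)$label, oracle_subject(vl, vc))
  }
})

test_that("aggregation is invariant to clip and view order", {
  set.seed(13)
  for (i in 1:100) {
    labs <- sample(0:2, 9, replace = TRUE)
    perm <- sample(9)
    expect_equal(aggregate_view(labs)$label, aggregate_view(labs[perm])$label)
    expect_equal(aggregate_view(labs)$confidence,
                 aggregate_view(labs[perm])$confidence)
    vl <- sample(0:2, 4, replace = TRUE)
    vc <- runif(4)
    bundles <- lapply(1:4, function(j) {
      structure(list(label = vl[j], confidence = vc[j]),
                class = "prediction_bundle")
    })
    pm <- sample(4)
    expect_equal(aggregate_subject(bundles)$label,
                 aggregate_subject(bundles[pm])$label)
  }
})

test_that("winning-view probabilities propagate for multi-view AUROC", {
  probs <- matrix(c(0.7, 0.2, 0.1,
                    0.6, 0.3, 0.1), 2, 3, byrow = TRUE)
  b1 <- aggregate_view(c(0, 0), clip_probs = probs)
  expect_equal(sum(b1$prob), 1)
  b2 <- aggregate_view(c(2, 2), clip_probs = matrix(c(0.1, 0.1, 0.8,
                                                      0.2, 0.2, 0.6),
                                                    2, 3, byrow = TRUE))
  s <- aggregate_subject(list(A = b1, B = b2, C = b2))
  expect_equal(s$label, 2)
  expect_equal(s$prob, b2$prob)
})
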