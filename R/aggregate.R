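#' Majority vote over predicted labels
#'
#' Returns the most frequently predicted label and its multiplicity. Ties
#' among modal labels are broken toward the higher severity — clinically
#' conservative, preferring to flag disease.
#'
#' @param labels nonempty vector of class labels.
#' @return List with `label` and `count`.
#' @export
majority_vote <- function(labels) {
  if (length(labels) == 0) stop("labels must be nonempty", call. = FALSE)
  tab <- table(labels)
  top <- max(tab)
  winners <- as.numeric(names(tab)[tab == top])
  list(label = max(winners), count = as.integer(top))
}

#' Aggregate clip predictions to a view-level prediction
#'
#' Majority vote over the clip labels of one recording, with the view-level
#' confidence `C = y_star / n`: the fraction of clips agreeing with the
#' modal label.
#'
#' @param clip_labels predicted labels of the `n` clips (or frames) of one
#'   view.
#' @param clip_probs optional `n x num_classes` matrix of per-clip class
#'   probabilities; its rows supporting the winning label are averaged into
#'   the bundle's `prob` slot (used for view-level AUROC).
#' @return A `prediction_bundle`: `label`, `modal_count`, `confidence`,
#'   `n`, `clip_labels` and optionally `prob`.
#' @export
aggregate_view <- function(clip_labels, clip_probs = NULL) {
  mv <- majority_vote(clip_labels)
  bundle <- list(label = mv$label, modal_count = mv$count,
                 confidence = mv$count / length(clip_labels),
                 n = length(clip_labels), clip_labels = clip_labels)
  if (!is.null(clip_probs)) {
    sup <- which(clip_labels == mv$label)
    p <- colMeans(clip_probs[sup, , drop = FALSE])
    bundle$prob <- p / sum(p)
  }
  structure(bundle, class = "prediction_bundle")
}

#' @export
print.prediction_bundle <- function(x, ...) {
  cat(sprintf("<prediction_bundle> label %s (%d/%d clips, C = %.2f)\n",
              x$label, x$modal_count, x$n, x$confidence))
  invisible(x)
}

#' Aggregate view-level predictions to a subject-level prediction
#'
#' Majority vote over the available views' labels. On a tie, the tied label
#' whose supporting views contain the single highest confidence wins; if
#' those confidences tie exactly, the higher severity wins. Missing views
#' are simply absent from the vote. The winning confidence and the most
#' confident supporting view are reported; the latter's probabilities are
#' what multi-view AUROC is computed from.
#'
#' @param view_bundles named list (by view) of `prediction_bundle`s from
#'   [aggregate_view()].
#' @return A `subject_prediction`: `label`, `confidence`, `winning_view`,
#'   `view_labels` and, when the winning bundle carries probabilities,
#'   `prob`.
#' @export
aggregate_subject <- function(view_bundles) {
  if (length(view_bundles) == 0) {
    stop("at least one view bundle is required", call. = FALSE)
  }
  labs <- vapply(view_bundles, function(b) as.numeric(b$label), numeric(1))
  confs <- vapply(view_bundles, function(b) b$confidence, numeric(1))
  tab <- table(labs)
  top <- max(tab)
  tied <- as.numeric(names(tab)[tab == top])
  if (length(tied) == 1L) {
    winner <- tied
  } else {
    best <- vapply(tied, function(lb) max(confs[labs == lb]), numeric(1))
    cand <- tied[best == max(best)]
    winner <- max(cand)       # residual exact-confidence tie: higher severity
  }
  sup <- which(labs == winner)
  best_view <- sup[which.max(confs[sup])]
  out <- list(label = winner,
              confidence = unname(confs[best_view]),
              winning_view = names(view_bundles)[best_view] %||%
                as.character(best_view),
              view_labels = labs)
  if (!is.null(view_bundles[[best_view]]$prob)) {
    out$prob <- view_bundles[[best_view]]$prob
  }
  structure(out, class = "subject_prediction")
}

#' @export
print.subject_prediction <- function(x, ...) {
  cat(sprintf("<subject_prediction> label %s (view %s, C = %.2f)\n",
              x$label, x$winning_view, x$confidence))
  invisible(x)
}
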