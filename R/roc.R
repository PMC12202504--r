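#' Empirical ROC curve with Youden cut-off
#'
#' Builds the empirical ROC curve of a continuous marker against binary
#' labels. Candidate cut-points are placed at midpoints between adjacent
#' distinct scores (plus open ends), the area under the curve is the pairwise
#' concordance probability with ties counted 1/2 (identical to the
#' trapezoidal area over the empirical curve), and the optimal cut-off
#' maximises Youden's index, sensitivity + specificity - 1. Among cut-offs
#' attaining the maximal index the one with the highest specificity is
#' reported.
#'
#' `direction = "greater"` treats high scores as predicting the event (test
#' positive when `score > cutoff`); `direction = "lesser"` treats low scores
#' as predicting it (positive when `score <= cutoff`), as appropriate for
#' markers that fall in cases.
#'
#' @param scores numeric marker values.
#' @param labels event indicator: logical, 0/1, or a factor whose first level
#'   is the positive class.
#' @param direction `"greater"` (default) or `"lesser"`.
#' @return An object of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity` (per threshold), `auc`, `direction`, `youden_cutoff`,
#'   `youden_sensitivity`, `youden_specificity`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, direction = c("greater", "lesser")) {
  direction <- match.arg(direction)
  pos <- as_positive(labels)
  stopifnot(length(scores) == length(pos))
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to build an ROC curve")

  # AUC as pairwise concordance via the rank-sum identity (ties -> 1/2)
  r <- rank(scores)
  auc_greater <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  auc <- if (direction == "greater") auc_greater else 1 - auc_greater

  u <- sort(unique(scores))
  mids <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  thr <- c(u[1] - 1, mids, u[length(u)] + 1)
  if (direction == "greater") {
    sens <- vapply(thr, function(t) mean(scores[pos] > t), numeric(1))
    spec <- vapply(thr, function(t) mean(scores[!pos] <= t), numeric(1))
  } else {
    sens <- vapply(thr, function(t) mean(scores[pos] <= t), numeric(1))
    spec <- vapply(thr, function(t) mean(scores[!pos] > t), numeric(1))
  }
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, direction = direction,
                 youden_cutoff = thr[best],
                 youden_sensitivity = sens[best],
                 youden_specificity = spec[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(labels == 1)
  }
  f <- as.factor(labels)
  stopifnot(nlevels(f) == 2L)
  f == levels(f)[1]
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC (%s-is-positive): AUC = %.3f (%d pos / %d neg)\n",
              x$direction, x$auc, x$n_pos, x$n_neg))
  op <- if (x$direction == "greater") ">" else "<="
  cat(sprintf("Youden cut-off: score %s %.4g (sens %.3f, spec %.3f)\n",
              op, x$youden_cutoff, x$youden_sensitivity,
              x$youden_specificity))
  invisible(x)
}

#' Analytic AUC for two Gaussian score distributions
#'
#' When positive and negative scores are Gaussian, the ROC area has the
#' closed form `pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))`. This
#' bridges published group summaries (mean and SD per group) to an expected
#' AUC without patient-level data.
#'
#' @param mu_pos,sd_pos mean and SD of the positive class.
#' @param mu_neg,sd_neg mean and SD of the negative class.
#' @return The AUC (greater-is-positive convention).
#' @export
binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  stopifnot(sd_pos > 0, sd_neg > 0)
  stats::pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}
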