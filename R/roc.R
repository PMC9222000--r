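# ROC analysis and optimal-cutoff selection for the discriminant score.

#' ROC curve of a score against binary class labels
#'
#' Thresholds are placed at the midpoints between adjacent distinct score
#' values plus -Inf and +Inf; at each threshold a sample is called positive
#' (high grade) when its score is at least the threshold. AUC is computed by
#' the trapezoidal rule over (1 - specificity, sensitivity).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels class labels; `positive` names the positive class.
#' @param positive the positive-class label (default: `"high"`, or the
#'   second factor level when labels are a factor).
#' @return object of class `nm_roc`: data.frame `curve` (threshold,
#'   sensitivity, specificity), `auc`, and the inputs.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  stopifnot_finite(scores, "scores")
  if (is.null(positive)) {
    positive <- if (is.factor(labels)) levels(labels)[nlevels(labels)] else "high"
  }
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  # trapezoid over the ROC polyline ordered by increasing threshold
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(sens)]) / 2)
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 auc = auc, positive = positive),
            class = "nm_roc")
}

#' @export
print.nm_roc <- function(x, ...) {
  cat(sprintf("<nm_roc> AUC = %.4f over %d thresholds\n", x$auc,
              nrow(x$curve)))
  invisible(x)
}

#' Youden-optimal cutoff from a ROC result
#'
#' Returns the threshold maximising Youden's J = sensitivity + specificity
#' - 1; ties are broken toward the threshold with higher specificity (and,
#' among those, the larger threshold).
#'
#' @param roc an `nm_roc` from [roc_curve()].
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
pick_cutoff <- function(roc) {
  stopifnot(inherits(roc, "nm_roc"))
  cv <- roc$curve
  j <- cv$sensitivity + cv$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1L) {
    best <- best[order(-cv$specificity[best], -cv$threshold[best])][1]
  }
  list(cutoff = cv$threshold[best],
       sensitivity = cv$sensitivity[best],
       specificity = cv$specificity[best],
       youden_j = j[best])
}
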