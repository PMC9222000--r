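# The multivariate stage: a 7-variable linear discriminant score, forward
# stepwise (Wilks' lambda) variable selection, ROC analysis with
# Youden-optimal cutoff, and binary low- vs high-grade classification.

#' Construct a discriminant-score model
#'
#' @param intercept score-units intercept.
#' @param coefficients named numeric vector of per-feature weights.
#' @param cutoff decision threshold in score units.
#' @param orientation `"higher_is_high_grade"` (the only supported
#'   convention): scores at or above the cutoff classify as high grade.
#' @return object of class `nm_discriminant`.
#' @export
nm_discriminant <- function(intercept, coefficients, cutoff,
                            orientation = "higher_is_high_grade") {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    stop("coefficients must be named", call. = FALSE)
  }
  stopifnot_finite(intercept, "intercept")
  stopifnot_finite(coefficients, "coefficients")
  stopifnot_finite(cutoff, "cutoff")
  orientation <- match.arg(orientation, "higher_is_high_grade")
  structure(list(intercept = intercept,
                 coefficients = coefficients,
                 cutoff = cutoff,
                 orientation = orientation),
            class = "nm_discriminant")
}

#' The published 7-variable discriminant-score model
#'
#' Full-precision intercept and weights of the published prostate-cancer
#' grading score over minimal radius, fractal dimension, minimal/maximal
#' gray level, margination and green/blue channel gray levels, with its
#' ROC-derived cutoff of -1.1134. Scores at or above the cutoff indicate
#' high-grade (Gleason >= 4) disease: evaluated at the published per-grade
#' feature means the score falls below the cutoff for grades 1-3 and above
#' it for grades 4 and 5, which fixes the orientation.
#'
#' @return an [nm_discriminant()] model.
#' @examples
#' ds_score(c(radius_min = 0, fractal_dimension = 0, gray_min = 0,
#'            gray_max = 0, margination = 0, gray_green = 0, gray_blue = 0),
#'          paper_model())
#' @export
paper_model <- function() {
  nm_discriminant(
    intercept = 1331.50420234964,
    coefficients = c(radius_min = 5.95568628644,
                     fractal_dimension = -1479.27930311731,
                     gray_min = 0.40274897061,
                     gray_max = 0.53105523026,
                     margination = 275.38324653827,
                     gray_green = -0.89343166330,
                     gray_blue = 0.51289341737),
    cutoff = -1.1134)
}

#' @export
print.nm_discriminant <- function(x, ...) {
  cat(sprintf("<nm_discriminant> %d features, cutoff %.4f (%s)\n",
              length(x$coefficients), x$cutoff, x$orientation))
  print(round(c(`(intercept)` = x$intercept, x$coefficients), 5))
  invisible(x)
}

#' Evaluate the discriminant score
#'
#' `DS = intercept + sum(coefficient * feature)`. Inputs must carry every
#' model feature with a finite value; nothing is imputed.
#'
#' @param features named numeric vector, or data.frame with one column per
#'   model feature (one score per row).
#' @param model an `nm_discriminant` (default: [paper_model()]).
#' @return numeric score(s).
#' @export
ds_score <- function(features, model = paper_model()) {
  need <- names(model$coefficients)
  if (is.data.frame(features)) {
    miss <- setdiff(need, names(features))
    if (length(miss)) {
      stop("missing feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    X <- as.matrix(features[need])
  } else {
    miss <- setdiff(need, names(features))
    if (length(miss)) {
      stop("missing feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    X <- matrix(features[need], nrow = 1,
                dimnames = list(NULL, need))
  }
  if (any(!is.finite(X))) {
    bad <- need[apply(!is.finite(X), 2, any)]
    stop("non-finite value for feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  drop(model$intercept + X %*% model$coefficients[need])
}

#' Classify a discriminant score into low vs high grade
#'
#' Scores at or above the model cutoff are called `high_grade_G45` (ties go
#' to high grade, favouring sensitivity for the clinically risky class);
#' lower scores are `low_grade_G13`.
#'
#' @param score numeric score(s) from [ds_score()].
#' @param model an `nm_discriminant`.
#' @return factor with levels `low_grade_G13`, `high_grade_G45`.
#' @export
classify_ds <- function(score, model = paper_model()) {
  stopifnot_finite(score, "score")
  factor(ifelse(score >= model$cutoff, "high_grade_G45", "low_grade_G13"),
         levels = c("low_grade_G13", "high_grade_G45"))
}
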