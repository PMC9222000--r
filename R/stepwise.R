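# Forward stepwise variable selection for a two-class linear discriminant,
# with Wilks' lambda entry/removal (the classical stepwise discriminant
# procedure) and an optional logistic-regression Wald variant.

# Wilks' lambda for a feature subset: det(W)/det(T), where W and T are the
# within-group and total SSCP matrices of the selected columns.
wilks_lambda <- function(X, g) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  T_mat <- crossprod(Xc)
  W_mat <- matrix(0, ncol(X), ncol(X))
  for (l in levels(g)) {
    Xl <- X[g == l, , drop = FALSE]
    Xl <- scale(Xl, center = TRUE, scale = FALSE)
    W_mat <- W_mat + crossprod(Xl)
  }
  if (rcond(T_mat) < 1e-12 || rcond(W_mat) < 1e-12) return(NA_real_)
  dT <- det(T_mat); dW <- det(W_mat)
  if (!is.finite(dT) || dT <= 0) return(NA_real_)
  dW / dT
}

# Partial F for changing the subset from lambda_old (p variables) to
# lambda_new (p + 1 variables), g groups, n observations.
partial_f <- function(lambda_old, lambda_new, n, n_groups, p_old) {
  if (!is.finite(lambda_new) || lambda_new <= 0) return(c(F = NA, p = NA))
  Fv <- ((n - n_groups - p_old) / (n_groups - 1)) *
    (lambda_old / lambda_new - 1)
  if (!is.finite(Fv) || Fv < 0) return(c(F = NA, p = NA))
  pv <- stats::pf(Fv, n_groups - 1, n - n_groups - p_old, lower.tail = FALSE)
  c(F = Fv, p = pv)
}

#' Forward stepwise discriminant model fit (low vs high grade)
#'
#' Selects features for a two-class linear discriminant by forward stepwise
#' search: at each step the candidate that minimises Wilks' lambda enters if
#' its partial-F p-value is at most `enter_p`; after every entry, any
#' selected variable whose partial-F p-value (for removal) exceeds
#' `remove_p` leaves again. The procedure stops when no entry or removal
#' changes the set. Candidates that would make the within-class covariance
#' singular (e.g. exact duplicates of a selected variable) are skipped with
#' a warning.
#'
#' The returned weights are the Fisher discriminant direction
#' `W^{-1}(mu_high - mu_low)` rescaled so the pooled within-class variance of
#' the score is 1, oriented so high-grade samples score higher; the
#' intercept centres the midpoint of the two class means at zero.
#'
#' With `method = "wald"` the selection criterion is instead the Wald test
#' of each candidate coefficient in a binomial logistic regression
#' (sensitivity-analysis variant); the final weights are still the Fisher
#' direction over the selected set.
#'
#' @param records `sample_records` (or any data.frame of per-sample feature
#'   means with a `grade_group` column).
#' @param candidates character vector of candidate feature names.
#' @param enter_p,remove_p entry / removal p-value thresholds
#'   (defaults 0.05 / 0.10).
#' @param method `"wilks"` (default) or `"wald"`.
#' @param high_grades grade labels forming the positive (high-grade) class.
#' @return an [nm_discriminant()] with an extra `selection` attribute
#'   recording the step history. The cutoff is set to 0 (class midpoint);
#'   refine it with [pick_cutoff()] on training scores.
#' @export
fit_stepwise <- function(records, candidates,
                         enter_p = 0.05, remove_p = 0.10,
                         method = c("wilks", "wald"),
                         high_grades = c("G4", "G5")) {
  method <- match.arg(method)
  cls <- factor(ifelse(records$grade_group %in% high_grades, "high", "low"),
                levels = c("low", "high"))
  if (nlevels(droplevels(cls)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  candidates <- candidates[vapply(candidates, function(f) {
    v <- records[[f]]
    !is.null(v) && all(is.finite(v)) && stats::sd(v) > 0
  }, logical(1))]
  if (!length(candidates)) stop("no usable candidate features", call. = FALSE)

  X_all <- as.matrix(records[candidates])
  n <- nrow(X_all)
  selected <- character(0)
  history <- list()

  entry_p_value <- function(cand, selected) {
    cols <- c(selected, cand)
    X <- X_all[, cols, drop = FALSE]
    if (method == "wilks") {
      l_new <- wilks_lambda(X, cls)
      l_old <- if (length(selected)) {
        wilks_lambda(X_all[, selected, drop = FALSE], cls)
      } else 1
      pf <- partial_f(l_old, l_new, n, 2L, length(selected))
      list(p = pf["p"], crit = l_new)
    } else {
      df <- data.frame(.cls = cls, X, check.names = FALSE)
      fit <- suppressWarnings(stats::glm(.cls ~ ., data = df,
                                         family = stats::binomial()))
      co <- summary(fit)$coefficients
      if (!cand %in% rownames(co)) return(list(p = NA_real_, crit = NA_real_))
      list(p = co[cand, "Pr(>|z|)"], crit = co[cand, "Pr(>|z|)"])
    }
  }

  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      ev <- lapply(pool, entry_p_value, selected = selected)
      crit <- vapply(ev, function(e) as.numeric(e$crit), numeric(1))
      pv <- vapply(ev, function(e) as.numeric(e$p), numeric(1))
      usable <- is.finite(crit) & is.finite(pv)
      if (any(usable)) {
        best <- which(usable)[which.min(crit[usable])]
        if (pv[best] <= enter_p) {
          selected <- c(selected, pool[best])
          history[[length(history) + 1L]] <-
            list(action = "enter", feature = pool[best], p = pv[best])
          changed <- TRUE
        }
      }
    }
    # removal pass
    if (length(selected) > 1L) {
      repeat {
        rem_p <- vapply(selected, function(f) {
          keep <- setdiff(selected, f)
          if (method == "wilks") {
            l_old <- if (length(keep)) {
              wilks_lambda(X_all[, keep, drop = FALSE], cls)
            } else 1
            l_new <- wilks_lambda(X_all[, selected, drop = FALSE], cls)
            as.numeric(partial_f(l_old, l_new, n, 2L, length(keep))["p"])
          } else {
            df <- data.frame(.cls = cls, X_all[, selected, drop = FALSE],
                             check.names = FALSE)
            fit <- suppressWarnings(stats::glm(.cls ~ ., data = df,
                                               family = stats::binomial()))
            co <- summary(fit)$coefficients
            if (!f %in% rownames(co)) NA_real_ else co[f, "Pr(>|z|)"]
          }
        }, numeric(1))
        worst <- which.max(rem_p)
        if (length(worst) && is.finite(rem_p[worst]) &&
            rem_p[worst] > remove_p) {
          history[[length(history) + 1L]] <-
            list(action = "remove", feature = selected[worst],
                 p = rem_p[worst])
          selected <- selected[-worst]
          changed <- TRUE
          if (length(selected) <= 1L) break
        } else break
      }
    }
    if (!changed) break
  }
  if (!length(selected)) {
    stop("no discriminative features: no candidate passed the entry test",
         call. = FALSE)
  }

  X <- X_all[, selected, drop = FALSE]
  mu_low <- colMeans(X[cls == "low", , drop = FALSE])
  mu_high <- colMeans(X[cls == "high", , drop = FALSE])
  W <- matrix(0, ncol(X), ncol(X))
  for (l in levels(cls)) {
    Xl <- scale(X[cls == l, , drop = FALSE], center = TRUE, scale = FALSE)
    W <- W + crossprod(Xl)
  }
  Sw <- W / (n - 2)
  w <- tryCatch(solve(Sw, mu_high - mu_low), error = function(e) {
    solve(Sw + diag(1e-8 * mean(diag(Sw)), ncol(Sw)), mu_high - mu_low)
  })
  s2 <- drop(t(w) %*% Sw %*% w)
  if (s2 > 0) w <- w / sqrt(s2)
  if (sum(w * (mu_high - mu_low)) < 0) w <- -w  # high grade scores higher
  names(w) <- selected
  intercept <- -sum(w * (mu_low + mu_high) / 2)
  model <- nm_discriminant(intercept = intercept, coefficients = w,
                           cutoff = 0)
  attr(model, "selection") <- history
  model
}
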