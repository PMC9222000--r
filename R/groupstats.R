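# Sample-level aggregation and the univariate screening stage: one-way ANOVA
# across the three Gleason groups with Bonferroni-corrected pairwise tests.

#' Aggregate a per-nucleus feature table to per-sample records
#'
#' Each biopsy sample is summarised by the arithmetic mean of every
#' descriptor over its nuclei (missing values dropped per feature), plus the
#' nucleus count. A sample id carrying more than one grade label is an error;
#' samples with zero valid nuclei are excluded with a message.
#'
#' @param table data.frame from [extract_table()] (columns `sample_id`,
#'   `grade_group`, descriptors).
#' @return data.frame of class `sample_records`: one row per sample with
#'   `sample_id`, `grade_group`, `n_nuclei` and per-feature means.
#' @export
aggregate_samples <- function(table) {
  stopifnot(all(c("sample_id", "grade_group") %in% names(table)))
  feat <- setdiff(names(table), c("sample_id", "nucleus_id", "grade_group"))
  split_tab <- split(table, table$sample_id)
  rows <- lapply(split_tab, function(d) {
    gr <- unique(d$grade_group)
    if (length(gr) != 1L) {
      stop(sprintf("sample %s carries multiple grade labels: %s",
                   d$sample_id[1], paste(gr, collapse = ", ")), call. = FALSE)
    }
    if (nrow(d) == 0L) return(NULL)
    means <- vapply(feat, function(f) mean(d[[f]], na.rm = TRUE), numeric(1))
    cbind(data.frame(sample_id = d$sample_id[1], grade_group = gr,
                     n_nuclei = nrow(d)), as.data.frame(as.list(means)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sample_records", "data.frame")
  out
}

#' One-way ANOVA screen across grade groups with Bonferroni pairwise tests
#'
#' For every feature, compares the per-sample means across the grade groups
#' with a classical one-way (equal-variance) ANOVA. Features whose overall p
#' is at most `alpha` are followed up with all pairwise two-sample
#' comparisons using the pooled within-group SD, Bonferroni-corrected across
#' the three pairs; only pairs surviving correction are reported. Features
#' with zero variance in every group are flagged with an undefined F.
#'
#' @param records `sample_records` from [aggregate_samples()].
#' @param alpha significance level (default 0.05).
#' @param features which features to screen (default: all numeric columns).
#' @return data.frame with one row per feature: per-group means and SDs,
#'   `F`, `p`, `significant`, and `pairs` (comma-separated significant pairs
#'   such as `"G13-G5"`).
#' @export
anova_screen <- function(records, alpha = 0.05, features = NULL) {
  g <- factor(records$grade_group)
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  if (is.null(features)) {
    features <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                        "n_nuclei")
  }
  lv <- levels(g)
  res <- lapply(features, function(f) {
    x <- records[[f]]
    ok <- is.finite(x)
    xs <- x[ok]; gs <- droplevels(g[ok])
    base <- data.frame(feature = f, F = NA_real_, p = NA_real_,
                       significant = FALSE, pairs = "", n_used = sum(ok))
    for (l in lv) {
      base[[paste0("mean_", l)]] <- mean(x[ok & g == l])
      base[[paste0("sd_", l)]] <- stats::sd(x[ok & g == l])
    }
    if (nlevels(gs) < 2L || any(table(gs) < 2L)) return(base)
    wvar <- tapply(xs, gs, stats::var)
    if (all(wvar == 0, na.rm = TRUE)) return(base)  # F undefined
    a <- stats::oneway.test(xs ~ gs, var.equal = TRUE)
    base$F <- unname(a$statistic)
    base$p <- a$p.value
    base$significant <- is.finite(a$p.value) && a$p.value <= alpha
    if (base$significant && nlevels(gs) >= 2L) {
      pw <- stats::pairwise.t.test(xs, gs, p.adjust.method = "bonferroni",
                                   pool.sd = TRUE)
      pm <- pw$p.value
      sig_pairs <- character(0)
      for (i in seq_len(nrow(pm))) for (j in seq_len(ncol(pm))) {
        if (!is.na(pm[i, j]) && pm[i, j] <= alpha) {
          sig_pairs <- c(sig_pairs, paste(colnames(pm)[j], rownames(pm)[i],
                                          sep = "-"))
        }
      }
      base$pairs <- paste(sig_pairs, collapse = ",")
    }
    base
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-grade chromatin summary (green-channel optical density x area)
#'
#' Reproduces the integer chromatin-quantity arithmetic: per grade, the mean
#' green gray level and mean nuclear area are rounded to integers, the
#' optical density is `256 - gray_green`, and the total chromatin quantity is
#' `OD * area`. An `quantity_exact` column carries the unrounded product.
#'
#' Accepts either `sample_records` (per-grade means are computed from the
#' samples) or a data.frame with one row per grade and columns `grade_group`,
#' `gray_green`, `nuclear_area` (values used as given).
#'
#' @param x `sample_records` or a per-grade data.frame (see Details).
#' @return data.frame with one row per grade: `grade_group`, `gray_green`,
#'   `optical_density`, `nuclear_area`, `quantity`, `quantity_exact`.
#' @examples
#' chromatin_summary(data.frame(grade_group = c("G13", "G4", "G5"),
#'                              gray_green = c(97, 114, 89),
#'                              nuclear_area = c(54, 61, 71)))
#' @export
chromatin_summary <- function(x) {
  if (inherits(x, "sample_records")) {
    gg <- tapply(x$gray_green, x$grade_group, mean)
    ar <- tapply(x$nuclear_area, x$grade_group, mean)
    x <- data.frame(grade_group = names(gg), gray_green = as.numeric(gg),
                    nuclear_area = as.numeric(ar))
  }
  stopifnot(all(c("grade_group", "gray_green", "nuclear_area") %in% names(x)))
  expected <- c("G13", "G4", "G5")
  if (!all(expected %in% x$grade_group)) {
    warning("missing grade(s): ",
            paste(setdiff(expected, x$grade_group), collapse = ", "),
            "; returning partial table")
  }
  od <- 256 - round(x$gray_green)
  data.frame(grade_group = x$grade_group,
             gray_green = x$gray_green,
             optical_density = od,
             nuclear_area = x$nuclear_area,
             quantity = od * round(x$nuclear_area),
             quantity_exact = (256 - x$gray_green) * x$nuclear_area)
}
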