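# Discriminant score, classification, stepwise selection and ROC analysis.

# Published per-grade means of the seven model variables (minimal radius,
# fractal dimension, min/max gray, margination, green/blue gray level).
grade_means <- list(
  G13 = c(radius_min = 3.36, fractal_dimension = 1.058, gray_min = 85.54,
          gray_max = 178.70, margination = 0.3400, gray_green = 97.079,
          gray_blue = 135.68),
  G4 = c(radius_min = 3.63, fractal_dimension = 1.057, gray_min = 102.94,
         gray_max = 205.66, margination = 0.334, gray_green = 114.22,
         gray_blue = 155.28),
  G5 = c(radius_min = 3.72, fractal_dimension = 1.056, gray_min = 82.446,
         gray_max = 180.61, margination = 0.352, gray_green = 89.46,
         gray_blue = 136.79))

test_that("the zero vector scores exactly the printed intercept", {
  z <- setNames(rep(0, 7), names(paper_model()$coefficients))
  expect_identical(ds_score(z), 1331.50420234964)
})

test_that("scoring is exactly linear in its inputs", {
  withr::with_seed(5, {
    nm <- names(paper_model()$coefficients)
    for (i in 1:20) {
      a <- setNames(rnorm(7, 0, 50), nm)
      b <- setNames(rnorm(7, 0, 50), nm)
      z <- setNames(rep(0, 7), nm)
      expect_equal(ds_score(a) + ds_score(b) - ds_score(z), ds_score(a + b),
                   tolerance = 1e-9)
    }
  })
})

test_that("published grade-group means fall on the right side of the cutoff", {
  # frozen values from an independent evaluation of the printed formula
  expect_equal(ds_score(grade_means$G13), -7.725247582321472, tolerance = 1e-9)
  expect_equal(ds_score(grade_means$G4), 9.7732474751554, tolerance = 1e-9)
  expect_equal(ds_score(grade_means$G5), 7.8265347561832925, tolerance = 1e-9)
  cut <- paper_model()$cutoff
  expect_lt(ds_score(grade_means$G13), cut)
  expect_gt(min(ds_score(grade_means$G4), ds_score(grade_means$G5)), cut)
  expect_equal(as.character(classify_ds(ds_score(grade_means$G4))),
               "high_grade_G45")
})

test_that("classification ties at the cutoff go to high grade", {
  cut <- paper_model()$cutoff
  expect_equal(as.character(classify_ds(cut)), "high_grade_G45")
  expect_equal(as.character(classify_ds(cut - 1e-6)), "low_grade_G13")
})

test_that("scoring refuses missing or non-finite features", {
  v <- grade_means$G13
  expect_error(ds_score(v[-1]), "radius_min")
  v["gray_max"] <- NA
  expect_error(ds_score(v), "gray_max")
})

test_that("stepwise selection keeps one copy of duplicated candidates", {
  rec <- simulate_candidates(30, 4, 2, 5, seed = 10)
  rec$f1_copy <- rec$f1
  fit <- fit_stepwise(rec, c("f1", "f1_copy", "f2", "f3", "f4"))
  sel <- names(fit$coefficients)
  expect_true(sum(c("f1", "f1_copy") %in% sel) <= 1)
  expect_true("f2" %in% sel)
})

test_that("stepwise refuses an all-low-grade cohort and pure noise rarely breaks", {
  rec <- simulate_candidates(20, 3, 0, 0, seed = 2)
  rec$grade_group <- "G13"
  expect_error(fit_stepwise(rec, c("f1", "f2", "f3")), "class")
  # null candidates: either a (rare, alpha-driven) small model or a clean error
  n_model <- 0L
  for (s in 1:25) {
    rec <- simulate_candidates(30, 10, 0, 0, seed = 400 + s)
    fit <- tryCatch(fit_stepwise(rec, paste0("f", 1:10)),
                    error = function(e) {
                      expect_match(conditionMessage(e), "no discriminative")
                      NULL
                    })
    if (!is.null(fit)) n_model <- n_model + 1L
  }
  # entry is alpha-gated over 10 candidates: a nonempty model is possible
  # but should stay a minority outcome
  expect_lt(n_model, 20L)
})

test_that("fitted discriminant orients high grade to higher scores with unit
          pooled within-class score variance", {
  rec <- simulate_candidates(40, 6, 2, 3, seed = 77)
  fit <- fit_stepwise(rec, paste0("f", 1:6))
  sc <- ds_score(rec, fit)
  hi <- rec$grade_group == "G4"
  expect_gt(mean(sc[hi]), mean(sc[!hi]))
  pooled <- ((sum(hi) - 1) * var(sc[hi]) + (sum(!hi) - 1) * var(sc[!hi])) /
    (length(sc) - 2)
  expect_equal(pooled, 1, tolerance = 1e-6)
  # intercept centres the class midpoint at zero
  expect_equal((mean(sc[hi]) + mean(sc[!hi])) / 2, 0, tolerance = 1e-9)
})

test_that("the Wald logistic variant also recovers strong signal features", {
  # moderate separation: complete separation would degenerate the Wald test
  # (Hauck-Donner effect), which is why Wilks' lambda is the default
  rec <- simulate_candidates(40, 6, 2, 2, seed = 55)
  fit <- fit_stepwise(rec, paste0("f", 1:6), method = "wald")
  expect_true(all(c("f1", "f2") %in% names(fit$coefficients)))
})

test_that("ROC handles separation, ties and matches the pair-counting oracle", {
  sep <- roc_curve(c(1, 2, 3, 10, 11, 12), rep(c("low", "high"), each = 3),
                   positive = "high")
  expect_equal(sep$auc, 1)
  cc <- pick_cutoff(sep)
  expect_equal(cc$sensitivity, 1)
  expect_equal(cc$specificity, 1)
  flat <- roc_curve(rep(2, 6), rep(c("low", "high"), each = 3),
                    positive = "high")
  expect_equal(flat$auc, 0.5)
  # exhaustive pair-counting oracle over all 9 (low, high) pairs
  scores <- c(1, 2, 3, 2.5, 3.5, 4.5)
  labels <- rep(c("low", "high"), each = 3)
  pairs <- expand.grid(l = scores[1:3], h = scores[4:6])
  oracle <- mean(ifelse(pairs$h > pairs$l, 1, ifelse(pairs$h == pairs$l, 0.5, 0)))
  expect_equal(roc_curve(scores, labels, positive = "high")$auc, oracle,
               tolerance = 1e-12)
  expect_error(roc_curve(1:3, rep("high", 3)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  withr::with_seed(31, {
    scores <- c(rnorm(40, 0), rnorm(35, 1.2))
    labels <- rep(c("low", "high"), c(40, 35))
    ours <- roc_curve(scores, labels, positive = "high")$auc
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(labels, scores, levels = c("low", "high"),
                direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-10)
  })
})

test_that("shifting every score shifts the chosen cutoff, not its quality", {
  withr::with_seed(13, {
    scores <- c(rnorm(25, 0), rnorm(25, 1.5))
    labels <- rep(c("low", "high"), each = 25)
    r1 <- roc_curve(scores, labels, positive = "high")
    r2 <- roc_curve(scores + 100, labels, positive = "high")
    c1 <- pick_cutoff(r1); c2 <- pick_cutoff(r2)
    expect_equal(c2$cutoff, c1$cutoff + 100, tolerance = 1e-9)
    expect_equal(c2$sensitivity, c1$sensitivity)
    expect_equal(c2$specificity, c1$specificity)
    expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  })
})

test_that("discriminant models round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_model(paper_model(), path)
  m <- read_model(path)
  expect_identical(m$intercept, paper_model()$intercept)
  expect_identical(m$coefficients, paper_model()$coefficients)
  expect_identical(m$cutoff, paper_model()$cutoff)
})
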