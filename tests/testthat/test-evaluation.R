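# two well-separated seeded Gaussian classes in the plane
gaussian_pair <- function(n_per = 20L, dist = 10, seed = 1L) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
               matrix(rnorm(n_per * 2, mean = dist), n_per, 2))
    list(x = x, y = rep(c("A", "B"), each = n_per))
  })
}

test_that("confusion_counts matches case-by-case enumeration", {
  expect_equal(confusion_counts(c("A", "A", "B"), c("A", "B", "B"), "A"),
               c(TP = 1L, TN = 1L, FP = 0L, FN = 1L))
  y <- c("A", "B", "C", "A")
  expect_equal(confusion_counts(y, y, "B"),
               c(TP = 1L, TN = 3L, FP = 0L, FN = 0L))
  # class absent from both vectors: all-negative
  expect_equal(confusion_counts(y, y, "Z"),
               c(TP = 0L, TN = 4L, FP = 0L, FN = 0L))
  expect_error(confusion_counts(c("A"), c("A", "B"), "A"), "length")
})

test_that("class_metrics computes Se, Sp and Matthews correlation", {
  m <- class_metrics(c(TP = 9, TN = 8, FP = 2, FN = 1))
  expect_equal(m[["Se"]], 0.9)
  expect_equal(m[["Sp"]], 0.8)
  expect_equal(m[["MCC"]], 70 / sqrt(9900), tolerance = 1e-12)

  perfect <- class_metrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1))

  degenerate <- class_metrics(c(TP = 0, TN = 10, FP = 0, FN = 10))
  expect_equal(degenerate[["Se"]], 0)
  expect_equal(degenerate[["MCC"]], 0)
})

test_that("metrics agree with the brute-force oracle on random labelings", {
  withr::with_seed(19, {
    for (i in 1:100) {
      n <- sample(5:30, 1)
      classes <- LETTERS[1:sample(2:4, 1)]
      yt <- sample(classes, n, replace = TRUE)
      yp <- sample(classes, n, replace = TRUE)
      cl <- sample(classes, 1)
      ref <- confusion_reference(yt, yp, cl)
      cnt <- confusion_counts(yt, yp, cl)
      expect_identical(cnt, ref)
      expect_equal(sum(cnt), n)
      m <- class_metrics(cnt)
      expect_true(m[["MCC"]] >= -1 && m[["MCC"]] <= 1)
      expect_true(m[["Se"]] >= 0 && m[["Se"]] <= 1)
      expect_true(m[["Sp"]] >= 0 && m[["Sp"]] <= 1)
    }
  })
})

test_that("jackknife scores separable classes perfectly", {
  g <- gaussian_pair()
  rep <- jackknife_evaluate(g$x, g$y)
  expect_equal(rep$overall_accuracy, 1.0)
  expect_equal(rep$n_scored, 40L)
  expect_true(all(rep$per_class$FP == 0) && all(rep$per_class$FN == 0))
})

test_that("jackknife on permuted labels sits near chance level", {
  g <- gaussian_pair()
  oa <- withr::with_seed(20, vapply(1:10, function(i) {
    jackknife_evaluate(g$x, sample(g$y))$overall_accuracy
  }, numeric(1)))
  expect_lt(abs(mean(oa) - 0.5), 0.15)
})

test_that("report satisfies its accounting identities", {
  g <- gaussian_pair(n_per = 12L, dist = 2, seed = 3)   # overlapping classes
  rep <- jackknife_evaluate(g$x, g$y)
  correct <- sum(rep$predictions$true == rep$predictions$predicted)
  expect_equal(sum(rep$per_class$TP), correct)
  expect_equal(rep$overall_accuracy, correct / rep$n_scored)
  expect_equal(rep$n_scored, 24L)
  expect_true(all(rep$per_class$TP + rep$per_class$TN +
                  rep$per_class$FP + rep$per_class$FN == rep$n_scored))
})

test_that("synthetic rows train but are never scored", {
  g <- gaussian_pair(n_per = 10L)
  syn <- smote_class(g$x[g$y == "B", ], 5, 3, seed = 2)$samples
  x <- rbind(g$x, syn)
  y <- c(g$y, rep("B", 5))
  flag <- c(rep(FALSE, 20), rep(TRUE, 5))
  rep <- jackknife_evaluate(x, y, synthetic = flag)
  expect_equal(rep$n_scored, 20L)
  expect_false(any(grepl("^2[1-5]$", rep$predictions$id)))
})

test_that("grid search returns the best configuration, first on ties", {
  g <- gaussian_pair()
  one <- svm_config("linear", cost = 1)
  expect_identical(grid_search_hyperparams(g$x, g$y, grid = list(one))$cost, 1)

  grid <- list(svm_config("linear", 1), svm_config("radial", 1))
  best <- grid_search_hyperparams(g$x, g$y, grid = grid)
  log <- attr(best, "search_log")
  expect_equal(nrow(log), 2L)
  # separable either way: tie broken by grid order
  expect_equal(log$OA, c(1, 1))
  expect_equal(best$kernel, "linear")
})

test_that("evaluation requires at least two scored classes", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(jackknife_evaluate(x, rep("A", 10)), "2 classes")
})

test_that("reports serialize to TSV and JSON", {
  g <- gaussian_pair(n_per = 8L)
  rep <- jackknife_evaluate(g$x, g$y)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_report(rep, tsv = tsv, json = js)
  expect_true(any(grepl("^# OA", readLines(tsv))))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$overall_accuracy, 1)
  expect_equal(parsed$n_scored, 16L)
})
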