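test_that("leave-one-out accuracy matches hand enumeration on a toy pool", {
  # 6 records, 2 inputs; oracle enumerates every held-out prediction with
  # explicit loops (standardization on the 5 remaining records each time)
  pool <- data.frame(
    subject_id = sprintf("P%d", 1:6), dataset_id = 1L,
    age = c(40, 42, 44, 70, 72, 74), gender = 1L,
    truth = c("nonUC", "nonUC", "nonUC", "UC", "UC", "UC"),
    cytology = c(1L, 1L, 2L, 3L, 4L, 4L),
    nmp22 = c(1L, 1L, 1L, 2L, 2L, 2L),
    fish = c(1L, 1L, 2L, 2L, 2L, 1L),
    cxbladder = c(1L, 1L, 1L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
  pool <- dxrank:::ensure_provenance(pool)
  inputs <- c("age", "cytology")
  k <- 3L
  oracle_correct <- 0L
  for (i in 1:6) {
    train <- pool[-i, ]
    mu <- sapply(inputs, function(v) mean(train[[v]]))
    sdv <- sapply(inputs, function(v) sd(train[[v]]))
    d <- sqrt(colSums((apply(train[, inputs], 1, function(r)
      (r - mu) / sdv) - (unlist(pool[i, inputs]) - mu) / sdv)^2))
    nb <- order(d)[1:3]
    votes <- table(train$nmp22[nb])
    pred <- as.integer(names(votes)[which.max(votes)])
    if (to_binary("nmp22", pred) == to_binary("nmp22", pool$nmp22[i])) {
      oracle_correct <- oracle_correct + 1L
    }
  }
  got <- loo_accuracy(pool, inputs, "nmp22", backend_config("knn", k = 3))
  expect_equal(got$n_eval, 6)
  expect_equal(got$accuracy, 100 * oracle_correct / 6)
})

test_that("degenerate leave-one-out pools behave as specified", {
  pool <- toy_cohort(n_uc = 4, n_nonuc = 4, seed = 5)
  pool$nmp22 <- 2L  # single observed class: every prediction is correct
  got <- loo_accuracy(pool, c("age", "cytology"), "nmp22",
                      backend_config("mlr"))
  expect_equal(got$accuracy, 100)
  expect_error(loo_accuracy(pool[1:3, ], c("age"), "nmp22",
                            backend_config("knn", k = 3)),
               "too small")
})

test_that("supervised imputation of a truth-determined target is perfect under LOO", {
  set.seed(71)
  pool <- toy_cohort(n_uc = 10, n_nonuc = 15, seed = 71)
  pool$fish <- ifelse(pool$truth == "UC", 2L, 1L)
  pool$.truth_code <- dxrank:::truth_code(pool$truth)
  for (kind in c("knn", "mlr", "mlp")) {
    got <- loo_accuracy(pool, c("age", "gender", ".truth_code"), "fish",
                        backend_config(kind, k = 3, seed = 2))
    expect_equal(got$accuracy, 100,
                 label = sprintf("backend %s", kind))
  }
})

test_that("accuracy distortion follows the measured-minus-imputed convention", {
  ds <- canonical_fixture(1)
  # identity: no missing cells means no distortion
  complete <- toy_cohort(n_uc = 10, n_nonuc = 30, seed = 6)
  ba0 <- before_after(complete, complete, "nmp22")
  expect_equal(ba0$sens_diff, 0)
  expect_equal(ba0$spec_diff, 0)
  expect_equal(ba0$avg_abs_diff, 0)

  imp <- run_plan(ds, canonical_plan(), backend_config("knn", k = 3))
  ba <- before_after(ds, imp, "fish")
  m <- sens_spec_ci(confusion_counts(ds, "fish", "measured_only"))
  i <- sens_spec_ci(confusion_counts(imp, "fish", "imputed_full"))
  expect_equal(ba$sens_diff, m$sens - i$sens)
  expect_equal(ba$avg_abs_diff,
               (abs(ba$sens_diff) + abs(ba$spec_diff)) / 2)
  expect_error(before_after(ds[1:10, ], imp, "fish"), "different numbers")
})

test_that("the average absolute difference matches the published arithmetic", {
  avg <- function(s, p) (abs(s) + abs(p)) / 2
  expect_equal(avg(2.68, 0.02), 1.35)
  expect_equal(avg(-1.38, 0.67), 1.025)
  # sign-convention invariance
  expect_equal(avg(-2.68, -0.02), avg(2.68, 0.02))
})

test_that("method summaries average each column over the tests", {
  rows <- data.frame(
    test = c("cytology", "nmp22", "fish", "cxbladder"),
    backend = "3nn", mode = "supervised",
    loo_acc = c(96, 84, 83, 81),
    sens_diff = c(2, -2, 2, -2),
    spec_diff = c(1, 1, 1, 1),
    avg_abs_diff = c(1.5, 1.5, 1.5, 1.5),
    stringsAsFactors = FALSE)
  s <- method_summary(rows)
  expect_equal(s$test, "mean_for_method")
  expect_equal(s$loo_acc, 86)
  expect_equal(s$sens_diff, 0)   # signed averaging
  expect_equal(s$spec_diff, 1)
  expect_equal(s$avg_abs_diff, 1.5)
  # identical rows: the mean equals any row
  same <- rows
  same[, 4:7] <- rep(c(90, 1, -1, 1), each = 4)
  s2 <- method_summary(same)
  expect_equal(unlist(s2[, c("loo_acc", "sens_diff", "spec_diff",
                             "avg_abs_diff")], use.names = FALSE),
               c(90, 1, -1, 1))
})

test_that("the validation report covers every test/backend/mode and picks a best method", {
  ds <- canonical_fixture(1)
  v <- validate_imputation(ds, backends = c("3nn", "mlr"),
                           modes = c("supervised", "unsupervised"),
                           seed = 2, loo_max_n = 40)
  rep <- v$report
  main <- rep[rep$test != "mean_for_method", ]
  expect_equal(nrow(main), 4 * 2 * 2)
  expect_true(all(main$loo_acc >= 0 & main$loo_acc <= 100))
  expect_equal(main$avg_abs_diff,
               (abs(main$sens_diff) + abs(main$spec_diff)) / 2)
  means <- rep[rep$test == "mean_for_method", ]
  expect_equal(nrow(means), 4)
  expect_true(v$best$backend %in% c("3nn", "mlr"))
  expect_true(v$best$mode %in% c("supervised", "unsupervised"))
})
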