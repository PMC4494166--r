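test_that("kNN prediction agrees with an exhaustive-distance oracle on small pools", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:20, 1)
    pool <- toy_cohort(n_uc = ceiling(n / 3), n_nonuc = n - ceiling(n / 3),
                       seed = seed)
    query <- toy_cohort(n_uc = 1, n_nonuc = 0, seed = seed + 1000)
    k <- sample(c(3, 5), 1)
    if (nrow(pool) < k) next
    inputs <- c("age", "gender", "cytology", "cxbladder")
    expect_identical(
      knn_impute(pool, query, inputs, "nmp22", k),
      oracle_knn(pool, query, inputs, "nmp22", k),
      label = sprintf("seed %d", seed))
  }
})

test_that("kNN degenerate neighbourhoods behave as specified", {
  pool <- toy_cohort(n_uc = 4, n_nonuc = 4, seed = 2)
  pool$nmp22 <- 2L  # unanimous neighbourhood
  q <- toy_cohort(n_uc = 1, n_nonuc = 0, seed = 9)
  expect_equal(knn_impute(pool, q, c("age", "cytology"), "nmp22", 3), 2L)
  # a query identical to a training record finds it at distance zero
  q2 <- pool[5, ]
  expect_equal(knn_impute(pool, q2, c("age", "gender", "cytology"),
                          "nmp22", 1),
               pool$nmp22[5])
  expect_error(knn_impute(pool[1:2, ], q, c("age"), "nmp22", 3),
               "need at least k = 3")
})

test_that("linear-model imputation matches the normal-equations closed form", {
  pool <- toy_cohort(n_uc = 3, n_nonuc = 5, seed = 31)
  queries <- toy_cohort(n_uc = 2, n_nonuc = 3, seed = 32)
  inputs <- c("age", "cytology", "cxbladder")
  # oracle: beta = (X'X)^{-1} X'y, predictions rounded to the nearest code
  X <- cbind(1, as.matrix(pool[, inputs]))
  beta <- solve(t(X) %*% X, t(X) %*% pool$nmp22)
  pred <- drop(cbind(1, as.matrix(queries[, inputs])) %*% beta)
  oracle <- ifelse(abs(pred - 1) <= abs(pred - 2), 1L, 2L)
  got <- model_impute(pool, queries, inputs, "nmp22", backend_config("mlr"))
  expect_identical(got, oracle)
})

test_that("global models handle constant targets, collinearity and determinism", {
  pool <- toy_cohort(n_uc = 4, n_nonuc = 8, seed = 12)
  queries <- toy_cohort(n_uc = 1, n_nonuc = 2, seed = 13)
  pool$fish <- 2L
  for (kind in c("mlr", "mlp")) {
    expect_equal(model_impute(pool, queries, c("age", "nmp22"), "fish",
                              backend_config(kind)),
                 rep(2L, 3))
  }
  # duplicated input column -> singular design
  pool2 <- toy_cohort(n_uc = 4, n_nonuc = 8, seed = 14)
  pool2$dup <- pool2$age
  queries2 <- queries
  queries2$dup <- queries2$age
  expect_error(model_impute(pool2, queries2, c("age", "dup"), "nmp22",
                            backend_config("mlr")),
               "collinear")
  # seeded MLP is deterministic
  pool3 <- toy_cohort(n_uc = 6, n_nonuc = 14, seed = 15)
  a <- model_impute(pool3, queries, c("age", "cytology", "cxbladder"),
                    "nmp22", backend_config("mlp", seed = 7))
  b <- model_impute(pool3, queries, c("age", "cytology", "cxbladder"),
                    "nmp22", backend_config("mlp", seed = 7))
  expect_identical(a, b)
})

test_that("the logistic variant of the global model predicts valid codes", {
  pool <- toy_cohort(n_uc = 8, n_nonuc = 16, seed = 18)
  queries <- toy_cohort(n_uc = 2, n_nonuc = 2, seed = 19)
  got <- model_impute(pool, queries, c("age", "cxbladder"), "nmp22",
                      backend_config("mlr", family = "logistic"))
  expect_true(all(got %in% 1:2))
  got4 <- model_impute(pool, queries, c("age", "cxbladder"), "cytology",
                       backend_config("mlr", family = "logistic"))
  expect_true(all(got4 %in% 1:4))
})

test_that("the canonical plan lists the published seven steps", {
  plan <- canonical_plan()
  expect_length(plan$steps, 7)
  s1 <- plan$steps[[1]]
  expect_equal(s1$target_dataset, 5L)
  expect_equal(s1$target_variable, "nmp22")
  expect_equal(s1$expected_count, 2L)
  expect_setequal(s1$input_variables,
                  c("age", "gender", "cytology", "fish", "cxbladder"))
  s4 <- plan$steps[[4]]
  expect_equal(s4$target_dataset, c(2L, 3L))
  expect_equal(s4$training_datasets, 1:5)
  s7 <- plan$steps[[7]]
  expect_equal(s7$target_dataset, 1L)
  expect_equal(s7$target_variable, "fish")
  expect_equal(s7$expected_count, 474L)
  expect_equal(s7$training_datasets, c(1L, 4L, 5L))
  # no step uses its target as an input
  for (s in plan$steps) {
    expect_false(s$target_variable %in% s$input_variables)
  }
})

test_that("the automatic planner starts with the smallest block and covers everything", {
  ds <- canonical_fixture(1)
  plan <- auto_plan(ds)
  s1 <- plan$steps[[1]]
  expect_equal(s1$target_dataset, 5L)
  expect_equal(s1$target_variable, "nmp22")
  expect_equal(s1$expected_count, 2L)
  imp <- run_plan(ds, plan, backend_config("knn", k = 3))
  expect_equal(sum(is.na(imp[c("cytology", "nmp22", "fish", "cxbladder")])), 0)
  # complete data -> empty plan
  expect_length(auto_plan(toy_cohort())$steps, 0)
})

test_that("equal-sized blocks break ties by test name", {
  ds <- toy_cohort(n_uc = 6, n_nonuc = 14, seed = 44)
  ds$nmp22[1:2] <- NA_integer_
  ds$fish[3:4] <- NA_integer_
  ds <- dxrank:::ensure_provenance(ds[, setdiff(names(ds), grep("_src", names(ds), value = TRUE))])
  plan <- auto_plan(ds)
  expect_equal(vapply(plan$steps, `[[`, character(1), "target_variable"),
               c("fish", "nmp22"))
})

test_that("plan execution conserves measured cells and fills every gap", {
  ds <- canonical_fixture(1)
  tests <- c("cytology", "nmp22", "fish", "cxbladder")
  for (label in c("3nn", "mlr")) {
    imp <- run_plan(ds, canonical_plan(), parse_backend(label, seed = 5))
    expect_equal(sum(is.na(imp[tests])), 0)
    log <- attr(imp, "impute_log")
    expect_equal(log$n_imputed[log$step == 1], 2)
    expect_equal(log$n_imputed[log$step == 7], 474)
    for (t in tests) {
      measured <- ds[[src_col <- paste0(t, "_src")]] == "measured"
      expect_identical(imp[[t]][measured], ds[[t]][measured])
      expect_identical(imp[[src_col]][measured], ds[[src_col]][measured])
      imputed <- imp[[src_col]] == "imputed"
      expect_true(all(is.na(ds[[t]][imputed])))
      expect_true(all(imp[[t]][imputed] %in% dxrank:::DX_ALPHABETS[[t]]))
    }
  }
})

test_that("an empty training pool aborts with the step identified", {
  ds <- canonical_fixture(1)
  plan <- canonical_plan()
  plan$steps[[1]]$training_datasets <- 2L  # no NMP22 measured in D2
  expect_error(run_plan(ds, plan, backend_config("knn", k = 3)),
               "step 1 .* empty training pool")
})

test_that("supervised mode passes the clinical truth to the backend", {
  # tests deterministic functions of truth: supervision makes imputation
  # exact even from otherwise uninformative inputs
  set.seed(60)
  n <- 40
  ds <- data.frame(
    subject_id = sprintf("S%02d", 1:n), dataset_id = 1L,
    age = runif(n, 40, 80), gender = sample(1:2, n, TRUE),
    truth = sample(c("UC", "nonUC"), n, TRUE),
    cytology = 1L, nmp22 = 1L, fish = NA_integer_, cxbladder = 1L,
    stringsAsFactors = FALSE)
  ds$fish <- ifelse(ds$truth == "UC", 2L, 1L)
  ds$fish[31:40] <- NA_integer_
  ds <- dxrank:::ensure_provenance(ds)
  plan <- auto_plan(ds)
  sup <- run_plan(ds, plan, backend_config("knn", k = 3, supervised = TRUE))
  expect_identical(sup$fish[31:40],
                   ifelse(ds$truth[31:40] == "UC", 2L, 1L))
})
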