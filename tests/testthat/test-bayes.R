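test_that("compatible cells enumerate exactly the free bits", {
  all_obs <- c(cytology = 3, nmp22 = 1, fish = 2, cxbladder = 1)
  # cytology positive (bit 8), fish positive (bit 2)
  expect_equal(compatible_cells(all_obs), 10L)
  one_missing <- c(cytology = 3, nmp22 = 1, fish = NA, cxbladder = 1)
  expect_equal(compatible_cells(one_missing), c(8L, 10L))
  expect_length(compatible_cells(c(cytology = NA, nmp22 = NA,
                                   fish = NA, cxbladder = NA)), 16L)
  # every observed pattern count: 2^missing
  for (m in 0:4) {
    partial <- c(cytology = 3, nmp22 = 2, fish = 2, cxbladder = 2)
    if (m > 0) partial[seq_len(m)] <- NA
    expect_length(compatible_cells(partial), 2^m)
  }
})

test_that("complete-data posterior means match the conjugate closed form", {
  ds <- toy_cohort(n_uc = 30, n_nonuc = 60, seed = 17)
  post <- gibbs_run(ds, n_iter = 4000, burn_in = 500, seed = 4)
  for (g in c("Tumor", "Normal")) {
    sub <- ds[ds$truth == (if (g == "Tumor") "UC" else "nonUC"), ]
    counts <- numeric(16)
    for (i in seq_len(nrow(sub))) {
      cell <- compatible_cells(sub[i, c("cytology", "nmp22", "fish",
                                        "cxbladder")])
      counts[cell + 1L] <- counts[cell + 1L] + 1
    }
    expected <- (counts + 1) / (nrow(sub) + 16)   # Dirichlet(1+counts) mean
    got <- colMeans(post$draws[, g, ])
    mc_se <- sqrt(expected * (1 - expected) / dim(post$draws)[1])
    expect_true(all(abs(got - expected) < 5 * mc_se))
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("every sampled probability vector lies on the simplex", {
  ds <- canonical_fixture(1)
  post <- gibbs_run(ds, n_iter = 200, burn_in = 50, seed = 2)
  sums <- apply(post$draws, 1:2, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(post$draws >= 0))
})

test_that("the chain is deterministic given its seed and errors on an empty group", {
  ds <- canonical_fixture(1)[1:200, ]
  a <- gibbs_run(ds, n_iter = 100, burn_in = 10, seed = 9)
  b <- gibbs_run(ds, n_iter = 100, burn_in = 10, seed = 9)
  expect_identical(a$draws, b$draws)
  uconly <- ds[ds$truth == "UC", ]
  expect_error(gibbs_run(uconly, 100, 10, 1), "empty group")
})

test_that("a never-observed test keeps its symmetric prior marginal", {
  ds <- toy_cohort(n_uc = 15, n_nonuc = 30, seed = 23)
  ds$fish <- NA_integer_
  ds$fish_src <- "missing"
  post <- gibbs_run(ds, n_iter = 3000, burn_in = 500, seed = 6)
  est <- marginal_sens_spec(post, "fish")
  expect_equal(est$sens, 50, tolerance = 5)
  expect_equal(est$spec, 50, tolerance = 5)
})

test_that("marginal summaries integrate the correct cells", {
  # degenerate posterior: all Tumor mass on the all-positive cell (15),
  # all Normal mass on the all-negative cell (0)
  draws <- array(0, c(10, 2, 16), dimnames = list(NULL, c("Tumor", "Normal"),
                                                  NULL))
  draws[, 1, 16] <- 1
  draws[, 2, 1] <- 1
  post <- structure(list(draws = draws, burn_in = 0,
                         n = c(Tumor = 1L, Normal = 1L)),
                    class = "dx_posterior")
  for (t in c("cytology", "nmp22", "fish", "cxbladder")) {
    est <- marginal_sens_spec(post, t)
    expect_equal(est$sens, 100)
    expect_equal(est$spec, 100)
  }
})

test_that("posterior means agree with empirical proportions on complete data", {
  ds <- toy_cohort(n_uc = 60, n_nonuc = 140, seed = 29,
                   p_pos_uc = 0.7, p_pos_nonuc = 0.2)
  post <- gibbs_run(ds, n_iter = 2000, burn_in = 500, seed = 3)
  acc <- test_accuracy(ds, "imputed_full")
  for (t in c("nmp22", "cxbladder")) {
    est <- marginal_sens_spec(post, t)
    row <- acc[acc$test == t, ]
    expect_equal(est$sens, row$sens, tolerance = 4)
    expect_equal(est$spec, row$spec, tolerance = 3)
    expect_true(est$sens_lo < est$sens && est$sens < est$sens_hi)
  }
})

test_that("heavier FISH missingness widens its posterior interval", {
  widths <- vapply(c(0, 60, 120), function(n_blank) {
    w <- 0
    for (seed in 1:3) {
      ds <- toy_cohort(n_uc = 40, n_nonuc = 120, seed = seed)
      if (n_blank > 0) {
        set.seed(seed + 500)
        ds$fish[sample(nrow(ds), n_blank)] <- NA_integer_
        ds <- dxrank:::ensure_provenance(
          ds[, setdiff(names(ds), paste0(c("cytology", "nmp22", "fish",
                                           "cxbladder"), "_src"))])
      }
      post <- gibbs_run(ds, n_iter = 1200, burn_in = 300, seed = seed)
      est <- marginal_sens_spec(post, "fish")
      w <- w + (est$sens_hi - est$sens_lo)
    }
    w / 3
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})
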