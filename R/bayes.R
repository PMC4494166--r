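## Cell indexing for the 16-cell joint outcome of the four binary tests:
## bit order cytology = MSB, then NMP22, FISH, Cxbladder = LSB; a set bit is
## a positive call. Cells are numbered 0..15 (stored 1-based internally).
CELL_BITS <- local({
  m <- as.matrix(expand.grid(cxbladder = 0:1, fish = 0:1, nmp22 = 0:1,
                             cytology = 0:1))
  m <- m[, c("cytology", "nmp22", "fish", "cxbladder")]
  m[order(m[, "cytology"] * 8 + m[, "nmp22"] * 4 + m[, "fish"] * 2 +
            m[, "cxbladder"]), ]
})

#' Outcome cells compatible with a partially observed subject
#'
#' Each subject's joint result over the four binary tests is one of 16
#' cells (cytology the most significant bit, Cxbladder Detect the least; a
#' set bit is a positive call). A subject with missing tests is compatible
#' with every cell that agrees with each observed outcome: `2^m` cells for
#' `m` missing tests.
#'
#' @param partial Named vector/list over the four tests with values `1`
#'   (negative), `2`-style codes, or `NA`; codes are collapsed via
#'   [to_binary()].
#' @return Integer vector of compatible cell indices in 0..15.
#' @examples
#' compatible_cells(c(cytology = 3, nmp22 = 1, fish = NA, cxbladder = NA))
#' @export
compatible_cells <- function(partial) {
  ok <- rep(TRUE, 16L)
  for (t in DX_TESTS) {
    code <- partial[[t]]
    if (is.null(code) || is.na(code)) next
    pos <- binary_positive(t, code)
    ok <- ok & (CELL_BITS[, t] == as.integer(pos))
  }
  which(ok) - 1L
}

## Compatible-cell sets for every row of a cohort, as 16-col logical matrix.
compatible_matrix <- function(ds) {
  ok <- matrix(TRUE, nrow(ds), 16L)
  for (t in DX_TESTS) {
    pos <- binary_positive(t, ds[[t]])
    obs <- !is.na(pos)
    if (any(obs)) {
      match_cell <- outer(as.integer(pos[obs]), CELL_BITS[, t], "==")
      ok[obs, ] <- ok[obs, , drop = FALSE] & match_cell
    }
  }
  ok
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Gibbs sampler for the two-group 16-cell multinomial model
#'
#' Subjects are allocated to a Tumor or Normal group by the cystoscopy
#' truth; within each group the joint outcome of the four binary tests
#' follows a 16-cell multinomial with a flat symmetric Dirichlet prior (all
#' concentration parameters 1 — the uniform prior over the probability
#' simplex). Missing test results are handled by data augmentation: each
#' incomplete subject's latent cell is drawn from the current group
#' probabilities restricted and renormalized over its compatible cells, then
#' the group probability vectors are redrawn from the conjugate Dirichlet
#' posterior given the completed counts. Subjects sharing a compatible-cell
#' set are augmented jointly with one multinomial draw, which leaves the
#' chain's law unchanged.
#'
#' @param ds Integrated cohort data frame (binary truth).
#' @param n_iter Number of retained plus burn-in iterations (default 2000).
#' @param burn_in Initial draws discarded (default 500).
#' @param seed Integer seed; fully determines the chain.
#' @return A `dx_posterior` list: `draws`, an
#'   `(n_iter - burn_in) x 2 x 16` array of cell probabilities (groups
#'   `Tumor`, `Normal`), plus `n_iter`, `burn_in`, `seed` and the group
#'   sizes.
#' @export
gibbs_run <- function(ds, n_iter = 2000L, burn_in = 500L, seed = 1L) {
  stopifnot(n_iter > burn_in)
  groups <- list(Tumor = ds[ds$truth == "UC", , drop = FALSE],
                 Normal = ds[ds$truth == "nonUC", , drop = FALSE])
  empty <- vapply(groups, nrow, integer(1)) == 0L
  if (any(empty)) {
    stop(sprintf("gibbs_run: empty group(s): %s",
                 paste(names(groups)[empty], collapse = ", ")), call. = FALSE)
  }
  ## Collapse each group to unique compatible-cell patterns with counts.
  patt <- lapply(groups, function(g) {
    cm <- compatible_matrix(g)
    key <- apply(cm, 1L, function(r) paste(which(r), collapse = ","))
    tab <- table(key)
    sets <- lapply(names(tab), function(k)
      as.integer(strsplit(k, ",", fixed = TRUE)[[1L]]))
    list(sets = sets, counts = as.integer(tab))
  })
  draws <- array(NA_real_, dim = c(n_iter - burn_in, 2L, 16L),
                 dimnames = list(NULL, c("Tumor", "Normal"), NULL))
  with_seed(seed, {
    p <- matrix(1 / 16, 2L, 16L)
    for (iter in seq_len(n_iter)) {
      for (g in 1:2) {
        counts <- numeric(16L)
        sets <- patt[[g]]$sets
        ns <- patt[[g]]$counts
        for (j in seq_along(sets)) {
          s <- sets[[j]]
          if (length(s) == 1L) {
            counts[s] <- counts[s] + ns[j]
          } else {
            w <- p[g, s]
            counts[s] <- counts[s] +
              as.numeric(stats::rmultinom(1L, ns[j], w))
          }
        }
        p[g, ] <- rdirichlet1(1 + counts)
      }
      if (iter > burn_in) draws[iter - burn_in, , ] <- p
    }
  })
  structure(list(draws = draws, n_iter = n_iter, burn_in = burn_in,
                 seed = seed,
                 n = vapply(groups, nrow, integer(1))),
            class = "dx_posterior")
}

#' @export
print.dx_posterior <- function(x, ...) {
  cat(sprintf("Posterior draws: %d retained iterations (%d burn-in), groups Tumor n=%d / Normal n=%d\n",
              dim(x$draws)[1], x$burn_in, x$n[["Tumor"]], x$n[["Normal"]]))
  invisible(x)
}

#' Marginal posterior sensitivity and specificity of one test
#'
#' Per retained draw, the test's sensitivity is the total Tumor-group
#' probability over the 8 cells where the test is positive, and its
#' specificity the total Normal-group probability over the 8 negative
#' cells. Point estimates are posterior means, intervals the 2.5 and 97.5
#' percentiles of the marginal distributions.
#'
#' @param post A `dx_posterior` from [gibbs_run()].
#' @param test Test name.
#' @param level Credible level, default 0.95.
#' @return One-row data frame: `test`, `sens`, `sens_lo`, `sens_hi`,
#'   `spec`, `spec_lo`, `spec_hi` (percent).
#' @export
marginal_sens_spec <- function(post, test, level = 0.95) {
  test <- match.arg(test, DX_TESTS)
  pos_cells <- CELL_BITS[, test] == 1L
  sens <- 100 * rowSums(post$draws[, "Tumor", pos_cells, drop = FALSE])
  spec <- 100 * rowSums(post$draws[, "Normal", !pos_cells, drop = FALSE])
  a <- (1 - level) / 2
  data.frame(test = test,
             sens = mean(sens),
             sens_lo = unname(stats::quantile(sens, a)),
             sens_hi = unname(stats::quantile(sens, 1 - a)),
             spec = mean(spec),
             spec_lo = unname(stats::quantile(spec, a)),
             spec_hi = unname(stats::quantile(spec, 1 - a)),
             stringsAsFactors = FALSE)
}

#' Bayesian accuracy table for every test
#'
#' Runs [gibbs_run()] once and summarizes [marginal_sens_spec()] for the
#' four tests.
#'
#' @inheritParams gibbs_run
#' @param level Credible level.
#' @return Data frame with one row per test.
#' @export
bayes_accuracy <- function(ds, n_iter = 2000L, burn_in = 500L, seed = 1L,
                           level = 0.95) {
  post <- gibbs_run(ds, n_iter = n_iter, burn_in = burn_in, seed = seed)
  do.call(rbind, lapply(DX_TESTS, function(t)
    marginal_sens_spec(post, t, level)))
}
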