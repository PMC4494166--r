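## Canonical synthetic fixture, integrated; cached per seed so test files
## that share a seed do not regenerate it.
.fixture_cache <- new.env(parent = emptyenv())

canonical_fixture <- function(seed = 1L) {
  key <- as.character(seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- integrate_cohort(generate_cohort(seed = seed))
  }
  .fixture_cache[[key]]
}

## Small hand-built cohort: n records, all four tests measured, binary codes
## drawn from per-group positivity rates. Valid under the cohort schema.
toy_cohort <- function(n_uc = 6, n_nonuc = 14, seed = 42,
                       p_pos_uc = 0.8, p_pos_nonuc = 0.15) {
  set.seed(seed)
  n <- n_uc + n_nonuc
  truth <- c(rep("UC", n_uc), rep("nonUC", n_nonuc))
  draw <- function(p) ifelse(runif(n) < p, 2L, 1L)
  p <- ifelse(truth == "UC", p_pos_uc, p_pos_nonuc)
  rec <- data.frame(
    subject_id = sprintf("T-%03d", seq_len(n)),
    dataset_id = 1L,
    age = round(runif(n, 30, 90), 1),
    gender = sample(1:2, n, replace = TRUE),
    truth = truth,
    cytology = ifelse(runif(n) < p, sample(3:4, n, replace = TRUE),
                      sample(1:2, n, replace = TRUE)),
    nmp22 = draw(p), fish = draw(p), cxbladder = draw(p),
    stringsAsFactors = FALSE
  )
  dxrank:::ensure_provenance(rec)
}

## Independent kNN oracle: explicit per-record loops, no shared code with
## the implementation beyond base arithmetic.
oracle_knn <- function(train, query, inputs, target, k) {
  mu <- sapply(inputs, function(v) mean(train[[v]]))
  sdv <- sapply(inputs, function(v) stats::sd(train[[v]]))
  sdv[sdv == 0 | is.na(sdv)] <- 1
  d <- numeric(nrow(train))
  for (i in seq_len(nrow(train))) {
    s <- 0
    for (v in inputs) {
      s <- s + ((train[[v]][i] - mu[[v]]) / sdv[[v]] -
                  (query[[v]][1] - mu[[v]]) / sdv[[v]])^2
    }
    d[i] <- sqrt(s)
  }
  nb <- order(d)[1:k]
  codes <- train[[target]][nb]
  votes <- table(codes)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    sums <- sapply(top, function(cc) sum(d[nb][codes == as.integer(cc)]))
    top <- top[sums == min(sums)]
    top <- as.character(min(as.integer(top)))
  }
  as.integer(top)
}

## Independent closed-form SNR oracle from a 2x2 table: a/n1 positives in
## the UC group, b/n0 in the non-UC group, codes 1/2.
snr_from_table <- function(a, n1, b, n0) {
  p1 <- a / n1
  p0 <- b / n0
  abs(p1 - p0) / (sqrt(p1 * (1 - p1)) + sqrt(p0 * (1 - p0)))
}
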