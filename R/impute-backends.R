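#' Imputation backend configuration
#'
#' @param kind `"knn"` (personalized modelling: k-nearest neighbours on
#'   standardized inputs), `"mlr"` (global modelling: least-squares linear
#'   regression on the numeric code, rounded to the nearest valid code) or
#'   `"mlp"` (global modelling: single-hidden-layer perceptron with logistic
#'   hidden units, predicting the argmax code).
#' @param k Neighbourhood size for `knn` (the study used 3, 5 and 10).
#' @param hidden,epochs,decay MLP hyperparameters: hidden units, training
#'   iterations, weight decay.
#' @param family `"linear"` (default, as in the multiple-linear-regression
#'   description) or `"logistic"` for the logistic variant of the `mlr`
#'   backend (binomial for binary targets, multinomial for cytology).
#' @param supervised Include the clinical truth as an input variable.
#' @param seed Seed for the MLP's random weight initialization and any other
#'   randomized choice; fully determines predictions.
#' @return A list of class `dx_backend`.
#' @export
backend_config <- function(kind = c("knn", "mlr", "mlp"), k = 3L,
                           hidden = 8L, epochs = 500L, decay = 1e-4,
                           family = c("linear", "logistic"),
                           supervised = FALSE, seed = 1L) {
  kind <- match.arg(kind)
  family <- match.arg(family)
  stopifnot(k >= 1L, hidden >= 1L, epochs >= 1L)
  structure(list(kind = kind, k = as.integer(k), hidden = as.integer(hidden),
                 epochs = as.integer(epochs), decay = decay, family = family,
                 supervised = isTRUE(supervised), seed = as.integer(seed)),
            class = "dx_backend")
}

## Parse CLI-style backend labels "3nn", "5nn", "10nn", "mlr", "mlp".
parse_backend <- function(label, supervised = FALSE, seed = 1L) {
  if (grepl("^[0-9]+nn$", label)) {
    backend_config("knn", k = as.integer(sub("nn$", "", label)),
                   supervised = supervised, seed = seed)
  } else {
    backend_config(match.arg(label, c("mlr", "mlp")), supervised = supervised,
                   seed = seed)
  }
}

## Standardize a numeric input matrix on training-pool statistics; constant
## columns get scale 1 so they contribute nothing to distances.
standardize_on <- function(train_mat, mat) {
  centre <- colMeans(train_mat)
  scale <- apply(train_mat, 2, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  sweep(sweep(mat, 2, centre, "-"), 2, scale, "/")
}

input_matrix <- function(records, inputs) {
  m <- as.matrix(records[, inputs, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' k-nearest-neighbour imputation of one missing code
#'
#' Personalized-modelling backend: inputs are standardized on the training
#' pool (centred, scaled by the training standard deviation), neighbours are
#' the `k` smallest Euclidean distances (ties between equidistant training
#' records broken by training order), and the prediction is the majority
#' code among the neighbours — ties between codes broken by the smallest
#' summed neighbour distance, then by the lowest code.
#'
#' @param train Data frame of training records, non-missing on `inputs` and
#'   `target`.
#' @param query One-row data frame, non-missing on `inputs`.
#' @param inputs Character vector of input variable names.
#' @param target Name of the variable being imputed.
#' @param k Neighbourhood size; `train` must have at least `k` rows.
#' @return The predicted integer code.
#' @export
knn_impute <- function(train, query, inputs, target, k = 3L) {
  preds <- knn_impute_many(train, query, inputs, target, k)
  preds[[1L]]
}

## Vectorized kNN over several query rows.
knn_impute_many <- function(train, queries, inputs, target, k) {
  if (nrow(train) < k) {
    stop(sprintf("knn_impute: %d training record(s), need at least k = %d",
                 nrow(train), k), call. = FALSE)
  }
  tm <- input_matrix(train, inputs)
  qm <- input_matrix(queries, inputs)
  tz <- standardize_on(tm, tm)
  qz <- standardize_on(tm, qm)
  y <- train[[target]]
  vapply(seq_len(nrow(qz)), function(i) {
    d <- sqrt(colSums((t(tz) - qz[i, ])^2))
    nb <- order(d)[seq_len(k)]   # order() is stable: row order breaks ties
    codes <- y[nb]
    tab <- tapply(rep(1L, k), codes, sum)
    best <- as.integer(names(tab)[tab == max(tab)])
    if (length(best) > 1L) {
      sums <- vapply(best, function(cc) sum(d[nb][codes == cc]), numeric(1))
      best <- best[sums == min(sums)]
      best <- min(best)
    }
    as.integer(best)
  }, integer(1))
}

## Round numeric predictions to the nearest code in the target's alphabet;
## ties go to the lower code.
round_to_code <- function(pred, alphabet) {
  vapply(pred, function(p) {
    d <- abs(alphabet - p)
    alphabet[which.min(d)]
  }, alphabet[1])
}

#' Global-model imputation of missing codes
#'
#' Fits one global model on the training pool and recalls it on all query
#' records. `mlr` fits ordinary least squares of the numeric target code on
#' the inputs and rounds predictions to the nearest code of the target's
#' alphabet (a `"logistic"` family variant uses binomial regression for
#' binary targets and multinomial regression for cytology). `mlp` trains a
#' single-hidden-layer perceptron (logistic activations, seeded random
#' initialization) classifying the target code and predicts the argmax code.
#' A target that is constant in training predicts that constant for every
#' query.
#'
#' @param train Data frame, complete on `inputs` and `target`.
#' @param queries Data frame, complete on `inputs`.
#' @param inputs Character vector of input variable names.
#' @param target Name of the variable being imputed (one of the four tests).
#' @param backend A `dx_backend` of kind `"mlr"` or `"mlp"`.
#' @return Integer vector of predicted codes, one per query row.
#' @export
model_impute <- function(train, queries, inputs, target, backend) {
  stopifnot(inherits(backend, "dx_backend"), backend$kind %in% c("mlr", "mlp"))
  alphabet <- DX_ALPHABETS[[target]]
  y <- train[[target]]
  if (length(unique(y)) == 1L) {
    return(rep(as.integer(y[1L]), nrow(queries)))
  }
  tm <- as.data.frame(input_matrix(train, inputs))
  qm <- as.data.frame(input_matrix(queries, inputs))
  tm$.y <- y
  if (backend$kind == "mlr") {
    if (backend$family == "logistic") {
      if (length(alphabet) == 2L) {
        fit <- stats::glm(I(.y == max(alphabet)) ~ ., data = tm,
                          family = stats::binomial())
        p <- stats::predict(fit, newdata = qm, type = "response")
        return(as.integer(ifelse(p > 0.5, max(alphabet), min(alphabet))))
      }
      fit <- nnet::multinom(factor(.y, levels = alphabet) ~ ., data = tm,
                            trace = FALSE)
      return(as.integer(as.character(stats::predict(fit, newdata = qm))))
    }
    fit <- stats::lm(.y ~ ., data = tm)
    coefs <- stats::coef(fit)
    if (anyNA(coefs)) {
      stop(sprintf("model_impute: singular design matrix; collinear input(s): %s",
                   paste(names(coefs)[is.na(coefs)], collapse = ", ")),
           call. = FALSE)
    }
    pred <- stats::predict(fit, newdata = qm)
    return(as.integer(round_to_code(pred, alphabet)))
  }
  ## mlp: seeded weight init makes the fit deterministic
  tm$.y <- factor(y, levels = alphabet)
  fit <- with_seed(backend$seed,
                   nnet::nnet(.y ~ ., data = tm, size = backend$hidden,
                              maxit = backend$epochs, decay = backend$decay,
                              trace = FALSE))
  as.integer(as.character(stats::predict(fit, newdata = qm, type = "class")))
}

## Backend dispatch used by the plan runner and the LOO validator.
impute_with_backend <- function(train, queries, inputs, target, backend) {
  if (backend$kind == "knn") {
    knn_impute_many(train, queries, inputs, target, backend$k)
  } else {
    model_impute(train, queries, inputs, target, backend)
  }
}
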