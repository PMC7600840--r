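#' Stratified train/test split
#'
#' Splits a specimen table into training and test sets per class
#' (`species_dna`), with `ceiling(train_frac * n)` of each class in the
#' training set (rounding toward training, but always keeping at least one
#' test member per class). Train and test partition the input.
#'
#' @param records specimen data frame with a `species_dna` column.
#' @param train_frac training fraction (default 0.60).
#' @param seed integer seed.
#' @return list with data frames `train` and `test`.
#' @export
stratified_split <- function(records, train_frac = 0.6, seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  stopifnot(train_frac > 0, train_frac < 1)
  set.seed(seed)
  tr <- .split_idx(records$species_dna, train_frac)
  list(train = records[tr, , drop = FALSE],
       test = records[-tr, , drop = FALSE])
}

#' Fit a two-class linear discriminant model on malar ratios
#'
#' Gaussian linear discriminant analysis with class-specific means, a
#' pooled within-class covariance matrix (pooled by degrees of freedom) and
#' priors equal to the training class frequencies. The decision rule
#' assigns the class maximising the Gaussian log-posterior with the shared
#' covariance, i.e. the linear discriminant score
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`.
#'
#' @param train training specimen data frame with ratio columns and
#'   `species_dna` labels; exactly two classes, each with >= 2 members.
#' @param measurements character subset of `c("mr1", "mr3", "mrl")`.
#' @return an object of class `bombus_lda` with elements `measurements`,
#'   `classes`, `means` (class x measurement matrix), `cov` (pooled),
#'   `priors`, and the precomputed discriminant weights.
#' @export
fit_lda <- function(train, measurements) {
  stopifnot(is.data.frame(train), length(measurements) >= 1,
            all(measurements %in% .ratio_names))
  if (!all(measurements %in% names(train))) {
    stop("training data lack measurement column(s): ",
         paste(setdiff(measurements, names(train)), collapse = ", "),
         call. = FALSE)
  }
  y <- train$species_dna
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    stop("exactly two classes required, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(train[, measurements, drop = FALSE])
  n_k <- table(y)[classes]
  if (any(n_k < 2L)) stop("each class needs >= 2 training records", call. = FALSE)

  means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(X[y == cl, , drop = FALSE])
  }))
  dimnames(means) <- list(classes, measurements)
  pooled <- matrix(0, length(measurements), length(measurements),
                   dimnames = list(measurements, measurements))
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    pooled <- pooled + crossprod(sweep(Xc, 2, colMeans(Xc)))
  }
  pooled <- pooled / (sum(n_k) - 2L)
  Sinv <- tryCatch(solve(pooled),
                   error = function(e) stop("singular pooled covariance (collinear or degenerate measurements)",
                                            call. = FALSE))
  priors <- as.numeric(n_k) / sum(n_k)
  names(priors) <- classes
  # Linear discriminant weights: score_k(x) = x' w_k + b_k.
  W <- Sinv %*% t(means)
  b <- -0.5 * colSums(t(means) * W) + log(priors)
  structure(list(measurements = measurements, classes = classes,
                 means = means, cov = pooled, priors = priors,
                 W = W, b = b),
            class = "bombus_lda")
}

#' Predict species labels from a fitted discriminant model
#'
#' @param model a [fit_lda()] fit.
#' @param records data frame with the model's measurement columns; if a
#'   `species_dna` column is present, test accuracy against it is returned.
#' @return list with `labels` (character vector) and `accuracy` (fraction
#'   of labels matching `species_dna`, or `NA` if labels are absent).
#' @export
predict_lda <- function(model, records) {
  stopifnot(inherits(model, "bombus_lda"))
  miss <- setdiff(model$measurements, names(records))
  if (length(miss)) {
    stop("records lack measurement column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(records[, model$measurements, drop = FALSE])
  scores <- X %*% model$W + matrix(model$b, nrow(X), 2L, byrow = TRUE)
  labels <- model$classes[max.col(scores, ties.method = "first")]
  acc <- NA_real_
  if ("species_dna" %in% names(records)) {
    acc <- mean(labels == records$species_dna)
  }
  list(labels = labels, accuracy = acc)
}

# Shared one-shot split/fit/predict kernel. Retries a degenerate dataset
# (singular pooled covariance after resampling) are handled by callers.
.acc_once <- function(df, measurements, train_frac) {
  tr <- .split_idx(df$species_dna, train_frac)
  model <- fit_lda(df[tr, , drop = FALSE], measurements)
  predict_lda(model, df[-tr, , drop = FALSE])$accuracy
}

.accuracy_estimate <- function(acc, B) {
  structure(list(median = median(acc), sd = sd(acc), replicates = B,
                 per_replicate = acc),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("Bootstrap accuracy: median %.3f, SD %.3f (%d replicates)\n",
              x$median, x$sd, x$replicates))
  invisible(x)
}

#' Bootstrap estimate of classification accuracy
#'
#' Repeats, `B` times: resample the dataset with replacement stratified by
#' class (keeping the observed class counts), make a fresh stratified 60/40
#' train/test split, fit the discriminant model on the training part and
#' record its accuracy on the test part. Returns the median and SD of the
#' per-replicate accuracies. A degenerate resample whose pooled covariance
#' is singular is redrawn (with a message).
#'
#' Use `measurements = c("mr1", "mr3")` for the combined bivariate
#' classifier.
#'
#' @param records specimen data frame with ratio columns and exactly two
#'   `species_dna` classes.
#' @param measurements character subset of `c("mr1", "mr3", "mrl")`.
#' @param B number of bootstrap replicates (default 999).
#' @param train_frac training fraction (default 0.60).
#' @param seed integer seed.
#' @return an `accuracy_estimate`: list with `median`, `sd`, `replicates`,
#'   `per_replicate`.
#' @export
bootstrap_accuracy <- function(records, measurements, B = 999L,
                               train_frac = 0.6, seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  stopifnot(B >= 1L)
  set.seed(seed)
  y <- records$species_dna
  idx_by_class <- split(seq_len(nrow(records)), y)
  acc <- numeric(B)
  for (b in seq_len(B)) {
    for (try in seq_len(100L)) {
      take <- unlist(lapply(idx_by_class,
                            function(ix) sample(ix, length(ix), replace = TRUE)),
                     use.names = FALSE)
      res <- tryCatch(.acc_once(records[take, , drop = FALSE],
                                measurements, train_frac),
                      error = function(e) NULL)
      if (!is.null(res)) break
      message("degenerate resample in replicate ", b, "; redrawing")
    }
    if (is.null(res)) stop("could not draw a non-degenerate resample", call. = FALSE)
    acc[b] <- res
  }
  .accuracy_estimate(acc, B)
}

#' Accuracy under repeated simulation from calibrated parameters
#'
#' Parametric counterpart of [bootstrap_accuracy()] for when no measured
#' dataset is available: each replicate simulates a fresh two-species
#' dataset from the calibrated per-cell normal distributions (a parametric
#' bootstrap), splits it 60/40 stratified by species, fits the discriminant
#' model and records test accuracy. Returns the median and SD over
#' replicates.
#'
#' @param params parameter list from [default_species_params()].
#' @param measurements character subset of `c("mr1", "mr3", "mrl")`.
#' @param caste `"queen"` or `"worker"`: which caste's cells to simulate.
#' @param species the two species to discriminate (default sandersoni vs
#'   vagans; perplexus is excluded from discriminant analysis because hair
#'   characters already identify it).
#' @param R number of simulation replicates (default 999).
#' @param train_frac training fraction (default 0.60).
#' @param seed integer seed.
#' @return an `accuracy_estimate`.
#' @export
simulation_accuracy <- function(params = default_species_params(),
                                measurements, caste,
                                species = c("sandersoni", "vagans"),
                                R = 999L, train_frac = 0.6, seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  stopifnot(caste %in% .bombus_castes, length(species) == 2L)
  keep <- vapply(params, function(p) p$caste == caste && p$species %in% species,
                 logical(1))
  cells <- params[keep]
  if (length(cells) != 2L) stop("parameters must cover both species for the caste",
                                call. = FALSE)
  set.seed(seed)
  acc <- vapply(seq_len(R), function(r) {
    .acc_once(.sim_ratio_frame(cells), measurements, train_frac)
  }, numeric(1))
  .accuracy_estimate(acc, R)
}
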