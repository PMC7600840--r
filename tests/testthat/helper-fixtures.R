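# Small in-code fixtures shared across test files.

# Minimal valid specimen table with n rows split over two species of workers.
make_specimens <- function(n1 = 5, n2 = 5, species = c("sandersoni", "vagans"),
                           caste = "worker", mrl = c(0.75, 0.92),
                           mr1 = c(1.21, 1.46), mr3 = c(1.49, 1.83)) {
  n <- c(n1, n2)
  rows <- lapply(1:2, function(k) {
    data.frame(
      id = sprintf("%s_%02d", species[k], seq_len(n[k])),
      species_dna = species[k],
      species_visual = species[k],
      caste = caste,
      region = rep_len(c("Midwest", "Northeast"), n[k]),
      observer = "Obs1",
      malar_length = mrl[k],
      malar_width = 1,
      flag1_length = mrl[k] / mr1[k],
      flag3_length = mrl[k] / mr3[k],
      mesipisternum = "light",
      scutum_black = "many",
      t5_yellow = "few",
      t3_yellow = FALSE,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Two well-separated Gaussian classes in 1-D with explicit parameters.
make_gaussian_classes <- function(n1 = 30, n2 = 30, mu1 = 0, mu2 = 1,
                                  sd1 = 0.1, sd2 = 0.1, seed = 1,
                                  measurement = "mrl") {
  set.seed(seed)
  df <- data.frame(
    species_dna = c(rep("sandersoni", n1), rep("vagans", n2)),
    x = c(rnorm(n1, mu1, sd1), rnorm(n2, mu2, sd2)),
    stringsAsFactors = FALSE
  )
  names(df)[2] <- measurement
  df
}

# Brute-force Gaussian log-posterior LDA oracle: pooled covariance,
# explicit density evaluation per class (no discriminant shortcut).
oracle_lda_labels <- function(train, measurements, newX) {
  y <- train$species_dna
  classes <- sort(unique(y))
  X <- as.matrix(train[, measurements, drop = FALSE])
  mus <- lapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  pooled <- Reduce(`+`, lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    crossprod(sweep(Xc, 2, colMeans(Xc)))
  })) / (nrow(X) - 2)
  Sinv <- solve(pooled)
  priors <- as.numeric(table(y)[classes]) / length(y)
  logpost <- sapply(seq_along(classes), function(k) {
    d <- sweep(newX, 2, mus[[k]])
    -0.5 * rowSums((d %*% Sinv) * d) + log(priors[k])
  })
  classes[max.col(logpost, ties.method = "first")]
}
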