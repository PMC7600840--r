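#' Bootstrap mean and sample SD of a measurement vector
#'
#' The location for the predictive-range simulation: the mean is the
#' average of `B` bootstrap-replicate means; the scale is the plain sample
#' SD of the original values. (The sample SD, not the bootstrap SE of the
#' mean, is what the downstream population simulation needs: predictive
#' ranges describe bees, not the mean, and must be wider than the observed
#' range, which an SE-based spread could never be.)
#'
#' @param values numeric vector, length >= 2.
#' @param B bootstrap replicates (default 500).
#' @param seed integer seed.
#' @return list with `mean` and `sd`.
#' @export
bootstrap_mean_sd <- function(values, B = 500L, seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  if (length(values) < 2L) stop("need >= 2 values", call. = FALSE)
  set.seed(seed)
  n <- length(values)
  boot_means <- vapply(seq_len(B),
                       function(b) mean(values[sample.int(n, n, replace = TRUE)]),
                       numeric(1))
  list(mean = mean(boot_means), sd = sd(values))
}

#' Simulated central quantile range of a normal population
#'
#' Draws `n_sim` values from `Normal(mean, sd)` and returns the empirical
#' central `level` interval, i.e. the `((1-level)/2, 1-(1-level)/2)`
#' quantiles — for the default `level = 0.99`, the (0.5%, 99.5%) quantiles.
#' As `n_sim` grows this converges to `mean +/- 2.576 sd`.
#'
#' @param mean,sd normal parameters (`sd >= 0`).
#' @param n_sim simulated population size (default 10000).
#' @param level central coverage (default 0.99).
#' @param seed integer seed.
#' @return numeric vector `c(lo, hi)`.
#' @export
simulate_quantile_range <- function(mean, sd, n_sim = 10000L, level = 0.99,
                                    seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  stopifnot(sd >= 0, level > 0, level < 1)
  set.seed(seed)
  draws <- rnorm(n_sim, mean, sd)
  alpha <- (1 - level) / 2
  unname(quantile(draws, c(alpha, 1 - alpha), names = FALSE))
}

#' Observed and predicted measurement ranges per species and caste
#'
#' For every species x caste x measurement cell present in the data:
#' the sample size, the observed min and max, and a predicted central 99%
#' interval obtained by bootstrapping the cell mean
#' ([bootstrap_mean_sd()]) and then simulating a population of `n_sim`
#' bees from a normal with that mean and the cell's sample SD
#' ([simulate_quantile_range()]). Cells with fewer than 2 records keep
#' their observed range but get `NA` predicted bounds.
#'
#' @param records specimen data frame with `species_dna`, `caste` and ratio
#'   columns (computed via [compute_ratios()] if raw measurements are
#'   present instead).
#' @param B bootstrap replicates per cell (default 500).
#' @param n_sim simulated population size per cell (default 10000).
#' @param level central coverage of the predicted interval (default 0.99).
#' @param seed integer seed.
#' @return a data frame of class `range_table` with columns `species`,
#'   `caste`, `measurement`, `n`, `observed_min`, `observed_max`,
#'   `predicted_lo`, `predicted_hi`.
#' @export
build_range_table <- function(records, B = 500L, n_sim = 10000L, level = 0.99,
                              seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  if (!all(.ratio_names %in% names(records))) records <- compute_ratios(records)
  cells <- unique(records[, c("species_dna", "caste")])
  cells <- cells[order(cells$species_dna, cells$caste, method = "radix"), ,
                 drop = FALSE]
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    sub <- records[records$species_dna == cells$species_dna[i] &
                     records$caste == cells$caste[i], , drop = FALSE]
    for (m in .ratio_names) {
      v <- sub[[m]]
      k <- k + 1L
      pred <- c(NA_real_, NA_real_)
      if (length(v) >= 2L) {
        bs <- bootstrap_mean_sd(v, B = B, seed = seed + k)
        pred <- simulate_quantile_range(bs$mean, bs$sd, n_sim = n_sim,
                                        level = level, seed = seed + 10000L + k)
      }
      rows[[k]] <- data.frame(
        species = cells$species_dna[i], caste = cells$caste[i], measurement = m,
        n = length(v), observed_min = min(v), observed_max = max(v),
        predicted_lo = pred[1], predicted_hi = pred[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("range_table", "data.frame")
  out
}

#' Identify candidate species from ratio ranges and hair characters
#'
#' Range-based identification: a species remains a candidate if every
#' supplied (non-`NA`) ratio lies inside its predicted 99% interval for the
#' given caste (falling back to the observed range where no predicted
#' interval is available). Hair-colour rules are then applied:
#' \enumerate{
#'   \item dark hairs on the lower mesipisternum (`"dark"` or
#'     `"dark-light"`) are diagnostic for *B. perplexus* — the candidate
#'     set becomes `{perplexus}` regardless of ratio overlap;
#'   \item many black scutum hairs exclude *B. perplexus* (its scutum has
#'     at most a few);
#'   \item yellow hairs on T3 favour light-form *B. perplexus* — it is
#'     moved to the front of the candidate set.
#' }
#' An empty candidate set is a valid result meaning "ambiguous/none".
#'
#' @param ratios named numeric vector or list with any of `mr1`, `mr3`,
#'   `mrl`; `NA` entries are skipped.
#' @param hair list with any of `mesipisternum`, `scutum_black`,
#'   `t5_yellow`, `t3_yellow` (unknown/missing fields are skipped).
#' @param caste `"queen"` or `"worker"`.
#' @param table a [build_range_table()] result covering the caste.
#' @return list of class `range_id` with `candidates` (character vector,
#'   possibly empty) and `rationale` (character vector of rule firings).
#' @export
classify_by_ranges <- function(ratios, hair = list(), caste, table) {
  stopifnot(inherits(table, "range_table"), caste %in% .bombus_castes)
  tab <- table[table$caste == caste, , drop = FALSE]
  if (nrow(tab) == 0L) stop("range table does not cover caste ", caste, call. = FALSE)
  ratios <- as.list(ratios)
  rationale <- character(0)
  candidates <- character(0)
  for (sp in unique(tab$species)) {
    inside <- TRUE
    for (m in intersect(names(ratios), .ratio_names)) {
      x <- ratios[[m]]
      if (is.null(x) || is.na(x)) next
      row <- tab[tab$species == sp & tab$measurement == m, , drop = FALSE]
      if (nrow(row) == 0L) next
      lo <- row$predicted_lo; hi <- row$predicted_hi
      src <- "predicted"
      if (is.na(lo) || is.na(hi)) {
        lo <- row$observed_min; hi <- row$observed_max; src <- "observed"
      }
      ok <- x >= lo && x <= hi
      rationale <- c(rationale, sprintf(
        "%s: %s=%.3f %s %s interval [%.3f, %.3f]",
        sp, m, x, if (ok) "inside" else "outside", src, lo, hi))
      if (!ok) inside <- FALSE
    }
    if (inside) candidates <- c(candidates, sp)
  }
  candidates <- sort(candidates)

  mesi <- hair$mesipisternum
  if (!is.null(mesi) && mesi %in% c("dark", "dark-light")) {
    candidates <- "perplexus"
    rationale <- c(rationale,
                   "dark hairs on lower mesipisternum: diagnostic for perplexus")
  } else {
    if (!is.null(hair$scutum_black) && identical(hair$scutum_black, "many") &&
        "perplexus" %in% candidates) {
      candidates <- setdiff(candidates, "perplexus")
      rationale <- c(rationale,
                     "many black scutum hairs: perplexus excluded (has none or few)")
    }
    if (isTRUE(hair$t3_yellow) && "perplexus" %in% candidates) {
      candidates <- c("perplexus", setdiff(candidates, "perplexus"))
      rationale <- c(rationale,
                     "yellow hairs on T3: favours light-form perplexus")
    }
  }
  if (length(rationale) == 0L) rationale <- "no applicable ratio or hair rule"
  structure(list(candidates = candidates, rationale = rationale),
            class = "range_id")
}

#' @export
print.range_id <- function(x, ...) {
  cat("Candidate species:",
      if (length(x$candidates)) paste(x$candidates, collapse = ", ")
      else "(none - ambiguous)", "\n")
  cat(paste0("  - ", x$rationale, collapse = "\n"), "\n")
  invisible(x)
}
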