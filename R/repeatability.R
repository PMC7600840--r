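#' Pearson correlation test
#'
#' Sample Pearson correlation with its t statistic on `n - 2` degrees of
#' freedom and two-sided p-value (`t = r * sqrt(df) / sqrt(1 - r^2)`),
#' via [stats::cor.test()]. Zero variance in either input is an error.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return one-row data frame with `r`, `t`, `df`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in x or y; correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), t = unname(ct$statistic),
             df = unname(ct$parameter), p = ct$p.value, n = length(x))
}

# Per-specimen mean and SD over replicate measurements of one ratio.
# Specimens with fewer than 2 non-missing replicates are excluded with a
# message.
.replicate_summary <- function(replicates, measurement) {
  v <- replicates[[measurement]]
  sp <- split(v[!is.na(v)], replicates$id[!is.na(v)])
  n_rep <- lengths(sp)
  if (any(n_rep < 2L)) {
    message(sum(n_rep < 2L),
            " specimen(s) with a single replicate excluded from SD-vs-mean")
    sp <- sp[n_rep >= 2L]
  }
  data.frame(id = names(sp),
             mean = vapply(sp, mean, numeric(1)),
             sd = vapply(sp, sd, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Association between replicate SD and replicate mean
#'
#' Tests whether measurement precision depends on measurement size: per
#' specimen, the mean and SD of its replicate measurements are computed and
#' their Pearson correlation is returned. A negative correlation indicates
#' measurements become less repeatable as the structure gets smaller.
#'
#' @param replicates long replicate table (`id`, `observer`, `rep`, ratio
#'   columns), optionally pre-filtered to the observers of interest.
#' @param measurement one of `"mr1"`, `"mr3"`, `"mrl"`.
#' @return one-row data frame as from [pearson_test()].
#' @export
sd_vs_mean <- function(replicates, measurement = c("mr1", "mr3", "mrl")) {
  measurement <- match.arg(measurement)
  s <- .replicate_summary(replicates, measurement)
  if (nrow(s) < 3L) stop("fewer than 3 specimens with replicates", call. = FALSE)
  pearson_test(s$mean, s$sd)
}

#' Observer repeatability report
#'
#' Builds the full repeatability table for a replicate measurement set:
#' \itemize{
#'   \item `Within <obs>`: correlation between an observer's first and
#'     second replicate across specimens;
#'   \item `Between <obsA> vs <obsB>`: correlation between the two
#'     observers' per-specimen replicate means;
#'   \item `SD vs mean (<obsA> vs <obsB>)`: correlation between the
#'     per-specimen SD and mean of the pooled replicates of the pair.
#' }
#' A comparison whose measurement is entirely missing for an observer
#' (e.g. an observer who never measured MRL) yields a row of `NA`s rather
#' than an error.
#'
#' @param replicates long replicate table with columns `id`, `observer`,
#'   `rep` and measurement columns.
#' @param measurements measurement columns to report (default all three
#'   ratios).
#' @return data frame with `comparison`, `measurement`, `r`, `t`, `df`,
#'   `p`, `n`.
#' @export
repeatability_report <- function(replicates,
                                 measurements = c("mr1", "mr3", "mrl")) {
  stopifnot(all(c("id", "observer", "rep") %in% names(replicates)),
            all(measurements %in% names(replicates)))
  observers <- sort(unique(replicates$observer))
  na_row <- function(comparison, m) {
    data.frame(comparison = comparison, measurement = m, r = NA_real_,
               t = NA_real_, df = NA_real_, p = NA_real_, n = NA_integer_,
               stringsAsFactors = FALSE)
  }
  with_result <- function(comparison, m, expr) {
    res <- tryCatch(expr, error = function(e) NULL)
    if (is.null(res)) return(na_row(comparison, m))
    data.frame(comparison = comparison, measurement = m, res,
               stringsAsFactors = FALSE)
  }
  rep_matrix <- function(sub, m) {
    # specimens x replicates matrix of one observer's measurements
    ids <- sort(unique(sub$id))
    reps <- sort(unique(sub$rep))
    out <- matrix(NA_real_, length(ids), length(reps),
                  dimnames = list(ids, reps))
    out[cbind(match(sub$id, ids), match(sub$rep, reps))] <- sub[[m]]
    out
  }

  rows <- list()
  for (m in measurements) {
    for (o in observers) {
      sub <- replicates[replicates$observer == o, , drop = FALSE]
      rows[[length(rows) + 1L]] <- with_result(paste("Within", o), m, {
        rm_ <- rep_matrix(sub, m)
        if (ncol(rm_) < 2L) stop("single replicate")
        pearson_test(rm_[, 1], rm_[, 2])
      })
    }
    if (length(observers) >= 2L) {
      pairs <- utils::combn(observers, 2)
      for (j in seq_len(ncol(pairs))) {
        oa <- pairs[1, j]; ob <- pairs[2, j]
        suba <- replicates[replicates$observer == oa, , drop = FALSE]
        subb <- replicates[replicates$observer == ob, , drop = FALSE]
        comparison <- paste("Between", oa, "vs", ob)
        rows[[length(rows) + 1L]] <- with_result(comparison, m, {
          ma <- rowMeans(rep_matrix(suba, m), na.rm = TRUE)
          mb <- rowMeans(rep_matrix(subb, m), na.rm = TRUE)
          ids <- intersect(names(ma)[is.finite(ma)], names(mb)[is.finite(mb)])
          pearson_test(ma[ids], mb[ids])
        })
        rows[[length(rows) + 1L]] <- with_result(
          paste0("SD vs mean (", oa, " vs ", ob, ")"), m, {
            if (all(is.na(suba[[m]])) || all(is.na(subb[[m]]))) {
              stop("measurement absent for one observer of the pair")
            }
            sd_vs_mean(replicates[replicates$observer %in% c(oa, ob), ,
                                  drop = FALSE], m)
          })
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
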