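#' Gaussian linear model for a malar ratio
#'
#' Ordinary least squares for one ratio response on treatment-coded factors
#' for species (DNA-confirmed), caste and region, optionally with
#' species:caste and species:region interactions. A Gaussian GLM with
#' identity link is exactly OLS, so `lm()` is the engine. Reference levels
#' are fixed (species `perplexus`, caste `queen`, region `Midwest`) so
#' coefficients are comparable across fits; with 115 specimens the
#' main-effects model has 110 residual degrees of freedom.
#'
#' @param records specimen data frame with ratio columns, `species_dna`,
#'   `caste` and `region`.
#' @param response one of `"mr1"`, `"mr3"`, `"mrl"`.
#' @param interactions include species:caste and species:region terms
#'   (default `TRUE`; prune with [anova_and_prune()]).
#' @return an `lm` fit (with the model data embedded) whose formula uses
#'   factors `species`, `caste`, `region`.
#' @export
fit_ratio_model <- function(records, response = c("mr1", "mr3", "mrl"),
                            interactions = TRUE) {
  response <- match.arg(response)
  if (!response %in% names(records)) records <- compute_ratios(records)
  dat <- data.frame(
    y = records[[response]],
    species = factor(records$species_dna, levels = .bombus_species),
    caste = factor(records$caste, levels = .bombus_castes),
    region = factor(records$region, levels = .bombus_regions)
  )
  dat <- droplevels(dat)
  names(dat)[1] <- response
  terms_used <- c("species", "caste", "region")[
    vapply(dat[c("species", "caste", "region")], nlevels, 0L) >= 2L]
  if (length(terms_used) == 0L) stop("no factor with >= 2 levels", call. = FALSE)
  rhs <- terms_used
  if (interactions && "species" %in% terms_used) {
    rhs <- c(rhs, paste0("species:", intersect(c("caste", "region"), terms_used)))
  }
  f <- as.formula(paste(response, "~", paste(rhs, collapse = " + ")),
                  env = globalenv())
  # Embed the data in the call so the fit is self-contained: update(),
  # car::Anova() and emmeans can re-evaluate it in any environment.
  fit <- do.call(stats::lm, list(formula = f, data = dat))
  if (any(is.na(coef(fit)))) stop("rank-deficient design", call. = FALSE)
  fit
}

#' Type II ANOVA with interaction pruning
#'
#' Computes marginal (Type II) F tests for every term of a [fit_ratio_model()]
#' fit, drops interaction terms whose p-value exceeds `alpha`, refits, and
#' returns the final fit together with its ANOVA table. Type II sums of
#' squares are used because the study design is unbalanced; on balanced
#' data they coincide with sequential tests.
#'
#' @param fit an `lm` from [fit_ratio_model()].
#' @param alpha pruning threshold for interaction p-values (default 0.05).
#' @return list with `fit` (final `lm`) and `anova` (data frame with
#'   `term`, `df_num`, `df_den`, `F`, `p` for the final model).
#' @export
anova_and_prune <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lm"))
  to_table <- function(f) {
    a <- car::Anova(f, type = 2)
    keep <- rownames(a) != "Residuals"
    data.frame(term = rownames(a)[keep],
               df_num = a$Df[keep],
               df_den = df.residual(f),
               F = a$`F value`[keep],
               p = a$`Pr(>F)`[keep],
               stringsAsFactors = FALSE)
  }
  tab <- to_table(fit)
  inter <- grepl(":", tab$term)
  drop_terms <- tab$term[inter & tab$p > alpha]
  if (length(drop_terms)) {
    f2 <- as.formula(paste(". ~ . -", paste(drop_terms, collapse = " - ")))
    fit <- update(fit, f2)
    tab <- to_table(fit)
  }
  list(fit = fit, anova = tab)
}

# Factor levels actually used by a fit, as a named list.
.fit_levels <- function(fit) {
  fit$xlevels
}

# Equal-weight averaging matrix over a reference grid: rows of the model
# matrix for every factor combination, averaged over the factors not in
# `by`. Returns list(L, grid) where grid has one row per kept combination.
.emm_lmat <- function(fit, by) {
  lv <- .fit_levels(fit)
  grid <- expand.grid(lv, stringsAsFactors = TRUE)
  X <- model.matrix(delete.response(terms(fit)), grid)
  key_df <- grid[, by, drop = FALSE]
  key <- do.call(paste, c(lapply(key_df, as.character), sep = "\r"))
  ukey <- unique(key)
  L <- t(vapply(ukey, function(k) colMeans(X[key == k, , drop = FALSE]),
                numeric(ncol(X))))
  out_grid <- key_df[match(ukey, key), , drop = FALSE]
  out_grid[] <- lapply(out_grid, as.character)
  rownames(L) <- NULL
  rownames(out_grid) <- NULL
  list(L = L, grid = out_grid)
}

#' Estimated marginal means by species and caste
#'
#' Model-based means for every species x caste combination, averaged with
#' equal weight over the levels of region (not by observed frequencies).
#' Standard errors come from the coefficient covariance (delta method on
#' the linear combination); 95% confidence limits use the t distribution
#' on the residual degrees of freedom.
#'
#' @param fit an `lm` from [fit_ratio_model()] (typically after
#'   [anova_and_prune()]).
#' @param level confidence level (default 0.95).
#' @return data frame with `species`, `caste`, `mean`, `se`, `lo`, `hi`.
#' @export
estimated_marginal_means <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "lm"))
  by <- intersect(c("species", "caste"), names(.fit_levels(fit)))
  lm_ <- .emm_lmat(fit, by)
  est <- drop(lm_$L %*% coef(fit))
  se <- sqrt(diag(lm_$L %*% vcov(fit) %*% t(lm_$L)))
  tq <- stats::qt(1 - (1 - level) / 2, df.residual(fit))
  out <- data.frame(lm_$grid, mean = est, se = se,
                    lo = est - tq * se, hi = est + tq * se,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tukey-adjusted pairwise contrasts of marginal means
#'
#' All pairwise differences of the estimated marginal means of one factor
#' (averaged with equal weight over every other factor in the model), with
#' t statistics on the residual degrees of freedom and p-values adjusted
#' for multiple comparison by the studentized-range (Tukey HSD)
#' distribution: `p = P(q_{k, df} >= |t| * sqrt(2))`. With `k = 2` levels
#' this reduces to the unadjusted two-sided t-test.
#'
#' @param fit an `lm` from [fit_ratio_model()].
#' @param factor name of the factor to contrast (default `"species"`).
#' @return data frame with `contrast`, `estimate`, `se`, `df`, `t`,
#'   `p_tukey`; contrasts are `levelA-levelB` in level order, so the
#'   estimate of `A-B` is minus that of `B-A`.
#' @export
tukey_pairwise <- function(fit, factor = "species") {
  stopifnot(inherits(fit, "lm"))
  lv <- .fit_levels(fit)
  if (!factor %in% names(lv)) stop("factor not in model: ", factor, call. = FALSE)
  k <- length(lv[[factor]])
  if (k < 2L) stop("factor needs >= 2 levels", call. = FALSE)
  lm_ <- .emm_lmat(fit, factor)
  # order rows by level order
  ord <- match(lv[[factor]], as.character(lm_$grid[[factor]]))
  L <- lm_$L[ord, , drop = FALSE]
  V <- vcov(fit)
  beta <- coef(fit)
  df <- df.residual(fit)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    cvec <- L[ij[1], ] - L[ij[2], ]
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    p <- ptukey(sqrt(2) * abs(tval), nmeans = k, df = df, lower.tail = FALSE)
    data.frame(contrast = paste(lv[[factor]][ij[1]], lv[[factor]][ij[2]],
                                sep = "-"),
               estimate = est, se = se, df = df, t = tval, p_tukey = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
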