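# Population structure (dosage PCA + k-means) and marker-trait association
# (additive / dominant linear models with step-up FDR control).

#' Principal component analysis of dosage genotypes
#'
#' Centred, unscaled PCA of the samples-by-sites dosage matrix: genotype
#' scores are all in allele-copy-number units, so no scaling is applied.
#' Requires fully-called sites (no missing cells); filter with
#' `rowSums(is.na(d)) == 0` first.
#'
#' @param x a `genotype_matrix` or dosage matrix (sites x samples).
#' @return List with `scores` (samples x components), `variance_fraction`
#'   (per component, of total variance), and the `prcomp` fit. A matrix
#'   with zero total variance returns an empty result.
#' @export
pca_dosage <- function(x) {
  d <- .dosage_matrix(x)
  if (anyNA(d)) {
    stop_param("dosage matrix has missing cells; restrict to fully-called ",
               "sites (rowSums(is.na(d)) == 0) before PCA")
  }
  X <- t(d)
  if (all(apply(X, 2, var) == 0)) {
    return(list(scores = matrix(numeric(0), nrow(X), 0),
                variance_fraction = numeric(0), fit = NULL))
  }
  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = fit$x,
       variance_fraction = fit$sdev^2 / sum(fit$sdev^2),
       fit = fit)
}

#' Group samples by k-means on leading principal components
#'
#' Runs `stats::kmeans` with multiple restarts on the first `n_components`
#' PCA scores; deterministic given the seed (best inertia over restarts).
#'
#' @param scores samples x components score matrix from [pca_dosage()].
#' @param k number of groups.
#' @param n_components leading components used (default 3).
#' @param seed integer seed.
#' @param nstart random restarts.
#' @return List with `groups` (integer labels), `inertia` (total
#'   within-cluster sum of squares) and the `kmeans` fit.
#' @export
kmeans_groups <- function(scores, k = 5, n_components = 3, seed = 1,
                          nstart = 25) {
  if (k > nrow(scores)) stop_param("'k' exceeds the number of samples")
  if (k == nrow(scores)) {
    # degenerate: every sample its own group
    return(list(groups = seq_len(k), inertia = 0, fit = NULL))
  }
  nc <- min(n_components, ncol(scores))
  fit <- withr::with_seed(seed, {
    kmeans(scores[, seq_len(nc), drop = FALSE], centers = k, nstart = nstart)
  })
  list(groups = fit$cluster, inertia = fit$tot.withinss, fit = fit)
}

# Shared per-variant OLS scan. design_fun maps a dosage vector to the
# tested regressor.
.assoc_scan <- function(dosages, phenotype, covariates, design_fun, model_tag) {
  d <- if (is.matrix(dosages)) dosages else matrix(dosages, nrow = 1)
  if (length(phenotype) != ncol(d)) {
    stop_param("'phenotype' length must equal the number of samples")
  }
  cov <- NULL
  if (!is.null(covariates)) {
    cov <- as.matrix(covariates)
    if (nrow(cov) != ncol(d)) stop_param("covariate rows must match samples")
  }
  site_ids <- if (!is.null(rownames(d))) rownames(d)
              else sprintf("site_%05d", seq_len(nrow(d)))
  out <- data.frame(site_id = site_ids, effect = NA_real_, se = NA_real_,
                    p = NA_real_, r_squared = NA_real_, n = NA_integer_,
                    skipped = FALSE, model = model_tag,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(d))) {
    g <- design_fun(d[i, ])
    keep <- !is.na(g) & !is.na(phenotype)
    if (!is.null(cov)) keep <- keep & complete.cases(cov)
    n <- sum(keep)
    if (n < 3 || var(g[keep]) == 0) {
      out$skipped[i] <- TRUE
      next
    }
    X <- cbind(1, if (is.null(cov)) NULL else cov[keep, , drop = FALSE],
               g[keep])
    y <- phenotype[keep]
    fit <- lm.fit(X, y)
    df <- n - fit$rank
    if (df < 1 || is.na(fit$coefficients[ncol(X)])) {
      out$skipped[i] <- TRUE
      next
    }
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / df
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * xtx_inv[ncol(X), ncol(X)])
    beta <- fit$coefficients[ncol(X)]
    tss <- sum((y - mean(y))^2)
    out$effect[i] <- beta
    out$se[i] <- se
    out$p[i] <- if (se == 0) 0 else 2 * pt(abs(beta / se), df, lower.tail = FALSE)
    out$r_squared[i] <- if (tss == 0) 0 else 1 - rss / tss
    out$n[i] <- n
  }
  out$p_adjusted <- NA_real_
  tested <- !out$skipped
  out$p_adjusted[tested] <- fdr_adjust(out$p[tested])
  out$neg_log10_p_adjusted <- -log10(out$p_adjusted)
  out
}

#' Additive dosage association scan
#'
#' Per variant, ordinary least squares of the phenotype on allele copy
#' number (0-4), optionally adjusted for population-structure covariates
#' (e.g. indicator columns for the k-means groups):
#' `response = allele copy number (+ structure) + error`. Two-sided p from
#' the slope t-statistic; `r_squared` is the full-model fraction of
#' phenotypic variance. Variants with fewer than 3 complete pairs or
#' constant dosage are skipped with a flag. Adjusted p-values
#' ([fdr_adjust()]) are computed over the tested variants.
#'
#' @param dosages sites x samples dosage matrix (or one vector); `NA`
#'   cells are dropped pairwise.
#' @param phenotype numeric phenotype vector, one value per sample.
#' @param covariates optional numeric matrix of structure covariates
#'   (samples in rows). Factor group labels should be expanded to
#'   indicators with [stats::model.matrix()] first.
#' @return data.frame with `site_id`, `effect` (phenotype units per allele
#'   copy), `se`, `p`, `r_squared`, `n`, `skipped`, `model`, `p_adjusted`,
#'   `neg_log10_p_adjusted`.
#' @export
assoc_additive <- function(dosages, phenotype, covariates = NULL) {
  .assoc_scan(dosages, phenotype, covariates, identity, "additive")
}

#' Dominant (presence/absence) association scan
#'
#' As [assoc_additive()] but with dosage recoded to carrier status
#' (`dosage >= 1` becomes 1): the simplistic dominant model that works well
#' when most variants are rare, since a rare allele is almost always absent
#' or simplex.
#'
#' @inheritParams assoc_additive
#' @export
assoc_dominant <- function(dosages, phenotype, covariates = NULL) {
  .assoc_scan(dosages, phenotype, covariates,
              function(g) as.numeric(g >= 1), "dominant")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' The step-up false-discovery-rate procedure: rank the p-values
#' ascending, scale `p_(i)` by `n/i`, enforce monotonicity from the largest
#' rank downward, and clip at 1. `NA`s are preserved and do not count
#' toward `n`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0) return(out)
  check_prob(p[ok], "p")
  n <- length(ok)
  o <- order(p[ok])
  scaled <- p[ok][o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out[ok[o]] <- adj
  out
}
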