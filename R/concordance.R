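# Validation of sequencing dosage calls against an orthogonal assay:
# 5x5 concordance tables, het/hom collapse, GQ threshold tuning, duplicate
# assay error rate, and validation SNP panel selection.

.pair_calls <- function(observed, expected) {
  need <- c("site_id", "sample_id", "dosage")
  if (!all(need %in% names(observed)) || !all(need %in% names(expected))) {
    stop_param("'observed'/'expected' need columns site_id, sample_id, dosage")
  }
  m <- merge(observed, expected, by = c("site_id", "sample_id"),
             suffixes = c("_obs", "_exp"))
  if (nrow(m) == 0) stop_param("no overlapping (site, sample) pairs")
  m
}

#' Cross-tabulate observed vs expected dosage calls
#'
#' Pairs the two call sets by `(site_id, sample_id)` and builds the 5x5
#' concordance table (rows = observed, columns = expected) with per
#' expected-class concordant/discordant counts, percentages to one decimal,
#' and -- when the observed calls carry them -- median depths and mean
#' alternate-read fractions of concordant and discordant calls. Missing
#' observed calls (`NA` dosage) are excluded from the table and counted in
#' `n_missing`.
#'
#' @param observed data.frame with `site_id`, `sample_id`, `dosage`, and
#'   optionally `depth` and `alt_frac`.
#' @param expected data.frame with `site_id`, `sample_id`, `dosage`.
#' @return An object of class `concordance_table`; see
#'   [concordance_rates()] for the rate arithmetic alone.
#' @export
concordance_table <- function(observed, expected) {
  m <- .pair_calls(observed, expected)
  n_missing <- sum(is.na(m$dosage_obs))
  m <- m[!is.na(m$dosage_obs), ]
  if (nrow(m) == 0) stop_param("all observed calls are missing")
  counts <- table(factor(m$dosage_obs, levels = DOSAGES),
                  factor(m$dosage_exp, levels = DOSAGES))
  conc <- diag(counts)
  disc <- colSums(counts) - conc
  per_class <- data.frame(
    expected_class = DOSAGES,
    concordant = as.integer(conc),
    discordant = as.integer(disc),
    pct_concordant = concordance_rates(conc, disc)$per_class
  )
  is_conc <- m$dosage_obs == m$dosage_exp
  summarise_by <- function(value, subset, fun) {
    vapply(DOSAGES, function(g) {
      v <- value[subset & m$dosage_exp == g]
      if (length(v) == 0) NA_real_ else fun(v, na.rm = TRUE)
    }, numeric(1))
  }
  if ("depth" %in% names(m)) {
    per_class$median_depth_concordant <- summarise_by(m$depth, is_conc, median)
    per_class$median_depth_discordant <- summarise_by(m$depth, !is_conc, median)
  }
  if ("alt_frac" %in% names(m)) {
    per_class$mean_alt_frac_concordant <- summarise_by(m$alt_frac, is_conc, mean)
    per_class$mean_alt_frac_discordant <- summarise_by(m$alt_frac, !is_conc, mean)
  }
  structure(list(counts = unclass(counts),
                 per_class = per_class,
                 overall_pct = concordance_rates(conc, disc)$overall,
                 n_pairs = nrow(m), n_missing = n_missing),
            class = "concordance_table")
}

#' Concordance percentage arithmetic
#'
#' Pure rate computation over per-class concordant/discordant counts:
#' per-class and overall percentages of concordant calls, to one decimal.
#'
#' @param concordant,discordant integer vectors of per-class counts.
#' @return List with `per_class` (percentages) and `overall`.
#' @examples
#' concordance_rates(c(4975, 4861, 2204, 1373, 1272),
#'                   c(67, 25, 86, 34, 25))
#' @export
concordance_rates <- function(concordant, discordant) {
  if (length(concordant) != length(discordant)) {
    stop_param("count vectors differ in length")
  }
  total <- concordant + discordant
  list(per_class = round(100 * concordant / total, 1),
       overall = round(100 * sum(concordant) / sum(total), 1))
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("<concordance_table> %d pairs (%d missing excluded)\n",
              x$n_pairs, x$n_missing))
  print(x$per_class, row.names = FALSE)
  cat(sprintf("overall concordance: %.1f%%\n", x$overall_pct))
  invisible(x)
}

#' Collapse dosage concordance to heterozygous/homozygous
#'
#' Dosage classes 0 and 4 are homozygous; 1, 2 and 3 heterozygous. A
#' duplex call observed where simplex was expected is concordant under this
#' collapse even though it is discordant in the 5-class table.
#'
#' @inheritParams concordance_table
#' @return List with the 2x2 `counts` (observed x expected), `per_class`
#'   percentages and `overall_pct`.
#' @export
collapse_het_hom <- function(observed, expected) {
  m <- .pair_calls(observed, expected)
  m <- m[!is.na(m$dosage_obs), ]
  zyg <- function(d) ifelse(d %in% c(0, PLOIDY), "hom", "het")
  counts <- table(factor(zyg(m$dosage_obs), levels = c("hom", "het")),
                  factor(zyg(m$dosage_exp), levels = c("hom", "het")))
  conc <- diag(counts)
  disc <- colSums(counts) - conc
  rates <- concordance_rates(conc, disc)
  list(counts = unclass(counts),
       per_class = setNames(rates$per_class, c("hom", "het")),
       overall_pct = rates$overall)
}

#' Tune the genotype-quality threshold on validation data
#'
#' Scans integer GQ thresholds and returns the smallest threshold at which
#' the discordance rate of the target expected class (among calls passing
#' the threshold) falls strictly below `max_discordance`. Duplex -- the
#' hardest class to resolve by read counts -- is the conventional target.
#'
#' @param observed data.frame with `site_id`, `sample_id`, `dosage`, `gq`.
#' @param expected data.frame with `site_id`, `sample_id`, `dosage`.
#' @param target_class expected dosage class to control (default 2, duplex).
#' @param max_discordance tolerated discordance fraction (strict `<`).
#' @param gq_grid integer thresholds to scan.
#' @return List with `threshold` (integer, or `NA` if unattainable) and
#'   `trace` (data.frame `threshold`, `n`, `discordance`).
#' @export
tune_gq_threshold <- function(observed, expected, target_class = 2,
                              max_discordance = 0.05, gq_grid = 0:99) {
  if (!"gq" %in% names(observed)) stop_param("'observed' must carry a gq column")
  m <- .pair_calls(observed, expected)
  m <- m[!is.na(m$dosage_obs) & m$dosage_exp == target_class, ]
  if (nrow(m) == 0) stop_param("no calls with the target expected class")
  trace <- do.call(rbind, lapply(gq_grid, function(t) {
    sel <- m$gq >= t
    data.frame(threshold = t, n = sum(sel),
               discordance = if (any(sel)) {
                 mean(m$dosage_obs[sel] != m$dosage_exp[sel])
               } else NA_real_)
  }))
  ok <- !is.na(trace$discordance) & trace$discordance < max_discordance
  list(threshold = if (any(ok)) trace$threshold[which(ok)[1]] else NA_integer_,
       trace = trace)
}

#' Duplicate-assay error rate
#'
#' Discordance between two independent assays of the same (site, sample)
#' pairs, reported as a percentage to one decimal. Two discordant calls
#' among 2 x 270 duplicated genotypes give 0.4%.
#'
#' @param call1,call2 paired dosage call vectors.
#' @return List with `percent`, `n_pairs`, `n_discordant`.
#' @export
duplicate_error_rate <- function(call1, call2) {
  if (length(call1) != length(call2)) stop_param("paired vectors differ in length")
  if (length(call1) == 0) stop_param("no duplicate pairs")
  n_disc <- sum(call1 != call2)
  list(percent = round(100 * n_disc / length(call1), 1),
       n_pairs = length(call1), n_discordant = n_disc)
}

#' Select an uncorrelated validation SNP panel
#'
#' Filters sites to a minor-allele-frequency window, computes pairwise `r^2`
#' between dosage vectors (squared Pearson correlation, pairwise-complete
#' observations), clusters sites by complete-linkage hierarchical clustering
#' on `1 - r^2`, cuts the tree so that every within-cluster pair has
#' `r^2 >= r2_threshold`, and keeps one representative per cluster (highest
#' call rate, ties broken by site order). One site is kept from each such
#' haplotype-block-like cluster so panel SNPs are mutually near-independent.
#'
#' @param x a `genotype_matrix` or dosage matrix.
#' @param maf_low,maf_high inclusive MAF window (defaults 0.15-0.35).
#' @param r2_threshold within-cluster correlation defining redundancy.
#' @param panel_size optional cap on the panel (first `panel_size`
#'   representatives in site order).
#' @return List of class `validation_panel`: `sites` (selected site ids),
#'   `maf_window`, `r2_threshold`, `clusters` (cluster id per window site).
#' @export
select_validation_snps <- function(x, maf_low = 0.15, maf_high = 0.35,
                                   r2_threshold = 0.16, panel_size = NULL) {
  d <- .dosage_matrix(x)
  af <- allele_frequencies(d)
  in_window <- !is.na(af$maf) & af$maf >= maf_low & af$maf <= maf_high
  ids <- af$site_id[in_window]
  if (length(ids) == 0) {
    warning("no sites in the MAF window; empty panel")
    return(structure(list(sites = character(0),
                          maf_window = c(maf_low, maf_high),
                          r2_threshold = r2_threshold, clusters = integer(0)),
                     class = "validation_panel"))
  }
  dw <- d[in_window, , drop = FALSE]
  if (length(ids) == 1) {
    cl <- setNames(1L, ids)
  } else {
    r2 <- suppressWarnings(cor(t(dw), use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0  # undefined correlations treated as independence
    h <- hclust(as.dist(1 - r2), method = "complete")
    cl <- cutree(h, h = 1 - r2_threshold)
    names(cl) <- ids
  }
  call_rate <- rowMeans(!is.na(dw))
  reps <- vapply(sort(unique(cl)), function(k) {
    members <- which(cl == k)
    members[which.max(call_rate[members])]  # ties -> first, i.e. site order
  }, integer(1))
  reps <- sort(reps)
  sites <- ids[reps]
  if (!is.null(panel_size) && length(sites) > panel_size) {
    sites <- sites[seq_len(panel_size)]
  }
  structure(list(sites = sites, maf_window = c(maf_low, maf_high),
                 r2_threshold = r2_threshold, clusters = cl),
            class = "validation_panel")
}

#' @export
print.validation_panel <- function(x, ...) {
  cat(sprintf("<validation_panel> %d SNPs, MAF [%.2f, %.2f], r2 >= %.2f\n",
              length(x$sites), x$maf_window[1], x$maf_window[2],
              x$r2_threshold))
  invisible(x)
}
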