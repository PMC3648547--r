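# Population-genetic summaries over a called dosage matrix: allele
# frequencies, MAF spectrum, gene diversity, nucleotide diversity by
# region/annotation, saturation curves, Ts/Tv, sample-unique variants and
# tetraploid Hardy-Weinberg expectations.

.dosage_matrix <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x$dosage)
  if (is.matrix(x)) return(x)
  stop_param("expected a genotype_matrix or a dosage matrix")
}

#' Per-site alternate-allele frequencies from dosage calls
#'
#' `q = sum(dosage) / (4 * n_called)` over the called (non-missing) cells of
#' each site; missing cells are excluded from both numerator and
#' denominator. Sites with zero calls get `NA` and are excluded from
#' downstream spectra. Sites called in fewer than half the samples are
#' flagged (`low_call_rate`).
#'
#' @param x a `genotype_matrix` or an integer dosage matrix (sites x
#'   samples, `NA` = missing).
#' @return data.frame with columns `site_id`, `q`, `maf`, `n_called`,
#'   `low_call_rate`.
#' @export
allele_frequencies <- function(x) {
  d <- .dosage_matrix(x)
  n_called <- rowSums(!is.na(d))
  q <- ifelse(n_called > 0, rowSums(d, na.rm = TRUE) / (PLOIDY * n_called), NA)
  data.frame(
    site_id = if (!is.null(rownames(d))) rownames(d)
              else sprintf("site_%05d", seq_len(nrow(d))),
    q = q,
    maf = pmin(q, 1 - q),
    n_called = n_called,
    low_call_rate = n_called < ncol(d) / 2,
    stringsAsFactors = FALSE
  )
}

#' Minor-allele-frequency spectrum summary
#'
#' Folds allele frequencies (`MAF = min(q, 1 - q)`), bins them, and reports
#' the mean MAF and the fraction of sites strictly below each threshold
#' (strict `<`, matching the usual "MAF < 0.01" phrasing).
#'
#' @param q vector of alternate-allele frequencies (`NA` dropped).
#' @param thresholds cut points for the "fraction below" report.
#' @param breaks histogram bin boundaries on `[0, 0.5]`.
#' @return List with `maf`, `mean_maf`, `frac_below` (named vector) and
#'   `histogram` (data.frame `bin_low`, `bin_high`, `count`). Empty input
#'   yields an empty summary.
#' @export
maf_spectrum <- function(q, thresholds = c(0.01, 0.05),
                         breaks = seq(0, 0.5, by = 0.025)) {
  q <- q[!is.na(q)]
  if (length(q) == 0) {
    return(list(maf = numeric(0), mean_maf = NA_real_,
                frac_below = setNames(rep(NA_real_, length(thresholds)),
                                      thresholds),
                histogram = data.frame(bin_low = numeric(0),
                                       bin_high = numeric(0),
                                       count = integer(0))))
  }
  check_prob(q, "q")
  maf <- pmin(q, 1 - q)
  counts <- table(cut(maf, breaks, include.lowest = TRUE, right = FALSE))
  list(maf = maf,
       mean_maf = mean(maf),
       frac_below = setNames(vapply(thresholds, function(t) mean(maf < t),
                                    numeric(1)), thresholds),
       histogram = data.frame(bin_low = head(breaks, -1),
                              bin_high = tail(breaks, -1),
                              count = as.integer(counts)))
}

#' Gene diversity (expected heterozygosity)
#'
#' `GD = 1 - sum(P_i^2)` over the allele frequencies `P_i` at a site. Works
#' for any number of alleles; for a biallelic site pass `c(p, 1 - p)`.
#'
#' @param p allele-frequency vector summing to 1 (tolerance `1e-9`... the
#'   check uses `1e-6` to absorb accumulated float error in long vectors).
#' @return Gene diversity in `[0, 1 - 1/n]`.
#' @examples
#' gene_diversity(c(0.95, 0.05))  # 0.095
#' @export
gene_diversity <- function(p) {
  check_prob(p, "p")
  if (abs(sum(p) - 1) > 1e-6) stop_param("allele frequencies must sum to 1")
  1 - sum(p^2)
}

#' Nucleotide diversity per region and annotation class
#'
#' For each region, `pi` is the sum of per-variant gene diversities of the
#' variant sites falling in the region, divided by the region length in bp:
#' invariant positions contribute zero to the numerator and their full
#' length to the denominator. Genome/annotation summaries average the
#' per-region `pi` values unweighted across regions (set
#' `length_weighted = TRUE` for the pooled, length-weighted alternative).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based) and `gd`
#'   (per-site gene diversity).
#' @param regions a [GenomicRanges::GRanges] of accessible regions;
#'   an optional metadata column `annotation` labels each region (e.g.
#'   `coding`/`noncoding`).
#' @param length_weighted if `TRUE` summary values pool numerators and
#'   denominators instead of averaging per-region values.
#' @return List with `per_region` (data.frame `chrom`, `start`, `end`,
#'   `length`, `n_variants`, `pi`, `annotation`) and `summary` (data.frame
#'   `annotation`, `n_regions`, `mean_pi`, `sd_pi`), where the `"all"` row
#'   covers every region. Sites outside all regions raise a warning and are
#'   excluded.
#' @export
nucleotide_diversity <- function(sites, regions, length_weighted = FALSE) {
  if (!inherits(regions, "GRanges")) stop_param("'regions' must be a GRanges")
  if (length(regions) == 0) stop_param("'regions' is empty")
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(site_gr, regions)
  if (length(S4Vectors::queryHits(hits)) < nrow(sites)) {
    n_out <- nrow(sites) - length(unique(S4Vectors::queryHits(hits)))
    warning(sprintf("%d site(s) outside all regions were excluded", n_out))
  }
  gd_sum <- rep(0, length(regions))
  n_var <- rep(0L, length(regions))
  if (length(hits) > 0) {
    agg <- tapply(sites$gd[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), sum)
    idx <- as.integer(names(agg))
    gd_sum[idx] <- as.numeric(agg)
    cnt <- table(S4Vectors::subjectHits(hits))
    n_var[as.integer(names(cnt))] <- as.integer(cnt)
  }
  len <- GenomicRanges::width(regions)
  ann <- if ("annotation" %in% names(S4Vectors::mcols(regions))) {
    as.character(S4Vectors::mcols(regions)$annotation)
  } else rep("unknown", length(regions))
  per_region <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    length = len, n_variants = n_var,
    pi = gd_sum / len, annotation = ann,
    stringsAsFactors = FALSE
  )
  summarise <- function(sel, label) {
    if (length_weighted) {
      data.frame(annotation = label, n_regions = sum(sel),
                 mean_pi = sum(gd_sum[sel]) / sum(len[sel]),
                 sd_pi = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(annotation = label, n_regions = sum(sel),
                 mean_pi = mean(per_region$pi[sel]),
                 sd_pi = sd(per_region$pi[sel]), stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, c(
    list(summarise(rep(TRUE, length(regions)), "all")),
    lapply(unique(ann), function(a) summarise(ann == a, a))
  ))
  list(per_region = per_region, summary = summary)
}

#' Tetraploid Hardy-Weinberg dosage class expectations
#'
#' Under random mating the allele copy number at frequency `q` follows
#' `Binomial(4, q)`. At `q = 0.05` the minor allele is absent in about 81%
#' of individuals, simplex in about 17%, and duplex in only 1.4% -- the
#' reason rare variants behave almost like presence/absence markers.
#'
#' @param q alternate-allele frequency in `[0, 1]`.
#' @return Named numeric 5-vector of class probabilities summing to 1.
#' @examples
#' hwe_dosage_expectations(0.05)
#' @export
hwe_dosage_expectations <- function(q) {
  check_prob(q, "q")
  if (length(q) != 1) stop_param("'q' must be a single frequency")
  setNames(dbinom(DOSAGES, PLOIDY, q), DOSAGES)
}

#' Variant saturation curve under sample permutation
#'
#' For each random ordering of the samples, counts the cumulative number of
#' variant sites carried (dosage >= 1) by at least one of the first `k`
#' samples, and averages over `n_perm` permutations. The final value equals
#' the total variant count for every permutation.
#'
#' @param presence logical matrix, sites x samples: does the sample carry a
#'   non-reference allele at the site?
#' @param n_perm number of random permutations (>= 1).
#' @param seed integer seed.
#' @return data.frame with `k`, `mean_cumulative`, `mean_new` (mean count of
#'   variants first seen at step `k`).
#' @export
saturation_curve <- function(presence, n_perm = 1000, seed = 1) {
  if (!is.matrix(presence) || !is.logical(presence) || length(presence) == 0) {
    stop_param("'presence' must be a non-empty logical matrix")
  }
  n_perm <- check_count(n_perm, "n_perm")
  n <- ncol(presence)
  carried <- presence[rowSums(presence) > 0, , drop = FALSE]
  cum <- matrix(0, n_perm, n)
  withr::with_seed(seed, {
    for (i in seq_len(n_perm)) {
      ord <- sample.int(n)
      first <- max.col(carried[, ord, drop = FALSE], ties.method = "first")
      cum[i, ] <- cumsum(tabulate(first, nbins = n))
    }
  })
  mc <- colMeans(cum)
  data.frame(k = seq_len(n), mean_cumulative = mc,
             mean_new = c(mc[1], diff(mc)))
}

#' Per-sample counts of private (sample-unique) variants
#'
#' A variant is private to sample `s` when `s` carries the alternate allele
#' (dosage >= 1) and every *other called* sample is nulliplex. Missing calls
#' in other samples do not disqualify privacy, but such sites are counted
#' separately in `n_private_with_missing`.
#'
#' @param x a `genotype_matrix` or dosage matrix.
#' @return data.frame with `sample_id`, `n_private`,
#'   `n_private_with_missing` (subset of `n_private` where at least one
#'   other sample was uncalled).
#' @export
unique_variant_counts <- function(x) {
  d <- .dosage_matrix(x)
  carrier <- !is.na(d) & d >= 1
  n_carriers <- rowSums(carrier)
  n_missing <- rowSums(is.na(d))
  private <- n_carriers == 1
  owner <- ifelse(private, max.col(carrier, ties.method = "first"), NA)
  n_private <- tabulate(owner[private], nbins = ncol(d))
  n_flagged <- tabulate(owner[private & n_missing > 0], nbins = ncol(d))
  data.frame(
    sample_id = if (!is.null(colnames(d))) colnames(d)
                else sprintf("sample_%03d", seq_len(ncol(d))),
    n_private = n_private,
    n_private_with_missing = n_flagged,
    stringsAsFactors = FALSE
  )
}

#' Transition/transversion ratio for biallelic SNPs
#'
#' Transitions are `A<->G` and `C<->T`; every other single-base substitution
#' is a transversion. Records whose ref/alt are not single distinct bases
#' are ignored.
#'
#' @param ref,alt character vectors of reference/alternate alleles.
#' @return List with `ratio`, `n_transitions`, `n_transversions`, and
#'   `infinite` flag (`TRUE` when there are no transversions).
#' @export
ts_tv <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- nchar(ref) == 1 & nchar(alt) == 1 & ref != alt &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  pair <- paste0(ref[ok], alt[ok])
  ts <- pair %in% c("AG", "GA", "CT", "TC")
  n_ts <- sum(ts); n_tv <- sum(!ts)
  list(ratio = if (n_tv == 0) Inf else n_ts / n_tv,
       n_transitions = n_ts, n_transversions = n_tv,
       infinite = n_tv == 0)
}
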