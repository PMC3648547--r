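# Allele dosage calling from allele-specific read depths: binomial
# likelihood over the five tetraploid dosage classes, phred-scaled genotype
# quality, and depth/quality filters.

#' Per-site, per-sample allele-specific read counts
#'
#' The dosage caller's sole evidence: matrices of reference and alternate
#' read counts with sites in rows and samples in columns.
#'
#' @param ref,alt non-negative integer matrices of identical dimension.
#' @param site_ids,sample_ids row/column identifiers.
#' @param site_info optional per-site metadata data.frame with columns among
#'   `site_id`, `chrom`, `pos` (1-based), `ref`, `alt`, `class`
#'   (`SNP`/`MNP`/`indel`), `annotation` (`coding`/`noncoding`/`unknown`).
#' @return An object of class `site_counts` with elements `ref`, `alt`,
#'   `depth` (= `ref + alt`), `site_ids`, `sample_ids`, `site_info`.
#' @export
site_counts <- function(ref, alt, site_ids = NULL, sample_ids = NULL,
                        site_info = NULL) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (!all(dim(ref) == dim(alt))) stop_param("'ref' and 'alt' dimensions differ")
  if (anyNA(ref) || anyNA(alt) || any(ref < 0) || any(alt < 0)) {
    stop_param("read counts must be non-negative and non-missing")
  }
  if (is.null(site_ids)) site_ids <- sprintf("site_%05d", seq_len(nrow(ref)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%03d", seq_len(ncol(ref)))
  if (anyDuplicated(site_ids)) stop_param("duplicate site ids")
  structure(list(ref = ref, alt = alt, depth = ref + alt,
                 site_ids = as.character(site_ids),
                 sample_ids = as.character(sample_ids),
                 site_info = site_info),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("<site_counts> %d sites x %d samples, median depth %g\n",
              nrow(x$ref), ncol(x$ref), median(x$depth)))
  invisible(x)
}

#' Expected alternate-read fraction of a dosage class
#'
#' The mean of the binomial read-count likelihood for allele copy number
#' `g`: first the error-perturbed fraction
#' `f0 = (g/4)(1 - e) + (1 - g/4) e` with wrong-allele rate `e`, then the
#' capture-bias adjustment `f = f0 b / (f0 b + (1 - f0))` with alternate
#' capture efficiency `b`. With `e = 0, b = 1` this is exactly `g/4`.
#'
#' @param dosage allele copy number(s) in `0..4` (vectorised).
#' @param model an [error_model()].
#' @return Expected alternate fractions in `[0, 1]`.
#' @examples
#' expected_alt_fraction(0:4, error_model(0.01, 1))
#' @export
expected_alt_fraction <- function(dosage, model = error_model()) {
  model <- as_error_model(model)
  if (anyNA(dosage) || any(dosage != as.integer(dosage)) ||
      any(dosage < 0 | dosage > PLOIDY)) {
    stop_param("'dosage' must contain integers in 0..4")
  }
  e <- model$error_rate
  f0 <- (dosage / PLOIDY) * (1 - e) + (1 - dosage / PLOIDY) * e
  f0 * model$alt_bias / (f0 * model$alt_bias + (1 - f0))
}

#' Variant discovery filter for one site
#'
#' A site passes discovery when at least one sample supports the alternate
#' allele with at least `min_alt_reads` reads that also make up at least
#' `min_alt_frac` of that sample's reads at the site. Both thresholds are
#' inclusive. Zero-depth samples are skipped (never divided by).
#'
#' @param ref,alt per-sample reference/alternate read counts at one site.
#' @param min_alt_reads minimum supporting reads (default 5).
#' @param min_alt_frac minimum supporting read fraction (default 0.125).
#' @return List with `pass` (logical) and `supporters` (indices of samples
#'   meeting both criteria).
#' @export
site_passes_discovery <- function(ref, alt, min_alt_reads = 5,
                                  min_alt_frac = 0.125) {
  if (length(ref) != length(alt)) stop_param("'ref'/'alt' length mismatch")
  depth <- ref + alt
  ok <- depth > 0 & alt >= min_alt_reads & alt / pmax(depth, 1) >= min_alt_frac
  list(pass = any(ok), supporters = which(ok))
}

#' Binomial dosage likelihoods
#'
#' Likelihood of each allele copy number `g` in `0..4` given `alt` alternate
#' reads among `ref + alt` total: the `Binomial(depth, f_g)` mass at `alt`,
#' with `f_g` from [expected_alt_fraction()]. At depth 0 all five components
#' are equal (the data are uninformative).
#'
#' @param ref,alt read counts (scalars).
#' @param model an [error_model()].
#' @return Numeric 5-vector of likelihoods (not normalised).
#' @export
dosage_likelihoods <- function(ref, alt, model = error_model()) {
  if (ref < 0 || alt < 0) stop_param("counts must be >= 0")
  f <- expected_alt_fraction(DOSAGES, model)
  dbinom(alt, ref + alt, f)
}

# Vectorised calling core shared by call_dosage() and call_matrix().
# Returns a list of parallel vectors plus the n x 5 posterior matrix.
.call_core <- function(ref, alt, prior, model, min_depth, min_gq, gq_cap) {
  depth <- ref + alt
  f <- expected_alt_fraction(DOSAGES, model)
  lik <- vapply(f, function(fg) dbinom(alt, depth, fg), numeric(length(alt)))
  lik <- matrix(lik, ncol = PLOIDY + 1L)
  post <- lik * rep(prior, each = nrow(lik))
  post <- post / rowSums(post)
  provisional <- max.col(post, ties.method = "first") - 1L
  pmax_post <- post[cbind(seq_len(nrow(post)), provisional + 1L)]
  gq <- phred(pmax(1 - pmax_post, 0), cap = gq_cap)
  reason <- rep(NA_character_, length(alt))
  dosage <- provisional
  low_gq <- gq < min_gq
  reason[low_gq] <- "low_gq"
  dosage[low_gq] <- NA_integer_
  low_depth <- depth < min_depth
  reason[low_depth] <- "low_depth"
  dosage[low_depth] <- NA_integer_
  provisional[low_depth] <- NA_integer_
  gq[low_depth] <- NA_real_
  list(dosage = dosage, provisional = provisional, gq = gq,
       depth = depth, reason = reason, posterior = post)
}

.check_prior <- function(prior) {
  if (is.null(prior)) prior <- rep(1 / (PLOIDY + 1), PLOIDY + 1)
  if (!is.numeric(prior) || length(prior) != PLOIDY + 1 || anyNA(prior) ||
      any(prior < 0) || abs(sum(prior) - 1) > 1e-6) {
    stop_param("'prior' must be a 5-vector of probabilities summing to 1")
  }
  prior
}

#' Call the allele dosage of one sample at one site
#'
#' Applies the binomial dosage model with the standard filters: a cell needs
#' depth of at least `min_depth` (default 15 reads) to be callable, the
#' posterior over the five dosage classes is `prior x likelihood`
#' (normalised), the call is the posterior mode, and its genotype quality is
#' `-10 log10(1 - max posterior)` capped at `gq_cap`. Calls with
#' `gq < min_gq` (default 26) are reported missing with reason `low_gq`,
#' retaining the provisional dosage and posterior; cells below the depth
#' gate are missing with reason `low_depth`. Posterior ties break toward the
#' lower dosage (such calls necessarily fail the GQ gate).
#'
#' @param ref,alt read counts for the cell.
#' @param prior 5-vector of class prior probabilities (default uniform);
#'   see [hwe_dosage_expectations()] for a Hardy-Weinberg prior.
#' @param model an [error_model()].
#' @param min_depth,min_gq,gq_cap filter settings (inclusive thresholds).
#' @return An object of class `dosage_call`: list with `dosage` (integer or
#'   `NA`), `reason` (`NA`, `"low_depth"` or `"low_gq"`), `provisional`,
#'   `posterior` (5-vector summing to 1), `gq`, `depth`.
#' @examples
#' call_dosage(ref = 30, alt = 31, model = error_model(0.01))
#' @export
call_dosage <- function(ref, alt, prior = NULL, model = error_model(),
                        min_depth = 15, min_gq = 26, gq_cap = 99) {
  prior <- .check_prior(prior)
  if (ref < 0 || alt < 0) stop_param("counts must be >= 0")
  res <- .call_core(ref, alt, prior, as_error_model(model),
                    min_depth, min_gq, gq_cap)
  structure(list(dosage = res$dosage[1], reason = res$reason[1],
                 provisional = res$provisional[1],
                 posterior = as.vector(res$posterior[1, ]),
                 gq = res$gq[1], depth = res$depth[1]),
            class = "dosage_call")
}

#' @export
print.dosage_call <- function(x, ...) {
  if (is.na(x$dosage)) {
    cat(sprintf("<dosage_call> missing (%s), depth %d", x$reason, x$depth))
    if (!is.na(x$provisional)) {
      cat(sprintf(", provisional dosage %d (gq %.1f)", x$provisional, x$gq))
    }
    cat("\n")
  } else {
    cat(sprintf("<dosage_call> dosage %d, gq %.1f, depth %d\n",
                x$dosage, x$gq, x$depth))
  }
  invisible(x)
}

#' Call dosages for a whole counts matrix
#'
#' Applies [call_dosage()] cell-wise over a [site_counts()] object and
#' records the per-site call rate. Deterministic.
#'
#' @param counts a [site_counts()].
#' @inheritParams call_dosage
#' @param keep_posterior retain the full sites x samples x 5 posterior
#'   array (memory grows accordingly).
#' @return A `genotype_matrix`: list with integer matrix `dosage` (`NA` =
#'   missing), matrices `provisional`, `gq`, `depth`, character matrix
#'   `reason`, per-site `call_rate`, `site_info`, ids and `settings`.
#' @export
call_matrix <- function(counts, prior = NULL, model = error_model(),
                        min_depth = 15, min_gq = 26, gq_cap = 99,
                        keep_posterior = FALSE) {
  if (!inherits(counts, "site_counts")) stop_param("'counts' must be site_counts")
  if (anyDuplicated(counts$site_ids)) stop_param("duplicate site keys")
  prior <- .check_prior(prior)
  dim <- dim(counts$ref)
  res <- .call_core(as.vector(counts$ref), as.vector(counts$alt), prior,
                    as_error_model(model), min_depth, min_gq, gq_cap)
  shape <- function(v) {
    m <- matrix(v, dim[1], dim[2])
    dimnames(m) <- list(counts$site_ids, counts$sample_ids)
    m
  }
  dosage <- shape(res$dosage)
  out <- list(dosage = dosage,
              provisional = shape(res$provisional),
              gq = shape(res$gq),
              depth = shape(res$depth),
              reason = shape(res$reason),
              call_rate = rowMeans(!is.na(dosage)),
              site_ids = counts$site_ids,
              sample_ids = counts$sample_ids,
              site_info = counts$site_info,
              settings = list(prior = prior, model = as_error_model(model),
                              min_depth = min_depth, min_gq = min_gq,
                              gq_cap = gq_cap))
  if (keep_posterior) {
    out$posterior <- array(res$posterior, c(dim[1], dim[2], PLOIDY + 1L))
  }
  structure(out, class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples, call rate %.1f%%\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(!is.na(x$dosage))))
  invisible(x)
}

#' Two-state call for a monoploid sample
#'
#' Monoploid individuals carry a variant as either absent or present; the
#' call is maximum likelihood between the nulliplex and quadruplex read
#' models, behind the same depth gate as the tetraploid caller.
#'
#' @param ref,alt read counts.
#' @param model an [error_model()].
#' @param min_depth depth gate (default 15).
#' @return `"absent"`, `"present"`, or `"missing"`.
#' @export
call_monoploid <- function(ref, alt, model = error_model(), min_depth = 15) {
  if (ref < 0 || alt < 0) stop_param("counts must be >= 0")
  if (ref + alt < min_depth) return("missing")
  f <- expected_alt_fraction(c(0L, PLOIDY), model)
  lik <- dbinom(alt, ref + alt, f)
  if (lik[2] > lik[1]) "present" else "absent"
}
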