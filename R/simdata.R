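# Synthetic tetraploid GBS panels: allele-frequency spectra, Hardy-Weinberg
# dosages, log-normal read depths, binomial allele-specific read sampling,
# and KASP-like orthogonal assay signals.

# Frozen defaults of the folded allele-frequency spectrum. A single Beta
# cannot carry ~61% of its folded mass below MAF 0.05 while keeping the mean
# folded MAF near 0.14 (the attainable mean caps near 0.10), so the minor
# allele frequency is modelled as a two-component Beta mixture on (0, 0.5):
# a rare-variant component and a common-variant component, each truncated at
# 0.5. Parameters below were fixed once by numerical calibration against
# mean MAF 0.14, P(MAF < 0.05) = 0.61 and P(MAF < 0.01) = 0.174, and are not
# tuning knobs. The minor allele is the alternate allele with probability
# ref_major_prob (about 10% of real variants have a non-reference major
# allele).
.SPECTRUM_DEFAULT <- list(
  w_rare = 0.7023,
  shape1_rare = 1.3634, shape2_rare = 50.5949,
  shape1_common = 4.7593, shape2_common = 1.5468,
  ref_major_prob = 0.896
)

#' Default minor-allele-frequency spectrum parameters
#'
#' Returns the frozen parameters of the folded allele-frequency spectrum
#' used by [sample_allele_freqs()]: a two-component Beta mixture on the
#' minor allele frequency (each component truncated to `(0, 0.5)`), with a
#' rare-variant component (weight `w_rare`) and a common-variant component.
#' The defaults emulate an L-shaped cultivated-germplasm spectrum with mean
#' MAF 0.14, 61% of variants below MAF 0.05 and 17.4% below MAF 0.01.
#' `fixed` forces a degenerate spectrum with every frequency equal to the
#' given value (useful for edge-case tests).
#'
#' @param w_rare mixture weight of the rare-variant component.
#' @param shape1_rare,shape2_rare Beta shapes of the rare component.
#' @param shape1_common,shape2_common Beta shapes of the common component.
#' @param ref_major_prob probability that the reference allele is the major
#'   allele (otherwise the alternate-allele frequency is `1 - MAF`).
#' @param fixed if non-`NULL`, a single frequency assigned to every site.
#' @return A list of class `maf_spectrum`.
#' @export
maf_spectrum_params <- function(w_rare = .SPECTRUM_DEFAULT$w_rare,
                                shape1_rare = .SPECTRUM_DEFAULT$shape1_rare,
                                shape2_rare = .SPECTRUM_DEFAULT$shape2_rare,
                                shape1_common = .SPECTRUM_DEFAULT$shape1_common,
                                shape2_common = .SPECTRUM_DEFAULT$shape2_common,
                                ref_major_prob = .SPECTRUM_DEFAULT$ref_major_prob,
                                fixed = NULL) {
  if (!is.null(fixed)) {
    check_prob(fixed, "fixed", 0, 1)
    return(structure(list(fixed = fixed), class = "maf_spectrum"))
  }
  check_prob(w_rare, "w_rare")
  check_prob(ref_major_prob, "ref_major_prob")
  shapes <- c(shape1_rare, shape2_rare, shape1_common, shape2_common)
  if (!is.numeric(shapes) || anyNA(shapes) || any(shapes <= 0)) {
    stop_param("Beta shape parameters must be positive")
  }
  structure(list(w_rare = w_rare,
                 shape1_rare = shape1_rare, shape2_rare = shape2_rare,
                 shape1_common = shape1_common, shape2_common = shape2_common,
                 ref_major_prob = ref_major_prob),
            class = "maf_spectrum")
}

# inverse-CDF draw from Beta(a, b) truncated to (0, 0.5)
.rbeta_trunc_half <- function(n, a, b) {
  qbeta(runif(n) * pbeta(0.5, a, b), a, b)
}

#' Sample per-site alternate-allele frequencies
#'
#' Draws alternate-allele frequencies for `n_sites` independent loci from
#' the folded spectrum described in [maf_spectrum_params()]. Values are
#' strictly inside `(0, 1)` (monomorphic sites carry no information for the
#' dosage caller and are not generated).
#'
#' @param n_sites number of loci.
#' @param spectrum a `maf_spectrum` object; defaults to the calibrated
#'   L-shaped spectrum.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return Numeric vector of length `n_sites` with values in `(0, 1)`.
#' @examples
#' q <- sample_allele_freqs(1000, seed = 1)
#' mean(pmin(q, 1 - q))  # mean folded MAF, about 0.14
#' @export
sample_allele_freqs <- function(n_sites, spectrum = maf_spectrum_params(),
                                seed = 1) {
  n_sites <- check_count(n_sites, "n_sites")
  if (!inherits(spectrum, "maf_spectrum")) {
    stop_param("'spectrum' must come from maf_spectrum_params()")
  }
  withr::with_seed(seed, {
    if (!is.null(spectrum$fixed)) return(rep(spectrum$fixed, n_sites))
    rare <- runif(n_sites) < spectrum$w_rare
    m <- numeric(n_sites)
    m[rare] <- .rbeta_trunc_half(sum(rare), spectrum$shape1_rare,
                                 spectrum$shape2_rare)
    m[!rare] <- .rbeta_trunc_half(sum(!rare), spectrum$shape1_common,
                                  spectrum$shape2_common)
    ref_major <- runif(n_sites) < spectrum$ref_major_prob
    ifelse(ref_major, m, 1 - m)
  })
}

#' Simulate tetraploid Hardy-Weinberg dosages
#'
#' Draws, for each site and sample, an allele copy number from
#' `Binomial(4, q)` where `q` is the site's alternate-allele frequency --
#' the tetraploid Hardy-Weinberg expectation under random mating.
#'
#' @param freqs per-site alternate-allele frequencies. Must lie strictly in
#'   `(0, 1)` unless `allow_fixed = TRUE` (monomorphic edge cases).
#' @param n_samples number of individuals in the panel.
#' @param seed integer seed.
#' @param allow_fixed permit frequencies of exactly 0 or 1.
#' @return A `sim_truth` object: list with `allele_freqs` and an integer
#'   `dosages` matrix (sites x samples, values 0-4).
#' @examples
#' truth <- simulate_dosages(c(0.05, 0.5), n_samples = 10, seed = 1)
#' truth$dosages
#' @export
simulate_dosages <- function(freqs, n_samples, seed = 1, allow_fixed = FALSE) {
  n_samples <- check_count(n_samples, "n_samples")
  if (allow_fixed) check_prob(freqs, "freqs")
  else check_prob(freqs, "freqs", lo_open = TRUE, hi_open = TRUE)
  n_sites <- length(freqs)
  if (n_sites < 1) stop_param("'freqs' must be non-empty")
  dosages <- withr::with_seed(seed, {
    matrix(rbinom(n_sites * n_samples, PLOIDY, freqs),
           nrow = n_sites, ncol = n_samples)
  })
  structure(list(allele_freqs = freqs,
                 dosages = dosages,
                 site_ids = sprintf("site_%05d", seq_len(n_sites)),
                 sample_ids = sprintf("sample_%03d", seq_len(n_samples))),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d sites x %d samples, mean MAF %.3f\n",
              nrow(x$dosages), ncol(x$dosages),
              mean(pmin(x$allele_freqs, 1 - x$allele_freqs))))
  invisible(x)
}

#' Simulate allele-specific read counts
#'
#' Forward model mirroring the caller's likelihood: per cell the total depth
#' is a discretised log-normal (parameterised by its median and log-sd), and
#' the alternate-read count is `Binomial(depth, f)` where `f` is the
#' error/bias-adjusted expected alternate fraction of the cell's true dosage
#' (see [expected_alt_fraction()]). Reference reads are `depth - alt`.
#'
#' @param truth a `sim_truth` from [simulate_dosages()].
#' @param depth_median median read depth (reads); default 63, a realistic
#'   per-cultivar median for target-enriched GBS.
#' @param depth_log_sd log-scale standard deviation of depth (0 gives a
#'   fixed depth equal to the median).
#' @param model an [error_model()] (sequencing error and capture bias).
#' @param seed integer seed.
#' @return A [site_counts()] object.
#' @export
simulate_counts <- function(truth, depth_median = 63, depth_log_sd = 0.5,
                            model = error_model(), seed = 1) {
  if (!inherits(truth, "sim_truth")) stop_param("'truth' must be a sim_truth")
  if (!is.numeric(depth_median) || depth_median <= 0) {
    stop_param("'depth_median' must be > 0")
  }
  if (!is.numeric(depth_log_sd) || depth_log_sd < 0) {
    stop_param("'depth_log_sd' must be >= 0")
  }
  model <- as_error_model(model)
  dim <- dim(truth$dosages)
  n <- prod(dim)
  f_by_dosage <- expected_alt_fraction(DOSAGES, model)
  withr::with_seed(seed, {
    depth <- pmax(round(rlnorm(n, meanlog = log(depth_median),
                               sdlog = depth_log_sd)), 0)
    alt <- rbinom(n, depth, f_by_dosage[as.vector(truth$dosages) + 1L])
  })
  alt <- matrix(alt, dim[1], dim[2])
  depth <- matrix(depth, dim[1], dim[2])
  site_counts(ref = depth - alt, alt = alt,
              site_ids = truth$site_ids, sample_ids = truth$sample_ids)
}

#' Simulate KASP-like orthogonal assay calls
#'
#' Emulates a competitive allele-specific PCR assay at the signal-ratio
#' level: the per-sample signal is `dosage/4` plus Gaussian noise, truncated
#' to `[0, 1]`, and hard-called to the nearest of `{0, 0.25, 0.5, 0.75, 1}`
#' to yield an assay dosage. Duplicate samples are independently re-assayed
#' (replicate 2), as used for estimating the assay's own error rate.
#'
#' @param truth a `sim_truth`.
#' @param panel_sites integer indices (or site ids) of the assayed sites.
#' @param signal_noise_sd Gaussian noise sd on the signal ratio; with sd 0
#'   the assay reproduces the true dosages exactly.
#' @param duplicate_samples indices of samples assayed twice.
#' @param seed integer seed.
#' @return A data.frame with columns `site_id`, `sample_id`, `replicate`,
#'   `signal`, `dosage`.
#' @export
simulate_kasp <- function(truth, panel_sites, signal_noise_sd = 0.05,
                          duplicate_samples = integer(0), seed = 1) {
  if (!inherits(truth, "sim_truth")) stop_param("'truth' must be a sim_truth")
  if (is.character(panel_sites)) {
    panel_sites <- match(panel_sites, truth$site_ids)
  }
  if (length(panel_sites) == 0 || anyNA(panel_sites) ||
      any(panel_sites < 1 | panel_sites > nrow(truth$dosages))) {
    stop_param("'panel_sites' must be a non-empty subset of the site index")
  }
  if (!is.numeric(signal_noise_sd) || signal_noise_sd < 0) {
    stop_param("'signal_noise_sd' must be >= 0")
  }
  assay_once <- function(samples) {
    d <- truth$dosages[panel_sites, samples, drop = FALSE]
    sig <- pmin(pmax(d / 4 + rnorm(length(d), sd = signal_noise_sd), 0), 1)
    data.frame(
      site_id = rep(truth$site_ids[panel_sites], times = length(samples)),
      sample_id = rep(truth$sample_ids[samples], each = length(panel_sites)),
      signal = as.vector(sig),
      dosage = as.integer(round(as.vector(sig) * 4)),
      stringsAsFactors = FALSE
    )
  }
  withr::with_seed(seed, {
    main <- assay_once(seq_len(ncol(truth$dosages)))
    main$replicate <- 1L
    if (length(duplicate_samples) > 0) {
      dup <- assay_once(duplicate_samples)
      dup$replicate <- 2L
      main <- rbind(main, dup)
    }
  })
  main[, c("site_id", "sample_id", "replicate", "signal", "dosage")]
}

#' Simulation configuration
#'
#' Bundles all generator parameters of a synthetic tetraploid panel.
#' Defaults describe the emulated study: an 84-sample panel with L-shaped
#' MAF spectrum (mean MAF about 0.14, about 61% of variants below MAF 0.05),
#' median read depth 63x with log-sd 0.5, and a 1% wrong-allele read rate.
#'
#' @param n_samples,n_sites panel dimensions.
#' @param spectrum a `maf_spectrum` ([maf_spectrum_params()]).
#' @param depth_median,depth_log_sd log-normal depth model parameters.
#' @param error_rate,alt_bias see [error_model()].
#' @param seed integer master seed; sub-stages use `seed`, `seed + 1`, ...
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 84, n_sites = 1000,
                       spectrum = maf_spectrum_params(),
                       depth_median = 63, depth_log_sd = 0.5,
                       error_rate = 0.01, alt_bias = 1, seed = 1) {
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples"),
    n_sites = check_count(n_sites, "n_sites"),
    spectrum = spectrum,
    depth_median = depth_median,
    depth_log_sd = depth_log_sd,
    model = error_model(error_rate, alt_bias),
    seed = check_count(seed, "seed", min = 0)
  )
  if (depth_median <= 0) stop_param("'depth_median' must be > 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a complete synthetic panel
#'
#' Runs the three generator stages (frequencies, dosages, read counts) under
#' one [sim_config()]. Deterministic given the config's seed.
#'
#' @param config a [sim_config()].
#' @return List with `truth` (a `sim_truth`), `counts` (a [site_counts()])
#'   and the `config`.
#' @examples
#' panel <- simulate_panel(sim_config(n_samples = 10, n_sites = 50, seed = 7))
#' panel$truth
#' @export
simulate_panel <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop_param("'config' must be a sim_config")
  freqs <- sample_allele_freqs(config$n_sites, config$spectrum,
                               seed = config$seed)
  truth <- simulate_dosages(freqs, config$n_samples, seed = config$seed + 1)
  counts <- simulate_counts(truth, config$depth_median, config$depth_log_sd,
                            config$model, seed = config$seed + 2)
  list(truth = truth, counts = counts, config = config)
}
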