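make_pairs <- function(obs_dosage, exp_dosage, ...) {
  n <- length(obs_dosage)
  extra <- list(...)
  obs <- data.frame(site_id = sprintf("s%03d", seq_len(n)),
                    sample_id = "x", dosage = obs_dosage)
  for (nm in names(extra)) obs[[nm]] <- extra[[nm]]
  exp <- data.frame(site_id = sprintf("s%03d", seq_len(n)),
                    sample_id = "x", dosage = exp_dosage)
  list(obs = obs, exp = exp)
}

test_that("concordance table reproduces printed percentages from counts", {
  # identical call sets: 100% everywhere
  p <- make_pairs(rep(0:4, 2), rep(0:4, 2))
  ct <- concordance_table(p$obs, p$exp)
  expect_equal(ct$per_class$pct_concordant, rep(100, 5))
  expect_equal(ct$overall_pct, 100)

  # the published-style count table: per-class 98.7/99.5/96.2/97.6/98.1,
  # overall 98.4
  r <- concordance_rates(c(4975, 4861, 2204, 1373, 1272),
                         c(67, 25, 86, 34, 25))
  expect_equal(r$per_class, c(98.7, 99.5, 96.2, 97.6, 98.1))
  expect_equal(r$overall, 98.4)

  # toy 10-pair set with 2 planned mismatches -> 80%
  p2 <- make_pairs(c(0, 1, 2, 3, 4, 0, 1, 2, 2, 4),
                   c(0, 1, 2, 3, 4, 0, 1, 2, 3, 0))
  expect_equal(concordance_table(p2$obs, p2$exp)$overall_pct, 80)

  # marginals conserved; overall is the count-weighted mean of per-class
  ct2 <- concordance_table(p2$obs, p2$exp)
  expect_equal(sum(ct2$counts), ct2$n_pairs)
  w <- ct2$per_class$concordant + ct2$per_class$discordant
  expect_equal(ct2$overall_pct,
               round(sum(ct2$per_class$pct_concordant * w) / sum(w), 1))

  # missing observed calls are excluded and counted
  p3 <- make_pairs(c(0, NA, 2), c(0, 1, 2))
  ct3 <- concordance_table(p3$obs, p3$exp)
  expect_equal(ct3$n_missing, 1L)
  expect_equal(ct3$n_pairs, 2L)
  expect_error(concordance_table(p3$obs[0, ], p3$exp), "overlapping")
})

test_that("depth and alt-fraction summaries are attached per class", {
  p <- make_pairs(c(2, 2, 1, 0), c(2, 2, 2, 0),
                  depth = c(100, 80, 50, 60),
                  alt_frac = c(0.5, 0.49, 0.3, 0))
  ct <- concordance_table(p$obs, p$exp)
  duplex <- ct$per_class[ct$per_class$expected_class == 2, ]
  expect_equal(duplex$median_depth_concordant, 90)
  expect_equal(duplex$median_depth_discordant, 50)
  expect_equal(duplex$mean_alt_frac_concordant, 0.495)
})

test_that("het/hom collapse merges within-heterozygous confusions", {
  # expected duplex observed simplex: discordant in 5-class, concordant
  # when collapsed; nulliplex vs quadruplex stays within homozygous
  p <- make_pairs(c(1, 4, 3), c(2, 0, 3))
  five <- concordance_table(p$obs, p$exp)
  expect_equal(five$overall_pct, round(100 / 3, 1))
  two <- collapse_het_hom(p$obs, p$exp)
  expect_equal(two$overall_pct, 100)
  expect_equal(unname(two$counts["het", "het"]), 2L)
  expect_equal(unname(two$counts["hom", "hom"]), 1L)
})

test_that("GQ threshold tuning finds the smallest passing integer", {
  # all concordant: threshold 0
  p <- make_pairs(rep(2, 10), rep(2, 10), gq = seq(10, 100, by = 10))
  expect_identical(tune_gq_threshold(p$obs, p$exp)$threshold, 0L)

  # constructed trace crossing 5% between gq 25 and 26: up to threshold 25
  # there are 2 discordant of 35 (5.7%); at 26 one discordant leaves and
  # 1/25 = 4% passes
  gq <- c(rep(25, 10), rep(50, 24), 99)
  obs_d <- rep(2, 35)
  obs_d[c(1, 35)] <- 1          # one discordant at gq 25, one at gq 99
  p2 <- make_pairs(obs_d, rep(2, 35), gq = gq)
  fit <- tune_gq_threshold(p2$obs, p2$exp, max_discordance = 0.05)
  expect_identical(fit$threshold, 26L)
  expect_true(all(c("threshold", "n", "discordance") %in% names(fit$trace)))

  # monotone contract: a laxer tolerance never raises the threshold
  laxer <- tune_gq_threshold(p2$obs, p2$exp, max_discordance = 0.10)
  expect_lte(laxer$threshold, fit$threshold)

  # unattainable target is reported with the trace, no exception
  p3 <- make_pairs(rep(1, 5), rep(2, 5), gq = rep(99, 5))
  out <- tune_gq_threshold(p3$obs, p3$exp)
  expect_true(is.na(out$threshold))
  expect_equal(nrow(out$trace), 100)
})

test_that("duplicate-assay error rate is a one-decimal percentage", {
  # 2 discordant of 2 x 270 duplicated genotypes -> 0.4%
  a <- rep(0L, 540); b <- a; b[c(1, 2)] <- 1L
  r <- duplicate_error_rate(a, b)
  expect_equal(r$percent, 0.4)
  expect_equal(r$n_discordant, 2L)
  expect_equal(duplicate_error_rate(a, a)$percent, 0)
  expect_equal(duplicate_error_rate(c(rep(0, 99), 1), rep(0, 100))$percent, 1)
  expect_error(duplicate_error_rate(integer(0), integer(0)), "pairs")
})

test_that("validation panel selection clusters correlated sites", {
  set.seed(9)
  n <- 60
  base <- rbinom(n, 4, 0.25)
  d <- rbind(
    site_a = base,                                  # block 1
    site_b = base,                                  # duplicate of site_a
    site_c = rbinom(n, 4, 0.25),                    # independent
    site_d = rbinom(n, 4, 0.3),                     # independent
    site_e = pmin(base + rbinom(n, 1, 0.05), 4)     # near-copy of site_a
  )
  panel <- select_validation_snps(d, maf_low = 0.1, maf_high = 0.4,
                                  r2_threshold = 0.16)
  # perfectly correlated / near-copy sites collapse to one representative
  expect_true(sum(c("site_a", "site_b", "site_e") %in% panel$sites) == 1)
  expect_true(all(c("site_c", "site_d") %in% panel$sites))
  # pairwise r2 between selected sites is below the threshold
  r2 <- cor(t(d[panel$sites, ]))^2
  expect_true(all(r2[upper.tri(r2)] < 0.16))

  # MAF window filter and empty-window warning
  expect_warning(
    empty <- select_validation_snps(matrix(rep(c(0L, 4L), 30), 2, 30),
                                    maf_low = 0.15, maf_high = 0.35),
    "MAF window")
  expect_length(empty$sites, 0)
})

test_that("end-to-end synthetic validation mirrors the expected pattern", {
  # simulate a default panel (median depth 63x, 1% error), call with the
  # GQ >= 26 filter, and validate against a near-noiseless orthogonal
  # assay. Expected pattern: (a) high overall concordance, (b) the extra
  # discordance of the 5-class table over the het/hom collapse comes from
  # within-heterozygous confusions, and (c) duplex is the weakest class
  # (its expected alternate fraction 0.5 sits closest to its neighbours)
  panel <- simulate_panel(sim_config(n_samples = 84, n_sites = 3000,
                                     depth_median = 63, seed = 51))
  cm <- call_matrix(panel$counts, model = error_model(0.01))
  kasp <- simulate_kasp(panel$truth, panel_sites = seq_len(3000),
                        signal_noise_sd = 0.01, seed = 52)
  obs <- data.frame(
    site_id = rep(cm$site_ids, times = length(cm$sample_ids)),
    sample_id = rep(cm$sample_ids, each = length(cm$site_ids)),
    dosage = as.vector(cm$dosage),
    depth = as.vector(cm$depth))
  exp <- kasp[kasp$replicate == 1, c("site_id", "sample_id", "dosage")]
  ct <- concordance_table(obs, exp)
  expect_gt(ct$overall_pct, 99)
  two <- collapse_het_hom(obs, exp)
  expect_gte(two$overall_pct, ct$overall_pct)
  # duplex has the highest per-class discordance fraction
  pc <- ct$per_class
  disc_rate <- pc$discordant / (pc$concordant + pc$discordant)
  expect_equal(which.max(disc_rate) - 1L, 2L)
  # nearly all 5-class discordance stays within the heterozygous block
  m <- merge(obs, exp, by = c("site_id", "sample_id"),
             suffixes = c("_o", "_e"))
  m <- m[!is.na(m$dosage_o), ]
  het <- function(d) d %in% 1:3
  n_cross <- sum(het(m$dosage_o) != het(m$dosage_e))
  n_disc <- sum(m$dosage_o != m$dosage_e)
  expect_lt(n_cross, n_disc / 2)
})
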