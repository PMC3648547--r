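# Independent oracles used to pin expected values. These deliberately avoid
# the package's own code paths: posteriors come from an explicit
# choose()-product binomial, permutations from full enumeration, and OLS
# from the closed-form normal equations.

# Exact posterior over the five dosage classes for one cell.
oracle_posterior <- function(ref, alt, eps = 0, beta = 1,
                             prior = rep(0.2, 5)) {
  g <- 0:4
  f0 <- (g / 4) * (1 - eps) + (1 - g / 4) * eps
  f <- f0 * beta / (f0 * beta + (1 - f0))
  n <- ref + alt
  lik <- choose(n, alt) * f^alt * (1 - f)^ref
  post <- lik * prior
  post / sum(post)
}

oracle_call <- function(ref, alt, eps = 0, beta = 1, prior = rep(0.2, 5),
                        gq_cap = 99) {
  post <- oracle_posterior(ref, alt, eps, beta, prior)
  g <- which.max(post) - 1L   # which.max takes the first (lowest) maximum
  p_err <- max(1 - post[g + 1L], 0)
  gq <- min(-10 * log10(max(p_err, 10^(-gq_cap / 10))), gq_cap)
  list(dosage = g, gq = gq, posterior = post)
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# Exact mean cumulative variant counts over all sample orderings.
oracle_saturation <- function(presence) {
  n <- ncol(presence)
  perms <- all_perms(n)
  cums <- sapply(perms, function(ord) {
    seen <- rep(FALSE, nrow(presence))
    vapply(ord, function(s) {
      seen <<- seen | presence[, s]
      sum(seen)
    }, numeric(1))
  })
  list(mean = rowMeans(cums), sd = apply(cums, 1, sd))
}

# Closed-form simple OLS of y on x with an intercept.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(x)
  res <- y - alpha - beta * x
  df <- n - 2
  se <- sqrt(sum(res^2) / df / sxx)
  t <- beta / se
  list(slope = beta, se = se,
       p = 2 * pt(abs(t), df, lower.tail = FALSE),
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Benjamini-Hochberg by direct definition: adj_i = min over j with
# p_j >= p_i of p_j * n / rank_j (step-up), clipped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    min(1, min((p * n / r)[r >= r[i]]))
  }, numeric(1))
}

# Build a sim_truth by hand (for controlled KASP / counts tests).
make_truth <- function(dosages, freqs = NULL) {
  dosages <- as.matrix(dosages)
  structure(list(
    allele_freqs = if (is.null(freqs)) rowMeans(dosages) / 4 else freqs,
    dosages = dosages,
    site_ids = sprintf("site_%05d", seq_len(nrow(dosages))),
    sample_ids = sprintf("sample_%03d", seq_len(ncol(dosages)))
  ), class = "sim_truth")
}
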