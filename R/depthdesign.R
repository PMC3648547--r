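# Read-depth design: how many reads are needed to tell two dosage classes
# apart, and how the full 5-class confusion behaves at a given depth.

.check_design_pair <- function(p1, p2) {
  check_prob(p1, "p1"); check_prob(p2, "p2")
  if (p1 >= p2) stop_param("'p1' must be strictly less than 'p2'")
}

#' Minimum depth to discriminate two allele fractions (normal approximation)
#'
#' Sample-size formula for distinguishing two binomial proportions with the
#' arcsine variance-stabilising transformation:
#' `n = ceil[(z_{1-alpha/2} + z_{power})^2 / (2 asin sqrt(p2) - 2 asin sqrt(p1))^2]`.
#' For the canonical autotetraploid question -- simplex (expected alternate
#' fraction 0.25) versus duplex (0.5) at two-sided alpha 0.05 and power
#' 0.95 -- the formula gives 47.40, i.e. at least 48 reads.
#'
#' @param p1,p2 expected allele fractions of the two classes, `p1 < p2`.
#' @param alpha two-sided type-I error level.
#' @param power required discrimination probability.
#' @return Integer read depth.
#' @examples
#' min_depth_power(0.25, 0.5, alpha = 0.05, power = 0.95)  # 48
#' @export
min_depth_power <- function(p1, p2, alpha = 0.05, power = 0.95) {
  .check_design_pair(p1, p2)
  check_prob(alpha, "alpha", lo_open = TRUE, hi_open = TRUE)
  check_prob(power, "power", lo_open = TRUE, hi_open = TRUE)
  num <- (qnorm(1 - alpha / 2) + qnorm(power))^2
  den <- (2 * asin(sqrt(p2)) - 2 * asin(sqrt(p1)))^2
  as.integer(ceiling(num / den))
}

#' Minimum depth to discriminate two allele fractions (exact binomial)
#'
#' Exact counterpart of [min_depth_power()]: the smallest depth `n` such
#' that, when each observed alternate-read count is assigned to whichever of
#' `Binomial(n, p1)` and `Binomial(n, p2)` gives it the larger likelihood
#' (ties to the lower fraction), the misassignment probability is at most
#' `max_error` under both true classes. Found by ascending search with exact
#' binomial tail sums.
#'
#' @inheritParams min_depth_power
#' @param max_error maximum tolerated misassignment probability per class.
#' @param max_n search bound.
#' @return Integer read depth.
#' @examples
#' min_depth_exact(0.25, 0.5, max_error = 0.05)
#' @export
min_depth_exact <- function(p1, p2, max_error = 0.05, max_n = 1e6) {
  .check_design_pair(p1, p2)
  check_prob(max_error, "max_error", lo_open = TRUE, hi_open = TRUE)
  for (n in seq_len(max_n)) {
    k <- 0:n
    assign2 <- dbinom(k, n, p2) > dbinom(k, n, p1)
    err1 <- sum(dbinom(k[assign2], n, p1))
    err2 <- sum(dbinom(k[!assign2], n, p2))
    if (max(err1, err2) <= max_error) return(as.integer(n))
  }
  stop_param(sprintf("no depth <= %g meets max_error = %g", max_n, max_error))
}

#' Dosage misclassification matrix at a given depth
#'
#' Entry `(g, g')` is the exact probability that a sample whose true allele
#' copy number is `g` is called `g'` by the maximum-posterior rule of
#' [call_dosage()] (no GQ gate), obtained by summing binomial masses over
#' each class's decision region of alternate-read counts. Rows sum to 1.
#'
#' @param depth read depth (>= 1).
#' @param model an [error_model()].
#' @param prior 5-vector class prior (default uniform).
#' @return 5 x 5 numeric matrix, rows = true class, columns = called class.
#' @examples
#' round(misclassification_matrix(60, error_model(0.01)), 4)
#' @export
misclassification_matrix <- function(depth, model = error_model(),
                                     prior = NULL) {
  depth <- check_count(depth, "depth")
  prior <- .check_prior(prior)
  model <- as_error_model(model)
  f <- expected_alt_fraction(DOSAGES, model)
  k <- 0:depth
  post <- vapply(f, function(fg) dbinom(k, depth, fg) , numeric(depth + 1))
  post <- post * rep(prior, each = depth + 1)
  called <- max.col(post, ties.method = "first")  # ties -> lower dosage
  m <- matrix(0, PLOIDY + 1, PLOIDY + 1,
              dimnames = list(true = DOSAGES, called = DOSAGES))
  for (g in DOSAGES) {
    mass <- dbinom(k, depth, f[g + 1])
    m[g + 1, ] <- vapply(seq_len(PLOIDY + 1),
                         function(j) sum(mass[called == j]), numeric(1))
  }
  m
}

#' Depth design table over a grid
#'
#' Convenience wrapper evaluating both design rules over a grid of class
#' pairs and, for the exact rule, error levels.
#'
#' @param pairs data.frame with columns `p1`, `p2`.
#' @param alpha,power passed to [min_depth_power()].
#' @param max_error passed to [min_depth_exact()].
#' @return The input with columns `depth_power` and `depth_exact` appended.
#' @export
depth_design_table <- function(pairs, alpha = 0.05, power = 0.95,
                               max_error = 0.05) {
  pairs$depth_power <- mapply(min_depth_power, pairs$p1, pairs$p2,
                              MoreArgs = list(alpha = alpha, power = power))
  pairs$depth_exact <- mapply(min_depth_exact, pairs$p1, pairs$p2,
                              MoreArgs = list(max_error = max_error))
  pairs
}
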