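# Internal helpers shared across modules.

DOSAGES <- 0:4
PLOIDY <- 4L

stop_param <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop_param(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE,
                       hi_open = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stop_param(sprintf("'%s' must be numeric", name))
  bad <- if (lo_open) x <= lo else x < lo
  bad <- bad | if (hi_open) x >= hi else x > hi
  if (any(bad)) {
    stop_param(sprintf("'%s' must lie in %s%g, %g%s", name,
                       if (lo_open) "(" else "[", lo, hi,
                       if (hi_open) ")" else "]"))
  }
  x
}

# ErrorModel constructor: epsilon = wrong-allele read probability,
# beta = relative capture efficiency of the alternate allele.
#' Sequencing error / capture bias model
#'
#' Bundles the two nuisance parameters of the read-count model: the
#' probability `error_rate` that a read reports the wrong allele, and the
#' relative capture (pull-down) efficiency `alt_bias` of the alternate allele
#' during hybridisation-based target enrichment. `alt_bias = 1` means no
#' bias; values below 1 under-represent the alternate allele.
#'
#' @param error_rate wrong-allele read probability, in `[0, 0.5)`.
#' @param alt_bias alternate-allele capture efficiency, in `(0, 1]`.
#' @return An object of class `error_model`.
#' @examples
#' error_model(0.01, 1)
#' @export
error_model <- function(error_rate = 0, alt_bias = 1) {
  check_prob(error_rate, "error_rate", 0, 0.5, hi_open = TRUE)
  check_prob(alt_bias, "alt_bias", 0, 1, lo_open = TRUE)
  structure(list(error_rate = error_rate, alt_bias = alt_bias),
            class = "error_model")
}

as_error_model <- function(x) {
  if (is.null(x)) return(error_model())
  if (inherits(x, "error_model")) return(x)
  stop_param("expected an 'error_model' object (see error_model())")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> error_rate = %g, alt_bias = %g\n",
              x$error_rate, x$alt_bias))
  invisible(x)
}

#' Phred-scale an error probability
#'
#' Converts an error probability to a phred quality score, `-10 * log10(p)`.
#' Probabilities below the cap-equivalent floor (`10^(-cap/10)`) return the
#' cap, so a zero error probability maps to `cap` rather than `Inf`.
#'
#' @param p_error error probability (vectorised), in `[0, 1]`.
#' @param cap maximum reported score (phred convention 99).
#' @return Numeric vector of phred scores in `[0, cap]`.
#' @examples
#' phred(0.1)            # 10
#' phred(10^(-2.6))      # 26: a 0.25% call-error probability
#' @export
phred <- function(p_error, cap = 99) {
  check_prob(p_error, "p_error")
  pmin(-10 * log10(pmax(p_error, 10^(-cap / 10))), cap)
}
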