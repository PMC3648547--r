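# Accessible-genome definition from per-base coverage profiles.

#' Per-base depth/mapping-quality profile
#'
#' @param chrom character vector of chromosome/contig names, one per base.
#' @param pos 0-based base positions, sorted (and unique) within chromosome.
#' @param counts matrix of per-sample counts of reads with MQ > 30 (bases in
#'   rows, samples in columns).
#' @param mq0_frac per-base fraction of reads mapping with MQ = 0.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(chrom, pos, counts, mq0_frac) {
  counts <- as.matrix(counts)
  n <- length(pos)
  if (length(chrom) != n || nrow(counts) != n || length(mq0_frac) != n) {
    stop_param("profile components differ in length")
  }
  if (anyNA(counts) || any(counts < 0)) stop_param("counts must be >= 0")
  check_prob(mq0_frac, "mq0_frac")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop_param(sprintf("positions on '%s' are not strictly increasing", ch))
    }
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 counts = counts, mq0_frac = mq0_frac),
            class = "depth_profile")
}

#' Call accessible regions from a coverage profile
#'
#' A base is adequately covered when at least `min_samples` samples each
#' have at least `min_reads` reads with MQ > 30 at the base (evaluated per
#' base independently; the qualifying samples may change along a run).
#' Maximal runs of contiguous covered bases form candidate regions; runs
#' shorter than `min_length` bp are dropped, regions whose mean per-base
#' MQ0 fraction exceeds `max_mq0_frac` are dropped, and regions overlapping
#' the organelle-homology mask are dropped.
#'
#' @param profile a [depth_profile()].
#' @param min_samples minimum number of qualifying samples per base.
#' @param min_reads per-sample read-count threshold (inclusive, MQ > 30).
#' @param min_length minimum region length in bp (default 261, a typical
#'   sequencing-library fragment size).
#' @param max_mq0_frac maximum tolerated multi-mapping read fraction.
#' @param organelle_mask optional [GenomicRanges::GRanges] of regions with
#'   high organelle homology (precomputed; homology search is upstream).
#' @return A sorted, non-overlapping [GenomicRanges::GRanges] with a
#'   `label` metadata column.
#' @export
accessible_regions <- function(profile, min_samples = 5, min_reads = 20,
                               min_length = 261, max_mq0_frac = 0.05,
                               organelle_mask = NULL) {
  if (!inherits(profile, "depth_profile")) {
    stop_param("'profile' must be a depth_profile")
  }
  covered <- rowSums(profile$counts >= min_reads) >= min_samples
  if (!any(covered)) return(.empty_regions())
  # runs of contiguous covered bases within a chromosome: break a run at a
  # chromosome change or any gap in the covered positions
  idx <- which(covered)
  ch <- profile$chrom[idx]
  po <- profile$pos[idx]
  n <- length(idx)
  new_run <- c(TRUE, ch[-1] != ch[-n] | po[-1] != po[-n] + 1L)
  runs <- split(idx, cumsum(new_run))
  reg <- lapply(runs, function(ix) {
    list(chrom = profile$chrom[ix[1]],
         start0 = profile$pos[ix[1]],
         end0 = profile$pos[ix[length(ix)]] + 1L,
         mq0 = mean(profile$mq0_frac[ix]))
  })
  len <- vapply(reg, function(r) r$end0 - r$start0, integer(1))
  mq0 <- vapply(reg, function(r) r$mq0, numeric(1))
  reg <- reg[len >= min_length & mq0 <= max_mq0_frac]
  if (length(reg) == 0) return(.empty_regions())
  gr <- GenomicRanges::GRanges(
    vapply(reg, `[[`, character(1), "chrom"),
    IRanges::IRanges(start = vapply(reg, `[[`, integer(1), "start0") + 1L,
                     end = vapply(reg, `[[`, integer(1), "end0"))
  )
  if (!is.null(organelle_mask)) {
    # masks on other chromosomes legitimately share no seqlevels
    hit <- suppressWarnings(IRanges::overlapsAny(gr, organelle_mask))
    gr <- gr[!hit]
  }
  if (length(gr) == 0) return(.empty_regions())
  gr <- GenomicRanges::sort(gr)
  S4Vectors::mcols(gr)$label <- sprintf("region_%04d", seq_along(gr))
  gr
}

.empty_regions <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$label <- character(0)
  gr
}

#' Re-express a region set as a saturated depth profile
#'
#' Utility mainly used to check idempotence of [accessible_regions()]: every
#' base of every region gets `n_samples` samples at `reads` reads and zero
#' MQ0 fraction.
#'
#' @param regions a `GRanges`.
#' @param n_samples,reads profile values to assign.
#' @return A [depth_profile()].
#' @export
regions_to_profile <- function(regions, n_samples = 5, reads = 20) {
  chrom <- rep(as.character(GenomicRanges::seqnames(regions)),
               GenomicRanges::width(regions))
  pos <- unlist(lapply(seq_along(regions), function(i) {
    seq(GenomicRanges::start(regions)[i] - 1L,
        GenomicRanges::end(regions)[i] - 1L)
  }), use.names = FALSE)
  depth_profile(chrom, pos,
                matrix(reads, length(pos), n_samples),
                rep(0, length(pos)))
}
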