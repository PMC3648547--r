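# File-format plumbing: VCF v4.2 with tetraploid genotypes, BED regions,
# CSV tables, and flat key-value configs.
#
# VCF dialect: FORMAT GT (four unphased "/"-separated alleles), AD
# (ref,alt), DP, GQ, MR (missing-reason: low_depth / low_gq); INFO VT
# (variant class) and ANN (coding/noncoding/unknown). BED is 0-based
# half-open; VCF positions are 1-based. Coordinate conversions are
# centralised here.

.default_site_info <- function(site_ids) {
  data.frame(site_id = site_ids,
             chrom = "contig_1",
             pos = seq_along(site_ids) * 100L,
             ref = "A", alt = "T",
             class = "SNP", annotation = "unknown",
             stringsAsFactors = FALSE)
}

.gt_string <- function(dosage) {
  ifelse(is.na(dosage), "./././.",
         vapply(dosage, function(g) {
           paste(c(rep("0", PLOIDY - g), rep("1", g)), collapse = "/")
         }, character(1)))
}

.gt_to_dosage <- function(gt) {
  vapply(strsplit(gt, "[/|]"), function(a) {
    if (any(a == ".")) NA_integer_ else sum(a == "1")
  }, integer(1))
}

#' Write dosage calls (and read counts) as VCF v4.2
#'
#' Emits tetraploid unphased genotypes (`0/0/0/1` style) with AD, DP, GQ
#' and a missing-reason tag MR per sample, plus INFO fields VT (variant
#' class) and ANN (annotation).
#'
#' @param calls a `genotype_matrix` from [call_matrix()].
#' @param counts the matching [site_counts()] (for the AD field).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, counts, path) {
  if (!inherits(calls, "genotype_matrix")) stop_param("'calls' must be a genotype_matrix")
  if (!inherits(counts, "site_counts")) stop_param("'counts' must be site_counts")
  info <- calls$site_info
  if (is.null(info)) info <- .default_site_info(calls$site_ids)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tetradose",
    "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant class (SNP/MNP/indel)\">",
    "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Annotation (coding/noncoding/unknown)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Tetraploid genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Genotype quality (phred)\">",
    "##FORMAT=<ID=MR,Number=1,Type=String,Description=\"Missing reason (low_depth/low_gq/.)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$sample_ids), collapse = "\t")
  )
  n <- nrow(calls$dosage)
  body <- vapply(seq_len(n), function(i) {
    cells <- vapply(seq_along(calls$sample_ids), function(j) {
      gq <- calls$gq[i, j]
      paste(.gt_string(calls$dosage[i, j]),
            paste0(counts$ref[i, j], ",", counts$alt[i, j]),
            calls$depth[i, j],
            if (is.na(gq)) "." else sprintf("%.4g", gq),
            if (is.na(calls$reason[i, j])) "." else calls$reason[i, j],
            sep = ":")
    }, character(1))
    paste(c(info$chrom[i], info$pos[i], info$site_id[i], info$ref[i],
            info$alt[i], ".", "PASS",
            sprintf("VT=%s;ANN=%s", info$class[i], info$annotation[i]),
            "GT:AD:DP:GQ:MR", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# geno(vcf)$AD comes back either as a 3-d array or as a matrix of lists,
# depending on the uniformity of the records; normalise to two matrices.
.split_ad <- function(ad) {
  if (is.array(ad) && length(dim(ad)) == 3) {
    list(ref = ad[, , 1, drop = TRUE], alt = ad[, , 2, drop = TRUE])
  } else {
    ref <- apply(ad, c(1, 2), function(x) x[[1]][1])
    alt <- apply(ad, c(1, 2), function(x) x[[1]][2])
    list(ref = ref, alt = alt)
  }
}

#' Read allele-specific read counts from VCF
#'
#' Parses the AD field of a VCF (the dialect of [write_calls_vcf()], or any
#' VCF carrying per-sample `ref,alt` allele depths) into a [site_counts()].
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @return A [site_counts()] with `site_info` filled from the VCF columns
#'   (and INFO VT/ANN when present).
#' @export
read_site_counts_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop_param("VCF has no AD FORMAT field")
  parts <- .split_ad(ad)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_chr <- vapply(as(VariantAnnotation::alt(vcf), "CharacterList"),
                    function(a) a[1], character(1))
  info <- data.frame(
    site_id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt_chr,
    stringsAsFactors = FALSE
  )
  vi <- VariantAnnotation::info(vcf)
  info$class <- if ("VT" %in% names(vi)) as.character(vi$VT) else {
    ifelse(nchar(info$ref) == 1 & nchar(info$alt) == 1, "SNP",
           ifelse(nchar(info$ref) == nchar(info$alt), "MNP", "indel"))
  }
  info$annotation <- if ("ANN" %in% names(vi)) as.character(vi$ANN) else "unknown"
  site_counts(ref = matrix(as.integer(parts$ref), nrow(info)),
              alt = matrix(as.integer(parts$alt), nrow(info)),
              site_ids = info$site_id,
              sample_ids = colnames(ad),
              site_info = info)
}

#' Read tetraploid dosage calls from VCF
#'
#' Converts GT strings to allele dosages by counting alternate alleles
#' (`0/0/1/1` imports as dosage 2; any `.` allele gives a missing call) and
#' carries DP, GQ and MR along when present.
#'
#' @param path VCF file.
#' @return List with matrices `dosage`, `depth`, `gq`, `reason` and the
#'   `site_info` data.frame.
#' @export
read_dosages_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(vcf)
  if (is.null(g$GT)) stop_param("VCF has no GT FORMAT field")
  dm <- matrix(.gt_to_dosage(as.vector(g$GT)), nrow(g$GT),
               dimnames = dimnames(g$GT))
  shape <- function(x, mode) {
    if (is.null(x)) return(NULL)
    storage.mode(x) <- mode
    x
  }
  reason <- g$MR
  if (!is.null(reason)) reason[reason == "."] <- NA_character_
  rr <- SummarizedExperiment::rowRanges(vcf)
  list(dosage = dm,
       depth = shape(g$DP, "integer"),
       gq = shape(g$GQ, "double"),
       reason = reason,
       site_info = data.frame(
         site_id = names(rr),
         chrom = as.character(GenomicRanges::seqnames(rr)),
         pos = GenomicRanges::start(rr),
         stringsAsFactors = FALSE))
}

#' Read / write region sets as BED
#'
#' BED uses 0-based half-open coordinates; in-memory regions are `GRanges`
#' (1-based closed). A BED record `(chr1, 100, 361)` imports as a width-261
#' range starting at 101.
#'
#' @param path BED file.
#' @return `read_regions_bed`: a `GRanges` with a `label` column.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lbl <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$label <-
    if (is.null(lbl)) sprintf("region_%04d", seq_along(gr)) else lbl
  gr
}

#' @rdname read_regions_bed
#' @param regions a `GRanges` (optionally with `label` / `annotation`).
#' @export
write_regions_bed <- function(regions, path) {
  gr <- regions
  lbl <- S4Vectors::mcols(gr)$label
  S4Vectors::mcols(gr) <- NULL
  if (!is.null(lbl)) S4Vectors::mcols(gr)$name <- lbl
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write read counts as CSV
#'
#' Long format with columns `site_id`, `sample_id`, `ref_reads`,
#' `alt_reads`.
#'
#' @param counts a [site_counts()].
#' @param path CSV file.
#' @export
write_counts_csv <- function(counts, path) {
  df <- data.frame(
    site_id = rep(counts$site_ids, times = length(counts$sample_ids)),
    sample_id = rep(counts$sample_ids, each = length(counts$site_ids)),
    ref_reads = as.vector(counts$ref),
    alt_reads = as.vector(counts$alt)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sites <- unique(df$site_id)
  samples <- unique(df$sample_id)
  ref <- matrix(NA_integer_, length(sites), length(samples))
  alt <- ref
  i <- match(df$site_id, sites)
  j <- match(df$sample_id, samples)
  ref[cbind(i, j)] <- df$ref_reads
  alt[cbind(i, j)] <- df$alt_reads
  site_counts(ref, alt, site_ids = sites, sample_ids = samples)
}

#' Write dosage calls (or simulation truth) as CSV
#'
#' @param calls a `genotype_matrix`, or a `sim_truth` for `write_truth_csv`.
#' @param path CSV file.
#' @export
write_calls_csv <- function(calls, path) {
  df <- data.frame(
    site_id = rep(calls$site_ids, times = length(calls$sample_ids)),
    sample_id = rep(calls$sample_ids, each = length(calls$site_ids)),
    dosage = as.vector(calls$dosage),
    gq = round(as.vector(calls$gq), 4),
    depth = as.vector(calls$depth),
    reason = as.vector(calls$reason)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calls_csv
#' @export
read_calls_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_calls_csv
#' @param truth a `sim_truth`.
#' @export
write_truth_csv <- function(truth, path) {
  df <- data.frame(
    site_id = rep(truth$site_ids, times = length(truth$sample_ids)),
    sample_id = rep(truth$sample_ids, each = length(truth$site_ids)),
    dosage = as.vector(truth$dosages)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flat key-value configuration files
#'
#' One `key=value` pair per line; values that parse as numbers are
#' coerced on read. Used to serialise [sim_config()] objects and by the
#' command-line interface's `--config`.
#'
#' @param config a [sim_config()] (for `write_sim_config`) or named list.
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  if (!inherits(config, "sim_config")) stop_param("'config' must be a sim_config")
  sp <- config$spectrum
  kv <- c(n_samples = config$n_samples, n_sites = config$n_sites,
          depth_median = config$depth_median,
          depth_log_sd = config$depth_log_sd,
          error_rate = config$model$error_rate,
          alt_bias = config$model$alt_bias,
          seed = config$seed)
  if (!is.null(sp$fixed)) {
    kv <- c(kv, spectrum_fixed = sp$fixed)
  } else {
    kv <- c(kv, spectrum_w_rare = sp$w_rare,
            spectrum_shape1_rare = sp$shape1_rare,
            spectrum_shape2_rare = sp$shape2_rare,
            spectrum_shape1_common = sp$shape1_common,
            spectrum_shape2_common = sp$shape2_common,
            spectrum_ref_major_prob = sp$ref_major_prob)
  }
  writeLines(paste0(names(kv), "=", vapply(kv, format, character(1))), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  kv <- read_config(path)
  spectrum <- if (!is.null(kv$spectrum_fixed)) {
    maf_spectrum_params(fixed = kv$spectrum_fixed)
  } else if (!is.null(kv$spectrum_w_rare)) {
    maf_spectrum_params(w_rare = kv$spectrum_w_rare,
                        shape1_rare = kv$spectrum_shape1_rare,
                        shape2_rare = kv$spectrum_shape2_rare,
                        shape1_common = kv$spectrum_shape1_common,
                        shape2_common = kv$spectrum_shape2_common,
                        ref_major_prob = kv$spectrum_ref_major_prob)
  } else maf_spectrum_params()
  sim_config(n_samples = kv$n_samples, n_sites = kv$n_sites,
             spectrum = spectrum,
             depth_median = kv$depth_median, depth_log_sd = kv$depth_log_sd,
             error_rate = kv$error_rate, alt_bias = kv$alt_bias,
             seed = kv$seed)
}

#' @rdname write_sim_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  kv <- lapply(parts, function(p) {
    v <- trimws(p[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(kv) <- trimws(vapply(parts, `[[`, character(1), 1))
  kv
}
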