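#' Read a variant profile from a VCF file
#'
#' Parses a VCF (v4.x) and converts every record into a position-only
#' variant: `start = POS`, `end = POS + nchar(REF) - 1`. Alleles are used
#' only to compute the end coordinate; multi-allelic records and records
#' that differ only in ALT collapse to a single variant. No FILTER-based
#' exclusion is applied by default: the method deliberately keeps every
#' record, including common SNPs, because the reference libraries may or may
#' not have been SNP-filtered and the weighting scheme downweights shared
#' variants anyway.
#'
#' @param path path to a VCF file.
#' @param ccl_id cell line name to attach; defaults to the file base name.
#' @param library_id source library name.
#' @param pass_only if `TRUE`, keep only records whose FILTER is `PASS` or
#'   missing (`.`). Default `FALSE`.
#' @return a [ccl_profile()].
#' @export
read_vcf_profile <- function(path, ccl_id = NULL, library_id = "user",
                             pass_only = FALSE) {
  if (!file.exists(path)) stop_format("VCF file not found: %s", path)
  if (is.null(ccl_id)) ccl_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop_format("unparseable VCF '%s': %s", path, conditionMessage(e))
  )
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (pass_only && length(rr)) {
    filt <- as.character(rr$FILTER)
    rr <- rr[is.na(filt) | filt %in% c("PASS", ".")]
  }
  keys <- unique(granges_to_keys(rr))
  prof <- ccl_profile(ccl_id = ccl_id, library_id = library_id, variants = keys)
  if (length(prof$variants) == 0L) {
    warning(sprintf("VCF '%s' yielded an empty profile", path), call. = FALSE)
  }
  prof
}

#' Write a variant profile as a minimal VCF
#'
#' Emits a minimal valid VCF v4.2 with placeholder `N` alleles whose REF
#' length encodes the variant span, so that
#' `read_vcf_profile(write_vcf_profile(p))` reproduces `p`'s variant set
#' exactly. Records are sorted by chromosome and position, making output
#' byte-deterministic.
#'
#' @param profile a [ccl_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ccl_profile"))
  vt <- variant_table(profile$variants)
  setorder(vt, chrom, start, end)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=cclid;ccl_id=%s;library_id=%s",
            profile$ccl_id, profile$library_id),
    paste0("##INFO=<ID=END,Number=1,Type=Integer,",
           "Description=\"End position of the variant\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- header
  if (nrow(vt)) {
    ref <- strrep("N", vt$end - vt$start + 1L)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t.\t.\t.\tEND=%d",
                              vt$chrom, vt$start, ref, vt$end))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_data("cannot write VCF to '%s'", path)
  invisible(path)
}

#' Read a BED file into a genomic interval set
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention (`chromStart + 1`, `chromEnd`) and
#' chromosome labels are canonicalized. Intervals may overlap.
#'
#' @param path path to a BED file (3+ columns).
#' @return a `GRanges` of 1-based inclusive intervals.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_format("BED file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) return(GenomicRanges::GRanges())
  # validate coordinates before import so chromEnd <= chromStart is a
  # format error rather than a silently dropped or zero-width range
  body <- raw[!grepl("^(track|browser|#)", raw)]
  flds <- strsplit(body, "\t| +")
  for (i in seq_along(flds)) {
    f <- flds[[i]]
    if (length(f) < 3L) stop_format("BED line %d has fewer than 3 columns", i)
    s <- suppressWarnings(as.numeric(f[2L])); e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e)) stop_format("BED line %d has non-numeric coordinates", i)
    if (e <= s) stop_format("BED line %d: chromEnd (%s) <= chromStart (%s)",
                            i, f[3L], f[2L])
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop_format("unparseable BED '%s': %s", path, conditionMessage(e))
  )
  chrom <- canonicalize_chrom(as.character(GenomicRanges::seqnames(gr)))
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::ranges(gr))
}
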