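#' Canonicalize a chromosome label
#'
#' Strips a leading `"chr"` prefix (any capitalization), uppercases the
#' remainder, and maps the mitochondrial label `"M"` to `"MT"`, so that
#' UCSC-style (`chr7`, `chrM`) and Ensembl/GRC-style (`7`, `MT`) files
#' interoperate. Contigs outside the canonical set (unplaced scaffolds etc.)
#' are retained verbatim after prefix stripping, not dropped.
#'
#' @param raw character vector of chromosome labels.
#' @return character vector of canonical labels.
#' @examples
#' canonicalize_chrom(c("chr7", "X", "chrM"))
#' @export
canonicalize_chrom <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  raw <- as.character(raw)
  bad <- is.na(raw) | !nzchar(trimws(raw))
  if (any(bad)) {
    stop_format("empty or whitespace-only chromosome label at position %d",
                which(bad)[1L])
  }
  out <- toupper(sub("^chr", "", raw, ignore.case = TRUE))
  out[out == "M"] <- "MT"
  out
}

#' Construct genomic variant keys
#'
#' A small variant is identified purely by its chromosome, 1-based inclusive
#' start and end; alleles play no role in variant identity, so calls from
#' different technologies and callers remain comparable. Variants are
#' represented internally as strings `"chrom:start:end"`.
#'
#' @param chrom character vector of chromosome labels (canonicalized).
#' @param start,end integer vectors, 1-based inclusive; `end >= start >= 1`.
#' @return character vector of variant keys.
#' @examples
#' genomic_variant("chr12", 25398284, 25398284)
#' @export
genomic_variant <- function(chrom, start, end = start) {
  chrom <- canonicalize_chrom(chrom)
  if (any(grepl("\\s", chrom))) stop_format("chromosome label contains whitespace")
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop_format("non-integer variant coordinates")
  }
  if (any(start < 1L)) stop_format("variant start must be >= 1")
  if (any(end < start)) stop_format("variant end must be >= start")
  paste(chrom, start, end, sep = ":")
}

## key string -> data.table(chrom, start, end)
variant_table <- function(keys) {
  if (length(keys) == 0L) {
    return(data.table(chrom = character(0), start = integer(0), end = integer(0)))
  }
  parts <- tstrsplit(keys, ":", fixed = TRUE)
  n <- length(parts)
  # chromosome labels themselves never contain ':' (validated at construction)
  data.table(chrom = parts[[1L]],
             start = as.integer(parts[[2L]]),
             end = as.integer(parts[[3L]]))
}

keys_to_granges <- function(keys) {
  vt <- variant_table(keys)
  GenomicRanges::GRanges(seqnames = vt$chrom,
                         ranges = IRanges::IRanges(start = vt$start, end = vt$end))
}

granges_to_keys <- function(gr, canonicalize = TRUE) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (canonicalize && length(chrom)) chrom <- canonicalize_chrom(chrom)
  if (length(chrom) == 0L) return(character(0))
  paste(chrom, GenomicRanges::start(gr), GenomicRanges::end(gr), sep = ":")
}

#' Create a CCL variant profile
#'
#' A profile is the deduplicated set of small variants called for one cancer
#' cell line sample, plus its identifiers. Variant order is canonical
#' (sorted), so two profiles with the same variant set compare identical.
#'
#' @param ccl_id raw cell line name.
#' @param library_id name of the source library/repository.
#' @param variants character vector of variant keys from [genomic_variant()].
#' @return an object of class `ccl_profile`.
#' @seealso [read_vcf_profile()], [write_vcf_profile()]
#' @export
ccl_profile <- function(ccl_id, library_id, variants = character(0)) {
  stopifnot(is.character(ccl_id), length(ccl_id) == 1L, nzchar(ccl_id),
            is.character(library_id), length(library_id) == 1L)
  variants <- sort(unique(as.character(variants)), method = "radix")
  structure(list(ccl_id = ccl_id, library_id = library_id, variants = variants),
            class = "ccl_profile")
}

#' @export
print.ccl_profile <- function(x, ...) {
  cat(sprintf("<ccl_profile> %s [%s]: %d variants\n",
              x$ccl_id, x$library_id, length(x$variants)))
  if (length(x$variants)) {
    shown <- utils::head(x$variants, 5L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$variants) > 5L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.ccl_profile <- function(x) length(x$variants)
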