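#' Define a sequencing panel
#'
#' A panel is a named set of genomic target intervals (1-based inclusive,
#' e.g. from [read_bed()]). Restricting a variant profile to a panel
#' emulates panel sequencing of the same sample.
#'
#' @param name panel name (used to suffix restricted profiles).
#' @param regions a `GRanges` of target intervals, or a data.frame with
#'   columns `chrom`, `start`, `end` (1-based inclusive).
#' @param gene_count number of genes the panel represents (metadata);
#'   defaults to the number of regions.
#' @return an object of class `ccl_panel`.
#' @export
panel_definition <- function(name, regions, gene_count = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.data.frame(regions)) {
    regions <- GenomicRanges::GRanges(
      seqnames = canonicalize_chrom(as.character(regions$chrom)),
      ranges = IRanges::IRanges(start = regions$start, end = regions$end))
  }
  stopifnot(methods::is(regions, "GRanges"))
  if (is.null(gene_count)) gene_count <- length(regions)
  structure(list(name = name, regions = regions,
                 gene_count = as.integer(gene_count)),
            class = "ccl_panel")
}

#' @export
print.ccl_panel <- function(x, ...) {
  cat(sprintf("<ccl_panel> '%s': %d regions (%d genes), %.0f bases\n",
              x$name, length(x$regions), x$gene_count,
              sum(as.numeric(GenomicRanges::width(x$regions)))))
  invisible(x)
}

#' Restrict a variant profile to panel regions
#'
#' Keeps exactly the variants whose `[start, end]` span shares at least one
#' base with some panel interval (any-base overlap, as `bedtools intersect`
#' does by default). The result is always a subset of the input; the cell
#' line name is preserved and the library name is suffixed with the panel
#' name.
#'
#' @param profile a [ccl_profile()].
#' @param panel a [panel_definition()] with at least one region.
#' @return the restricted [ccl_profile()].
#' @export
restrict_profile <- function(profile, panel) {
  stopifnot(inherits(profile, "ccl_profile"), inherits(panel, "ccl_panel"))
  if (length(panel$regions) == 0L) {
    stop_data("panel '%s' has no regions", panel$name)
  }
  suffix <- paste0("_", panel$name)
  lib_id <- if (endsWith(profile$library_id, suffix)) profile$library_id
            else paste0(profile$library_id, suffix)
  if (length(profile$variants) == 0L) {
    return(ccl_profile(profile$ccl_id, lib_id, character(0)))
  }
  gr <- keys_to_granges(profile$variants)
  hits <- GenomicRanges::findOverlaps(gr, panel$regions, minoverlap = 1L)
  keep <- profile$variants[unique(S4Vectors::queryHits(hits))]
  ccl_profile(profile$ccl_id, lib_id, keep)
}

#' Restrict many profiles to each of several panels
#'
#' Produces one restricted copy of every profile per panel (the
#' panel-sequencing benchmark construction: `n profiles x m panels`
#' restricted profiles).
#'
#' @param profiles list of [ccl_profile()] objects.
#' @param panels list of [panel_definition()] objects.
#' @return named list (one element per panel) of lists of restricted
#'   profiles.
#' @export
panel_sweep <- function(profiles, panels) {
  if (inherits(profiles, "ccl_profile")) profiles <- list(profiles)
  if (inherits(panels, "ccl_panel")) panels <- list(panels)
  stopifnot(length(panels) >= 1L)
  out <- lapply(panels, function(p) lapply(profiles, restrict_profile, panel = p))
  names(out) <- vapply(panels, `[[`, character(1), "name")
  out
}
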