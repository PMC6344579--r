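#' Coordinate-only genome model
#'
#' 24 chromosomes (1-22, X, Y) with human-proportional lengths scaled to a
#' configurable total. The default total of 30 Mb is an exome-scale
#' coordinate space: every technology the synthetic data emulates
#' (RNA-seq, exome, hybrid-capture, panel) interrogates genic territory, so
#' variants are modelled as uniform over a gene-dense space rather than the
#' full 3 Gb genome. Positions only; no sequence.
#'
#' @param total_length total genome length in bases (default `3e7`).
#' @return named integer vector of chromosome lengths.
#' @export
genome_model <- function(total_length = 3e7) {
  stopifnot(is.numeric(total_length), total_length >= 24)
  hs_mb <- c(249, 243, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
             114, 107, 102, 90, 83, 80, 59, 63, 48, 51, 155, 57)
  names(hs_mb) <- c(as.character(1:22), "X", "Y")
  len <- pmax(1L, as.integer(round(hs_mb / sum(hs_mb) * total_length)))
  names(len) <- names(hs_mb)
  len
}

## global offset (1..sum(genome)) -> (chrom, pos)
.offset_to_pos <- function(off, genome) {
  cum <- cumsum(as.numeric(genome))
  ci <- findInterval(off - 1, c(0, cum), rightmost.closed = FALSE)
  pos <- as.integer(off - c(0, cum)[ci])
  list(chrom = names(genome)[ci], pos = pos)
}

.offset_to_keys <- function(off, genome) {
  p <- .offset_to_pos(off, genome)
  paste(p$chrom, p$pos, p$pos, sep = ":")
}

## run code under a temporary RNG state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

#' Configuration of the synthetic profile generator
#'
#' The generated world mirrors the structure the identification method
#' assumes: several independent libraries holding copies of the same cell
#' lines, each cell line owning private (informative) variants plus a
#' subset of a shared common-SNP background, and libraries whose mean
#' per-profile variant counts differ by powers of two (technology scope).
#'
#' Library scaling is *nested*: every master variant of a cell line carries
#' a coverage quantile `u`, and the copy stored in a library with size
#' factor `s` keeps the variants with `u <= s`. Scope differences between
#' real technologies are ordered (panel targets sit inside exome targets,
#' which sit inside transcribed regions), so smaller-scope libraries see a
#' subset of what larger-scope libraries see -- independent per-variant
#' thinning would instead make cross-library overlaps shrink with the
#' *product* of the two scales, which no technology pair exhibits.
#'
#' Background carrier probabilities follow a Beta distribution with mean
#' `background_rate` (concentration `background_concentration`), i.e. a
#' heavy-tailed site-frequency-like spectrum: many background variants are
#' carried by only one or two lines, some by nearly all. Only the mean
#' carriage per line (`background_rate * background_pool_size`) is fixed.
#'
#' @param n_libraries number of reference libraries.
#' @param n_ccl number of distinct cell lines.
#' @param presence_prob probability a cell line appears in a given library.
#' @param private_variant_range integer `(min, max)` of per-line private
#'   variants.
#' @param background_pool_size size of the shared common-SNP pool.
#' @param background_rate mean fraction of the pool carried per cell line.
#' @param background_concentration Beta concentration of per-variant
#'   carrier probabilities (1 = strongly skewed, large = near-uniform).
#' @param library_size_factors per-library scale factors in `(0, 1]`;
#'   default consecutive powers of two `(1, 1/2, 1/4, ...)`.
#' @param retention_rate,noise_rate defaults used when deriving queries,
#'   see [derive_query()].
#' @param genome a [genome_model()].
#' @param seed integer RNG seed; fixed seed implies byte-identical output.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_libraries = 3, n_ccl = 100, presence_prob = 0.8,
                         private_variant_range = c(500, 2000),
                         background_pool_size = 20000, background_rate = 0.3,
                         background_concentration = 1,
                         library_size_factors = NULL,
                         retention_rate = 0.3, noise_rate = 0.2,
                         genome = genome_model(), seed = 42) {
  if (is.null(library_size_factors)) {
    library_size_factors <- 2^(-(seq_len(n_libraries) - 1))
  }
  stopifnot(n_libraries >= 1, n_ccl >= 1,
            presence_prob >= 0, presence_prob <= 1,
            length(private_variant_range) == 2L,
            private_variant_range[1] >= 0,
            private_variant_range[2] >= private_variant_range[1],
            background_pool_size >= 0,
            background_rate >= 0, background_rate <= 1,
            background_concentration > 0,
            length(library_size_factors) == n_libraries,
            all(library_size_factors > 0), all(library_size_factors <= 1),
            retention_rate >= 0, retention_rate <= 1,
            noise_rate >= 0, noise_rate <= 1,
            is.numeric(genome), length(genome) >= 1)
  total <- sum(as.numeric(genome))
  if (background_pool_size > total) {
    stop_data("background pool (%d) larger than the genome model (%.0f bases)",
              background_pool_size, total)
  }
  if (private_variant_range[2] > total) {
    stop_data("private variant range exceeds the genome model")
  }
  structure(list(n_libraries = as.integer(n_libraries),
                 n_ccl = as.integer(n_ccl),
                 presence_prob = presence_prob,
                 private_variant_range = as.integer(private_variant_range),
                 background_pool_size = as.integer(background_pool_size),
                 background_rate = background_rate,
                 background_concentration = background_concentration,
                 library_size_factors = library_size_factors,
                 retention_rate = retention_rate, noise_rate = noise_rate,
                 genome = genome, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic multi-library collection of CCL profiles
#'
#' Each cell line owns a master variant set (private variants placed
#' uniformly on the genome model, plus its background subset); every
#' library the line is present in stores a nested, library-scaled copy.
#' The returned truth lists every cross-library pair of profiles of the
#' same cell line.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_collection`: `libraries` (list of
#'   `ccl_library`), `truth` (list with `members` and `pairs` data.tables)
#'   and `config`.
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    genome <- config$genome
    total <- sum(as.numeric(genome))
    nL <- config$n_libraries
    pool_off <- sort(sample.int(total, config$background_pool_size))
    k <- config$background_concentration
    r <- config$background_rate
    pool_pi <- if (config$background_pool_size > 0 && r > 0) {
      rbeta(config$background_pool_size, r * k, (1 - r) * k)
    } else numeric(0)
    ccl_ids <- sprintf("CCL%04d", seq_len(config$n_ccl))
    lib_ids <- sprintf("synthlib%d", seq_len(nL))
    lib_profiles <- lapply(seq_len(nL), function(j) list())
    members <- vector("list", config$n_ccl)
    for (ci in seq_len(config$n_ccl)) {
      carries <- if (length(pool_pi)) which(runif(length(pool_pi)) < pool_pi)
                 else integer(0)
      pr <- config$private_variant_range
      npriv <- if (pr[2] > pr[1]) sample(pr[1]:pr[2], 1L) else pr[1]
      priv_off <- if (npriv > 0) sample.int(total, npriv) else integer(0)
      off <- unique(c(pool_off[carries], priv_off))
      u <- runif(length(off))
      present <- runif(nL) < config$presence_prob
      keys <- .offset_to_keys(off, genome)
      for (j in which(present)) {
        sel <- u <= config$library_size_factors[j]
        lib_profiles[[j]][[length(lib_profiles[[j]]) + 1L]] <-
          ccl_profile(ccl_ids[ci], lib_ids[j], keys[sel])
      }
      if (any(present)) {
        members[[ci]] <- data.table(ccl_id = ccl_ids[ci],
                                    library_id = lib_ids[which(present)])
      }
    }
    keep <- which(vapply(lib_profiles, length, integer(1)) > 0L)
    if (length(keep) == 0L) stop_data("generated collection is empty")
    libraries <- lapply(keep, function(j) {
      build_library(lib_profiles[[j]], library_id = lib_ids[j])
    })
    memb <- rbindlist(members)
    a <- copy(memb); b <- copy(memb)
    setnames(b, "library_id", "library_id_b")
    pairs <- merge(a, b, by = "ccl_id", allow.cartesian = TRUE)
    pairs <- pairs[library_id < library_id_b]
    structure(list(libraries = libraries,
                   truth = list(members = memb,
                                pairs = pairs[, .(ccl_id, library_id_a = library_id,
                                                  library_id_b)]),
                   config = config),
              class = "synth_collection")
  })
}

#' @export
print.synth_collection <- function(x, ...) {
  cat(sprintf("<synth_collection> %d libraries, %d profiles, %d cross-library pairs\n",
              length(x$libraries),
              sum(vapply(x$libraries, function(l) length(l$profiles), integer(1))),
              nrow(x$truth$pairs)))
  invisible(x)
}

#' Derive a degraded query from a reference profile
#'
#' Emulates re-sequencing the same cell line with a different, smaller
#' scope technology plus caller noise: each variant of the source profile
#' is kept independently with probability `retention_rate`, and
#' `ceiling(noise_rate * |variants|)` novel variants absent from the source
#' are added at uniform genome positions.
#'
#' @param profile source [ccl_profile()].
#' @param retention_rate,noise_rate rates in `[0, 1]`.
#' @param seed optional RNG seed for reproducible derivation.
#' @param genome a [genome_model()] used for noise placement.
#' @return a [ccl_profile()] with the same identifiers.
#' @export
derive_query <- function(profile, retention_rate = 0.3, noise_rate = 0.2,
                         seed = NULL, genome = genome_model()) {
  stopifnot(inherits(profile, "ccl_profile"),
            retention_rate >= 0, retention_rate <= 1,
            noise_rate >= 0, noise_rate <= 1)
  .with_seed(seed, {
    n <- length(profile$variants)
    kept <- if (n > 0) profile$variants[runif(n) < retention_rate] else character(0)
    n_noise <- ceiling(noise_rate * n)
    noise <- character(0)
    if (n_noise > 0) {
      total <- sum(as.numeric(genome))
      src <- profile$variants
      tries <- 0L
      while (length(noise) < n_noise && tries < 50L) {
        cand <- .offset_to_keys(sample.int(total, n_noise * 2L), genome)
        noise <- unique(c(noise, setdiff(cand, src)))
        tries <- tries + 1L
      }
      noise <- utils::head(noise, n_noise)
    }
    ccl_profile(profile$ccl_id, profile$library_id, c(kept, noise))
  })
}

#' Generate a synthetic sequencing panel
#'
#' Places `n_regions` non-overlapping gene-sized intervals uniformly on the
#' genome model; stands in for commercial panel manifests of matched gene
#' counts (e.g. 151/94/49 genes), whose region lists are not
#' redistributable.
#'
#' @param config a [synth_config()] (provides genome and base seed; the
#'   panel seed is derived from the base seed and `n_regions`, so panels of
#'   different sizes differ but each is reproducible).
#' @param n_regions number of regions (`>= 1`).
#' @param region_length region length in bases, default 10 kb.
#' @return a [panel_definition()] named `panel<n_regions>` (synthetic).
#' @export
generate_panel <- function(config, n_regions, region_length = 10000) {
  stopifnot(inherits(config, "synth_config"), n_regions >= 1, region_length >= 1)
  genome <- config$genome
  total <- sum(as.numeric(genome))
  if (n_regions * region_length > total / 2) {
    stop_data("genome model too small for %d regions of %d bases",
              n_regions, region_length)
  }
  seed <- (as.numeric(config$seed) * 7919 + n_regions) %% (2^31 - 1)
  .with_seed(seed, {
    cum <- c(0, cumsum(as.numeric(genome)))
    placed <- data.table(chrom = character(0), start = integer(0), end = integer(0))
    guard <- 0L
    while (nrow(placed) < n_regions && guard < 200L) {
      need <- n_regions - nrow(placed)
      off <- sample.int(total, need * 3L)
      p <- .offset_to_pos(off, genome)
      cand <- data.table(chrom = p$chrom, start = p$pos,
                         end = p$pos + as.integer(region_length) - 1L)
      cand <- cand[end <= genome[chrom]]
      cand <- rbind(placed, cand)
      # drop overlaps, keeping earlier (already placed) regions first
      setorder(cand, chrom, start)
      # linear scan per chromosome: drop any candidate starting before the
      # previous kept region ends
      ok <- rep(TRUE, nrow(cand))
      last_end <- -Inf; last_chr <- ""
      for (i in seq_len(nrow(cand))) {
        if (cand$chrom[i] != last_chr) { last_end <- -Inf; last_chr <- cand$chrom[i] }
        if (cand$start[i] <= last_end) ok[i] <- FALSE
        else last_end <- cand$end[i]
      }
      placed <- utils::head(cand[ok], n_regions)
      guard <- guard + 1L
    }
    if (nrow(placed) < n_regions) {
      stop_data("could not place %d non-overlapping regions", n_regions)
    }
    setorder(placed, chrom, start)
    panel_definition(paste0("panel", n_regions), placed,
                     gene_count = n_regions)
  })
}

#' Write a synthetic collection to disk
#'
#' Emits one VCF directory per library (`<dir>/<library_id>/<ccl_id>.vcf`),
#' a `members.tsv` and a `pairs.tsv` truth table. Output is
#' byte-deterministic given the collection.
#'
#' @param collection a `synth_collection`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "synth_collection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lib in collection$libraries) {
    ld <- file.path(dir, lib$library_id)
    dir.create(ld, showWarnings = FALSE)
    for (p in lib$profiles) {
      write_vcf_profile(p, file.path(ld, paste0(p$ccl_id, ".vcf")))
    }
  }
  fwrite(collection$truth$members, file.path(dir, "members.tsv"), sep = "\t")
  fwrite(collection$truth$pairs, file.path(dir, "pairs.tsv"), sep = "\t")
  invisible(dir)
}
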