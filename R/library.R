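#' Build a reference library from CCL profiles
#'
#' A reference library is a named, homogeneous collection of CCL variant
#' profiles (one repository/technology) together with a frequency index:
#' for every variant `v`, `f(v)` counts how many profiles of *this* library
#' contain `v`. Libraries are matched independently of one another, so
#' frequencies are never pooled across libraries.
#'
#' @param profiles list of [ccl_profile()] objects, all carrying
#'   `library_id`; cell line names must be unique within a library.
#' @param library_id library name; defaults to the profiles' common
#'   `library_id`.
#' @return an object of class `ccl_library` with elements `library_id`,
#'   `profiles` (named list) and `index` (data.table of variant/profile
#'   memberships).
#' @examples
#' p1 <- ccl_profile("A", "demo", genomic_variant("1", c(100, 200)))
#' p2 <- ccl_profile("B", "demo", genomic_variant("1", c(100, 300)))
#' lib <- build_library(list(p1, p2))
#' freq_index(lib)
#' @export
build_library <- function(profiles, library_id = NULL) {
  if (length(profiles) < 1L) stop_data("a library needs at least one profile")
  if (inherits(profiles, "ccl_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "ccl_profile")))
  lids <- unique(vapply(profiles, `[[`, character(1), "library_id"))
  if (is.null(library_id)) {
    if (length(lids) != 1L) {
      stop_data("profiles carry multiple library_ids (%s); pass library_id",
                paste(lids, collapse = ", "))
    }
    library_id <- lids
  } else if (!identical(lids, library_id)) {
    stop_data("profiles carry library_id(s) %s, expected '%s'",
              paste(lids, collapse = ", "), library_id)
  }
  ids <- vapply(profiles, `[[`, character(1), "ccl_id")
  if (anyDuplicated(ids)) {
    stop_data("duplicate ccl_id within library '%s': %s", library_id,
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(profiles) <- ids
  index <- .library_index(profiles)
  structure(list(library_id = library_id, profiles = profiles, index = index),
            class = "ccl_library")
}

## long membership table: one row per (variant, member profile)
.library_index <- function(profiles) {
  pieces <- lapply(profiles, function(p) {
    if (length(p$variants) == 0L) return(NULL)
    # data.table()'s `key` argument shadows a column of that name
    setDT(list(key = p$variants, ccl_id = rep(p$ccl_id, length(p$variants))))
  })
  idx <- rbindlist(pieces)
  if (nrow(idx) == 0L) {
    idx <- setDT(list(key = character(0), ccl_id = character(0)))
  }
  setkey(idx, key)
  idx
}

#' Per-variant frequency index of a library
#'
#' @param lib a `ccl_library`.
#' @return data.table with columns `key` (variant) and `f` (number of
#'   profiles of the library containing the variant, `1 <= f <= n profiles`).
#' @export
freq_index <- function(lib) {
  stopifnot(inherits(lib, "ccl_library"))
  lib$index[, .(f = .N), by = key]
}

#' @export
print.ccl_library <- function(x, ...) {
  nv <- length(unique(x$index$key))
  cat(sprintf("<ccl_library> '%s': %d profiles, %d distinct variants, %d memberships\n",
              x$library_id, length(x$profiles), nv, nrow(x$index)))
  invisible(x)
}

#' Variant inclusion weight
#'
#' The weight of a variant carried by `f` profiles of a library is
#' `w(f) = 2^(1-f)` (default scheme): a library-unique variant has weight 1,
#' and the weight halves with every additional carrier, so widely shared
#' (non-informative) variants are driven towards zero. A variant is
#' *characteristic* when its weight is at least the user-selected threshold;
#' threshold 1.0 therefore retains only library-unique variants and
#' threshold 0.0 retains everything. The `"reciprocal"` scheme `w(f) = 1/f`
#' (the first-generation weighting) is available for comparison; the two
#' differ only from `f = 3` on (0.25 vs 0.333...).
#'
#' @param f positive integer vector of per-library variant frequencies.
#' @param scheme `"halving"` (default, `2^(1-f)`) or `"reciprocal"` (`1/f`).
#' @return numeric weights in `(0, 1]`, strictly decreasing in `f`.
#' @examples
#' variant_weight(1:4)
#' @export
variant_weight <- function(f, scheme = c("halving", "reciprocal")) {
  scheme <- match.arg(scheme)
  if (length(f) == 0L) return(numeric(0))
  if (any(is.na(f)) || any(f < 1)) stop_data("variant frequency must be >= 1")
  switch(scheme,
         halving = 2^(1 - f),
         reciprocal = 1 / f)
}

## characteristic-variant index at a weight threshold; the workhorse behind
## characteristic_variants(), match_counts() and identify_ccl(). Returns the
## distinct characteristic pool size, the restricted membership table, and
## per-profile characteristic set sizes (zeros included).
.char_index <- function(lib, weight_threshold = 0.5,
                        scheme = c("halving", "reciprocal")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(lib, "ccl_library"),
            is.numeric(weight_threshold), length(weight_threshold) == 1L,
            weight_threshold >= 0, weight_threshold <= 1)
  fr <- freq_index(lib)
  keep <- fr[variant_weight(f, scheme) >= weight_threshold, key]
  long <- lib$index[J(keep), nomatch = 0L]
  sizes <- structure(integer(length(lib$profiles)), names = names(lib$profiles))
  if (nrow(long)) {
    cnt <- long[, .N, by = ccl_id]
    sizes[cnt$ccl_id] <- cnt$N
  }
  list(pool_size = length(keep), long = long, sizes = sizes,
       weight_threshold = weight_threshold, scheme = scheme,
       library_id = lib$library_id)
}

#' Characteristic variants of each profile at a weight threshold
#'
#' @param lib a `ccl_library`.
#' @param weight_threshold inclusion weight threshold in `[0, 1]`;
#'   default 0.5 (retains variants shared by at most two profiles under the
#'   halving scheme). 0.0 retains every variant.
#' @param scheme weight scheme, see [variant_weight()].
#' @return named list (one element per profile) of characteristic variant
#'   key vectors.
#' @export
characteristic_variants <- function(lib, weight_threshold = 0.5,
                                    scheme = c("halving", "reciprocal")) {
  idx <- .char_index(lib, weight_threshold, scheme)
  out <- lapply(names(lib$profiles), function(id) {
    sort(idx$long[ccl_id == id, key], method = "radix")
  })
  names(out) <- names(lib$profiles)
  out
}

#' Persist / restore a reference library
#'
#' The on-disk format is two plain TSV files:
#' `<prefix>.variants.tsv` (`chrom`, `start`, `end`, `n_members`, `members`
#' with comma-separated profile ids) and `<prefix>.profiles.tsv`
#' (`ccl_id`, `library_id`, `n_variants`). The round trip is lossless,
#' including empty profiles. Corrupt or truncated files raise a load error
#' rather than producing a silently partial library.
#'
#' @param lib a `ccl_library`.
#' @param prefix file path prefix (directory must exist).
#' @return `save_library()` returns `prefix` invisibly; `load_library()`
#'   returns the restored `ccl_library`.
#' @export
save_library <- function(lib, prefix) {
  stopifnot(inherits(lib, "ccl_library"))
  prof <- data.table(
    ccl_id = names(lib$profiles),
    library_id = lib$library_id,
    n_variants = vapply(lib$profiles, function(p) length(p$variants), integer(1))
  )
  idx <- copy(lib$index)
  if (nrow(idx)) {
    agg <- idx[, .(n_members = .N,
                   members = paste(sort(ccl_id, method = "radix"), collapse = ",")),
               by = key]
    vt <- variant_table(agg$key)
    vars <- cbind(vt, agg[, .(n_members, members)])
    setorder(vars, chrom, start, end)
  } else {
    vars <- data.table(chrom = character(0), start = integer(0), end = integer(0),
                       n_members = integer(0), members = character(0))
  }
  fwrite(vars, paste0(prefix, ".variants.tsv"), sep = "\t")
  fwrite(prof, paste0(prefix, ".profiles.tsv"), sep = "\t")
  invisible(prefix)
}

#' @rdname save_library
#' @export
load_library <- function(prefix) {
  vfile <- paste0(prefix, ".variants.tsv")
  pfile <- paste0(prefix, ".profiles.tsv")
  if (!file.exists(vfile) || !file.exists(pfile)) {
    stop_format("library store '%s' not found (need %s and %s)",
                prefix, basename(vfile), basename(pfile))
  }
  prof <- tryCatch(fread(pfile, sep = "\t", colClasses = list(character = "ccl_id")),
                   error = function(e) stop_format("corrupt profile table: %s",
                                                   conditionMessage(e)))
  vars <- tryCatch(fread(vfile, sep = "\t"),
                   error = function(e) stop_format("corrupt variant index: %s",
                                                   conditionMessage(e)))
  need_p <- c("ccl_id", "library_id", "n_variants")
  need_v <- c("chrom", "start", "end", "n_members", "members")
  if (!all(need_p %in% names(prof)) || !all(need_v %in% names(vars))) {
    stop_format("library store '%s' has unexpected columns", prefix)
  }
  if (nrow(prof) == 0L) stop_format("library store '%s' contains no profiles", prefix)
  lid <- unique(prof$library_id)
  if (length(lid) != 1L) stop_format("library store mixes library_ids")
  member_sets <- strsplit(vars$members, ",", fixed = TRUE)
  if (nrow(vars) && !identical(lengths(member_sets), as.integer(vars$n_members))) {
    stop_format("library store '%s' is corrupt: member counts disagree", prefix)
  }
  keys <- if (nrow(vars)) genomic_variant(as.character(vars$chrom), vars$start, vars$end)
          else character(0)
  long <- setDT(list(key = rep(keys, lengths(member_sets)),
                     ccl_id = as.character(unlist(member_sets))))
  if (nrow(long) && !all(unique(long$ccl_id) %in% prof$ccl_id)) {
    stop_format("library store '%s' is corrupt: unknown member profile ids", prefix)
  }
  profiles <- lapply(prof$ccl_id, function(id) {
    ccl_profile(id, lid, long[ccl_id == id, key])
  })
  lib <- build_library(profiles, library_id = lid)
  recount <- vapply(lib$profiles, function(p) length(p$variants), integer(1))
  if (!identical(unname(recount[prof$ccl_id]), as.integer(prof$n_variants))) {
    stop_format("library store '%s' is corrupt: variant counts disagree", prefix)
  }
  lib
}

#' Add or remove a profile of a reference library
#'
#' The frequency index is updated incrementally; the result is identical to
#' rebuilding the library from scratch. Users can thereby maintain custom
#' reference collections.
#'
#' @param lib a `ccl_library`.
#' @param profile a [ccl_profile()] whose `library_id` matches `lib` and
#'   whose `ccl_id` is not yet present.
#' @param ccl_id cell line name to remove (must be present).
#' @return the updated `ccl_library`.
#' @export
add_profile <- function(lib, profile) {
  stopifnot(inherits(lib, "ccl_library"), inherits(profile, "ccl_profile"))
  if (!identical(profile$library_id, lib$library_id)) {
    stop_data("profile library_id '%s' does not match library '%s'",
              profile$library_id, lib$library_id)
  }
  if (profile$ccl_id %in% names(lib$profiles)) {
    stop_data("ccl_id '%s' already present in library '%s'",
              profile$ccl_id, lib$library_id)
  }
  lib$profiles[[profile$ccl_id]] <- profile
  add <- if (length(profile$variants)) {
    setDT(list(key = profile$variants,
               ccl_id = rep(profile$ccl_id, length(profile$variants))))
  } else NULL
  lib$index <- rbindlist(list(lib$index, add))
  setkey(lib$index, key)
  lib
}

#' @rdname add_profile
#' @export
remove_profile <- function(lib, ccl_id) {
  stopifnot(inherits(lib, "ccl_library"))
  if (!ccl_id %in% names(lib$profiles)) {
    stop_data("ccl_id '%s' not present in library '%s'", ccl_id, lib$library_id)
  }
  if (length(lib$profiles) == 1L) {
    stop_data("cannot remove the last profile of library '%s'", lib$library_id)
  }
  drop <- ccl_id
  lib$profiles[[drop]] <- NULL
  lib$index <- lib$index[ccl_id != drop]
  setkey(lib$index, key)
  lib
}
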