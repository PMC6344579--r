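#' Normalize a cell line name
#'
#' Removes every character that is not a letter or digit and uppercases the
#' rest, the preprocessing under which e.g. `"MDA-MB-435"` becomes
#' `"MDAMB435"`. Distinct cell lines can collide after normalization
#' (`"TT"` vs `"T.T"`); such collisions are resolved by curation lists in
#' [build_gold_standard()].
#'
#' @param raw character vector of cell line names.
#' @return character vector of normalized names (A-Z, 0-9 only).
#' @export
normalize_ccl_name <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  out <- toupper(gsub("[^A-Za-z0-9]", "", as.character(raw)))
  bad <- !nzchar(out) | is.na(out)
  if (any(bad)) {
    stop_data("cell line name empty after normalization: '%s'",
              raw[which(bad)[1L]])
  }
  out
}

#' Flag candidate identity pairs from names
#'
#' Two distinct cell lines whose normalized names are in a prefix relation
#' (e.g. `MDAMB435` / `MDAMB435S`) are candidates for being identical and
#' should be resolved by literature curation; candidates are flagged, never
#' auto-merged.
#'
#' @param names character vector of raw cell line names.
#' @return data.table with columns `name_a`, `name_b` (raw names whose
#'   normalized forms are in a strict prefix relation or collide exactly).
#' @export
identity_candidates <- function(names) {
  names <- unique(as.character(names))
  norm <- normalize_ccl_name(names)
  out <- list()
  if (length(names) >= 2L) {
    cmb <- utils::combn(seq_along(names), 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      if (startsWith(norm[a], norm[b]) || startsWith(norm[b], norm[a])) {
        out[[length(out) + 1L]] <- data.table(name_a = names[a], name_b = names[b])
      }
    }
  }
  if (length(out) == 0L) return(data.table(name_a = character(0), name_b = character(0)))
  rbindlist(out)
}

#' Build a gold standard of cell line identity relationships
#'
#' Profiles from different libraries describe the same underlying cell line
#' when their normalized names match -- unless a curated *split* marks a
#' name collision as two distinct lines -- and additionally when a curated
#' *merge* links two differently-named lines known to share an origin
#' (e.g. a renamed derivative).
#'
#' @param members data.frame with columns `library_id` and `ccl_id`, one
#'   row per reference profile.
#' @param merge_list optional data.frame (`name_a`, `name_b`) of raw names
#'   curated as identical.
#' @param split_list optional data.frame (`name_a`, `name_b`) of raw names
#'   that collide after normalization but are distinct cell lines.
#' @return an object of class `ccl_gold`: a data.table of members with
#'   their identity `group`.
#' @examples
#' m <- data.frame(library_id = c("L1", "L2", "L1"),
#'                 ccl_id = c("TT", "T.T", "HELA"))
#' g <- build_gold_standard(m, split_list = data.frame(name_a = "TT", name_b = "T.T"))
#' gold_related(g, "L1", "TT", "L2", "T.T")  # FALSE despite the collision
#' @export
build_gold_standard <- function(members, merge_list = NULL, split_list = NULL) {
  members <- as.data.table(members)
  stopifnot(all(c("library_id", "ccl_id") %in% names(members)))
  members <- unique(members[, .(library_id = as.character(library_id),
                                ccl_id = as.character(ccl_id))])
  members[, norm := normalize_ccl_name(ccl_id)]
  members[, group := norm]
  pair_key <- function(df) {
    apply(cbind(as.character(df$name_a), as.character(df$name_b)), 1L,
          function(r) paste(sort(r), collapse = "\r"))
  }
  if (!is.null(merge_list) && !is.null(split_list) &&
      nrow(as.data.frame(merge_list)) && nrow(as.data.frame(split_list))) {
    both <- intersect(pair_key(as.data.frame(merge_list)),
                      pair_key(as.data.frame(split_list)))
    if (length(both)) {
      stop_data("pair(s) present in both merge and split lists: %s",
                gsub("\r", "/", paste(both, collapse = ", ")))
    }
  }
  if (!is.null(split_list)) {
    split_list <- as.data.frame(split_list)
    for (j in seq_len(nrow(split_list))) {
      a <- as.character(split_list$name_a[j]); b <- as.character(split_list$name_b[j])
      if (!identical(normalize_ccl_name(a), normalize_ccl_name(b))) {
        stop_data("split pair '%s'/'%s' does not collide after normalization", a, b)
      }
      # members carrying the second raw name get their own group
      members[ccl_id == b, group := paste0(norm, "//", b)]
    }
  }
  if (!is.null(merge_list)) {
    merge_list <- as.data.frame(merge_list)
    for (j in seq_len(nrow(merge_list))) {
      a <- normalize_ccl_name(as.character(merge_list$name_a[j]))
      b <- normalize_ccl_name(as.character(merge_list$name_b[j]))
      ga <- members[norm == a, unique(group)]
      gb <- members[norm == b, unique(group)]
      target <- if (length(ga)) ga[1L] else a
      from <- if (length(gb)) gb else b
      members[group %in% from, group := target]
    }
  }
  setattr(members, "class", c("ccl_gold", class(members)))
  members[]
}

#' Read a gold standard from a TSV file
#'
#' Expected columns: `library_id`, `ccl_id`, `canonical_group`.
#'
#' @param path path to a tab-separated file.
#' @return a `ccl_gold` object.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stop_format("gold standard file not found: %s", path)
  dt <- fread(path, sep = "\t", colClasses = "character")
  need <- c("library_id", "ccl_id", "canonical_group")
  if (!all(need %in% names(dt))) {
    stop_format("gold standard '%s' must have columns %s", path,
                paste(need, collapse = ", "))
  }
  out <- dt[, .(library_id, ccl_id, norm = normalize_ccl_name(ccl_id),
                group = canonical_group)]
  setattr(out, "class", c("ccl_gold", class(out)))
  out[]
}

## group of a (library_id, ccl_id); falls back to the normalized name for
## entries absent from the gold table (e.g. derived query profiles)
.gold_group <- function(gold, library_id, ccl_id) {
  look <- data.table(library_id = as.character(library_id),
                     ccl_id = as.character(ccl_id))
  res <- gold[look, on = c("library_id", "ccl_id"), mult = "first", x.group]
  miss <- is.na(res)
  if (any(miss)) {
    norm_m <- normalize_ccl_name(ccl_id[miss])
    by_name <- gold[data.table(norm = norm_m), on = "norm", mult = "first", x.group]
    res[miss] <- ifelse(is.na(by_name), norm_m, by_name)
  }
  res
}

#' Are two profiles gold-related?
#'
#' @param gold a `ccl_gold` object.
#' @param lib_a,ccl_a,lib_b,ccl_b identifiers of the two profiles
#'   (vectorized).
#' @return logical vector: same identity group.
#' @export
gold_related <- function(gold, lib_a, ccl_a, lib_b, ccl_b) {
  .gold_group(gold, lib_a, ccl_a) == .gold_group(gold, lib_b, ccl_b)
}

#' All identity pairs of a gold standard
#'
#' @param gold a `ccl_gold` object.
#' @return data.table of unordered pairs of distinct (library, cell line)
#'   entries sharing an identity group.
#' @export
identity_pairs <- function(gold) {
  a <- as.data.table(gold)[, .(library_id, ccl_id, group)]
  b <- copy(a)
  setnames(b, c("library_id_b", "ccl_id_b", "group"))
  pr <- merge(a, b, by = "group", allow.cartesian = TRUE)
  pr <- pr[paste(library_id, ccl_id, sep = "\r") <
           paste(library_id_b, ccl_id_b, sep = "\r")]
  pr[, .(group, library_id_a = library_id, ccl_id_a = ccl_id,
         library_id_b, ccl_id_b)]
}

#' Confusion counts and performance metrics of identification calls
#'
#' Each scored query/reference comparison contributes exactly one count:
#' TP if identified and gold-related, FP if identified and unrelated, FN if
#' not identified but related, TN otherwise. Sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), PPV = TP/(TP+FP), F1 = harmonic mean of PPV
#' and sensitivity. Undefined ratios are reported as `NA`, not zero.
#'
#' @param comparisons data.table with columns `query_library_id`,
#'   `query_ccl_id`, `library_id`, `ccl_id` (the reference) and
#'   `identified` (logical). A precomputed logical column `related` is used
#'   if present, otherwise relatedness is looked up in `gold`.
#' @param gold a `ccl_gold` object (required unless `related` is supplied).
#' @return list with `counts` (tp, fp, fn, tn), `metrics` (sensitivity,
#'   specificity, ppv, f1) and `possible_tp`.
#' @export
evaluate_calls <- function(comparisons, gold = NULL) {
  comparisons <- as.data.table(comparisons)
  if (nrow(comparisons) == 0L) stop_data("no comparisons to evaluate")
  if (!"related" %in% names(comparisons)) {
    if (is.null(gold)) stop_data("need a gold standard or a 'related' column")
    comparisons[, related := gold_related(gold, query_library_id, query_ccl_id,
                                          library_id, ccl_id)]
  }
  stopifnot(is.logical(comparisons$identified), is.logical(comparisons$related))
  tp <- comparisons[, sum(identified & related)]
  fp <- comparisons[, sum(identified & !related)]
  fn <- comparisons[, sum(!identified & related)]
  tn <- comparisons[, sum(!identified & !related)]
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(tp, tp + fn)
  spec <- rat(tn, tn + fp)
  ppv <- rat(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  list(counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
       metrics = c(sensitivity = sens, specificity = spec, ppv = ppv, f1 = f1),
       possible_tp = tp + fn)
}

#' All-vs-all cross-validation of the identification method
#'
#' Every query profile is identified within every reference library and
#' each query/reference comparison is scored once; by default the reference
#' profiles themselves serve as queries (each query then meets its own
#' library entry, which counts as a gold-related pair). Metrics are
#' computed for each inclusion weight threshold, yielding one metric column
#' per threshold.
#'
#' @param libraries list of `ccl_library` objects.
#' @param gold a `ccl_gold`; defaults to normalized-name identity over the
#'   library members (no curation).
#' @param queries optional list of [ccl_profile()] queries; defaults to all
#'   library profiles.
#' @param params a [scoring_params()]; its `weight_threshold` is ignored in
#'   favour of `thresholds`.
#' @param thresholds numeric vector of weight thresholds to sweep.
#' @param keep_calls if `TRUE`, attach the full per-comparison call table.
#' @return list of class `cclid_benchmark`: `metrics` (data.table, one row
#'   per threshold) and optionally `calls`.
#' @export
cross_validate <- function(libraries, gold = NULL, queries = NULL,
                           params = scoring_params(),
                           thresholds = c(1, 0.5, 0.25, 0),
                           keep_calls = FALSE) {
  if (inherits(libraries, "ccl_library")) libraries <- list(libraries)
  stopifnot(length(libraries) >= 1L,
            all(vapply(libraries, inherits, logical(1), "ccl_library")))
  all_profiles <- unlist(lapply(libraries, `[[`, "profiles"), recursive = FALSE)
  if (length(all_profiles) < 2L) stop_data("need at least two profiles overall")
  if (is.null(queries)) queries <- all_profiles
  if (inherits(queries, "ccl_profile")) queries <- list(queries)
  if (is.null(gold)) {
    memb <- rbindlist(lapply(all_profiles, function(p) {
      data.table(library_id = p$library_id, ccl_id = p$ccl_id)
    }))
    gold <- build_gold_standard(memb)
  }
  qmeta <- data.table(
    query_id = seq_along(queries),
    query_library_id = vapply(queries, `[[`, character(1), "library_id"),
    query_ccl_id = vapply(queries, `[[`, character(1), "ccl_id"))
  qgroup <- .gold_group(gold, qmeta$query_library_id, qmeta$query_ccl_id)
  all_calls <- vector("list", length(thresholds))
  metrics <- vector("list", length(thresholds))
  for (ti in seq_along(thresholds)) {
    thr <- thresholds[ti]
    idxs <- lapply(libraries, .char_index, weight_threshold = thr,
                   scheme = params$weight_scheme)
    per_q <- vector("list", length(queries))
    for (qi in seq_along(queries)) {
      res <- rbindlist(lapply(idxs, function(idx) {
        .identify_one(queries[[qi]]$variants, idx, params)
      }))
      res[, query_id := qi]
      per_q[[qi]] <- res[, .(query_id, library_id, ccl_id, m_l, cs, rank, identified)]
    }
    calls <- rbindlist(per_q)
    calls <- qmeta[calls, on = "query_id"]
    rgroup <- .gold_group(gold, calls$library_id, calls$ccl_id)
    calls[, related := qgroup[query_id] == rgroup]
    ev <- evaluate_calls(calls[, .(identified, related)])
    metrics[[ti]] <- data.table(
      threshold = thr, possible_tp = ev$possible_tp,
      tp = ev$counts[["tp"]], fp = ev$counts[["fp"]],
      fn = ev$counts[["fn"]], tn = ev$counts[["tn"]],
      sensitivity = ev$metrics[["sensitivity"]],
      specificity = ev$metrics[["specificity"]],
      ppv = ev$metrics[["ppv"]], f1 = ev$metrics[["f1"]])
    if (keep_calls) {
      calls[, threshold := thr]
      all_calls[[ti]] <- calls
    }
  }
  out <- list(metrics = rbindlist(metrics),
              calls = if (keep_calls) rbindlist(all_calls) else NULL)
  class(out) <- "cclid_benchmark"
  out
}

#' @export
print.cclid_benchmark <- function(x, ...) {
  cat("<cclid_benchmark>\n")
  print(x$metrics)
  invisible(x)
}
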