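#' Scoring parameters
#'
#' Defaults follow the method's published settings: confidence threshold
#' `t = 3` (condition A), rank cutoff `k = 2` (condition B), inclusion
#' weight threshold 0.5.
#'
#' @param confidence_t minimum confidence score `cs = -ln(P)` for an
#'   identification (condition A); `cs >= t` is equivalent to
#'   `P <= exp(-t)`.
#' @param top_k a profile must rank among the top `k` confidence scores of
#'   its library (condition B).
#' @param weight_threshold inclusion weight threshold selecting
#'   characteristic variants, see [variant_weight()].
#' @param weight_scheme weight scheme, see [variant_weight()].
#' @param include_zero_overlap if `TRUE` (default) the library-average
#'   overlap `m_avg` used by the spuriousness filter averages over *all*
#'   profiles, including those sharing nothing with the query.
#' @param p_floor lower clamp for the binomial tail probability so the
#'   confidence score of near-certain self-matches stays finite.
#' @return a list of class `cclid_params`.
#' @export
scoring_params <- function(confidence_t = 3, top_k = 2, weight_threshold = 0.5,
                           weight_scheme = c("halving", "reciprocal"),
                           include_zero_overlap = TRUE, p_floor = 1e-300) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(is.numeric(confidence_t), confidence_t >= 0,
            is.numeric(top_k), top_k >= 1,
            is.numeric(weight_threshold),
            weight_threshold >= 0, weight_threshold <= 1,
            is.numeric(p_floor), p_floor > 0)
  structure(list(confidence_t = confidence_t, top_k = as.integer(top_k),
                 weight_threshold = weight_threshold,
                 weight_scheme = weight_scheme,
                 include_zero_overlap = isTRUE(include_zero_overlap),
                 p_floor = p_floor),
            class = "cclid_params")
}

#' Single-match probability
#'
#' The probability that one query variant matching the library's
#' characteristic pool falls into reference profile `l`, estimated as the
#' relative characteristic size of `l`: `p_l = |l| / |L|`, with `|l|` the
#' number of characteristic variants of profile `l` and `|L|` the number of
#' distinct characteristic variants in the library. This compensates for
#' large profiles being matched by chance more often.
#'
#' @param l_size characteristic variant count of the profile (`>= 1`).
#' @param L_size distinct characteristic variant count of the library.
#' @return numeric in `(0, 1]`.
#' @export
single_match_probability <- function(l_size, L_size) {
  if (any(L_size == 0)) stop_data("library characteristic pool is empty")
  if (any(l_size < 1) || any(l_size > L_size)) {
    stop_data("profile size must satisfy 1 <= |l| <= |L|")
  }
  l_size / L_size
}

#' Binomial tail probability of an observed overlap
#'
#' Probability of observing at least `m_l` matches to one profile among the
#' query's `m_L` library-wide matches under the null hypothesis that each
#' match independently falls into the profile with probability `p_l`:
#' `P = P(X >= m_l)`, `X ~ Binomial(m_L, p_l)`. `m_l = 0` gives `P = 1`.
#' The value is clamped below at `p_floor` so confidence scores stay finite.
#'
#' @param m_l observed overlap with the profile (`0 <= m_l <= m_L`).
#' @param m_L query variants matching any characteristic variant of the
#'   library.
#' @param p_l single-match probability in `(0, 1]`.
#' @param p_floor lower clamp, default `1e-300`.
#' @return tail probability in `[p_floor, 1]`.
#' @examples
#' binomial_tail(10, 10, 0.5)   # 2^-10
#' @export
binomial_tail <- function(m_l, m_L, p_l, p_floor = 1e-300) {
  n <- max(length(m_l), length(m_L), length(p_l))
  m_l <- rep_len(m_l, n); m_L <- rep_len(m_L, n); p_l <- rep_len(p_l, n)
  if (any(p_l <= 0) || any(p_l > 1)) stop_data("p_l must lie in (0, 1]")
  if (any(m_l < 0) || any(m_l > m_L)) stop_data("need 0 <= m_l <= m_L")
  out <- ifelse(m_l == 0, 1,
                stats::pbinom(m_l - 1, m_L, p_l, lower.tail = FALSE))
  pmax(out, p_floor)
}

#' Confidence score
#'
#' `cs = -ln(P)`; the default decision boundary `cs >= 3` corresponds to a
#' tail probability of at most `exp(-3)` (about 0.0498).
#'
#' @param P_L binomial tail probability in `(0, 1]` (pre-clamped).
#' @return non-negative confidence score.
#' @export
confidence_score <- function(P_L) {
  if (any(P_L <= 0) || any(P_L > 1)) stop_data("P must lie in (0, 1]")
  -log(P_L)
}

#' Size-induced spuriousness of a query/library comparison
#'
#' The beta function of the maximum and average per-profile overlap,
#' `SP = B(m_max, m_avg) = Gamma(m_max) Gamma(m_avg) / Gamma(m_max + m_avg)`,
#' evaluated in log space. When the best overlap towers over the average,
#' `SP` is tiny and matching is considered informative; when the best
#' overlap is close to what every profile achieves, `SP` approaches (or
#' exceeds) 1 and identification is blocked via [overlap_threshold()].
#'
#' @param m_avg mean overlap over all profiles of the library (`> 0`).
#' @param m_max maximum overlap (`>= 1`).
#' @return spuriousness value (symmetric in its arguments).
#' @examples
#' spuriousness(1, 1)    # B(1,1) = 1
#' spuriousness(1, 2)    # B(2,1) = 1/2
#' @export
spuriousness <- function(m_avg, m_max) {
  if (any(m_avg <= 0) || any(m_max <= 0)) {
    stop_data("spuriousness requires positive overlap statistics")
  }
  exp(lbeta(m_max, m_avg))
}

#' Absolute-overlap threshold for condition C
#'
#' `T = (m_avg + m_max * SP) / (1 - SP)`. As `SP -> 0` the threshold tends
#' to the average overlap; for degenerate spuriousness (`SP >= 1 - 1e-12`,
#' e.g. when the best overlap is a single variant) the threshold is
#' infinite and no profile can be identified -- such a library simply does
#' not support identification of this query.
#'
#' @param m_avg,m_max overlap statistics as in [spuriousness()].
#' @param sp spuriousness value (`> 0`).
#' @return threshold (possibly `Inf`); condition C requires `m_l > T`.
#' @export
overlap_threshold <- function(m_avg, m_max, sp) {
  if (any(sp <= 0)) stop_data("spuriousness must be positive")
  ifelse(sp >= 1 - 1e-12, Inf, (m_avg + m_max * sp) / (1 - sp))
}

#' Overlap counts between a query and every profile of a library
#'
#' Matching is restricted to characteristic variants: `m_l` is the number
#' of characteristic variants of profile `l` also present in the query, and
#' `m_L` the number of query variants matching any characteristic variant
#' of the library. Every profile appears in the result, including those
#' with `m_l = 0`.
#'
#' @param query a [ccl_profile()].
#' @param lib a `ccl_library`.
#' @param weight_threshold,scheme characteristic-variant selection, see
#'   [variant_weight()].
#' @return list with `counts` (data.table `ccl_id`, `m_l`, `l_char_size`),
#'   `m_L` and `pool_size`.
#' @export
match_counts <- function(query, lib, weight_threshold = 0.5,
                         scheme = c("halving", "reciprocal")) {
  stopifnot(inherits(query, "ccl_profile"))
  idx <- .char_index(lib, weight_threshold, scheme)
  if (idx$pool_size == 0L) {
    warning(sprintf("library '%s' has no characteristic variants at threshold %g",
                    lib$library_id, weight_threshold), call. = FALSE)
  }
  mc <- .match_counts_idx(query$variants, idx)
  list(counts = mc$counts, m_L = mc$m_L, pool_size = idx$pool_size)
}

.match_counts_idx <- function(qkeys, idx) {
  counts <- data.table(ccl_id = names(idx$sizes),
                       m_l = 0L, l_char_size = as.integer(idx$sizes))
  m_L <- 0L
  if (length(qkeys) && nrow(idx$long)) {
    hits <- idx$long[J(unique(qkeys)), nomatch = 0L]
    m_L <- length(unique(hits$key))
    if (nrow(hits)) {
      tab <- hits[, .N, by = ccl_id]
      counts[tab, m_l := i.N, on = "ccl_id"]
    }
  }
  list(counts = counts, m_L = m_L)
}

## score one query against one characteristic index; returns the per-profile
## call table (unsorted input order -> sorted by rank)
.identify_one <- function(qkeys, idx, params) {
  mc <- .match_counts_idx(qkeys, idx)
  dt <- mc$counts
  m_L <- mc$m_L
  pool <- idx$pool_size
  p_l <- ifelse(dt$l_char_size > 0 & pool > 0, dt$l_char_size / pool, 0)
  # profiles with an empty characteristic set can only have m_l = 0
  P <- rep(1, nrow(dt))
  nz <- which(dt$m_l > 0L)
  if (length(nz)) P[nz] <- binomial_tail(dt$m_l[nz], m_L, p_l[nz], params$p_floor)
  cs <- -log(P)
  m_avg <- if (params$include_zero_overlap) mean(dt$m_l)
           else if (any(dt$m_l > 0L)) mean(dt$m_l[dt$m_l > 0L]) else 0
  m_max <- if (nrow(dt)) max(dt$m_l) else 0L
  if (m_max >= 1L && m_avg > 0) {
    sp <- spuriousness(m_avg, m_max)
    # B(m_max, m_avg) underflows to 0 for large overlaps; T -> m_avg in the
    # sp -> 0 limit
    t_thr <- if (sp == 0) m_avg else overlap_threshold(m_avg, m_max, sp)
  } else {
    sp <- NA_real_
    t_thr <- Inf
  }
  ord <- order(-cs, -dt$m_l, dt$ccl_id, method = "radix")
  rank_ <- integer(nrow(dt)); rank_[ord] <- seq_len(nrow(dt))
  out <- data.table(
    library_id = idx$library_id, ccl_id = dt$ccl_id,
    m_l = dt$m_l, m_L = m_L, p_l = p_l, p_value = P, cs = cs,
    rank = rank_, m_avg = m_avg, m_max = as.integer(m_max), sp = sp,
    t_threshold = t_thr,
    cond_a = cs >= params$confidence_t,
    cond_b = rank_ <= params$top_k,
    cond_c = dt$m_l > t_thr
  )
  out[, identified := cond_a & cond_b & cond_c]
  setorder(out, rank)
  out[]
}

#' Identify a query cell line within reference libraries
#'
#' For each library independently: compute the characteristic-variant
#' overlap of the query with every reference profile, the binomial-tail
#' confidence score, the spuriousness statistic and the absolute-overlap
#' threshold, then call a profile identified when all three conditions
#' hold: (A) `cs >= t`, (B) the score ranks among the library's top `k`,
#' and (C) the overlap `m_l` exceeds the library threshold `T`. Rank ties
#' are resolved deterministically by larger overlap, then cell line name.
#'
#' @param query a [ccl_profile()].
#' @param libraries a `ccl_library` or list of them.
#' @param params a [scoring_params()] object.
#' @return data.table with one row per (library, reference profile), sorted
#'   by confidence within each library: columns `library_id`, `ccl_id`,
#'   `m_l`, `m_L`, `p_l`, `p_value`, `cs`, `rank`, `m_avg`, `m_max`, `sp`,
#'   `t_threshold`, `cond_a`, `cond_b`, `cond_c`, `identified`.
#' @export
identify_ccl <- function(query, libraries, params = scoring_params()) {
  stopifnot(inherits(query, "ccl_profile"), inherits(params, "cclid_params"))
  if (inherits(libraries, "ccl_library")) libraries <- list(libraries)
  stopifnot(length(libraries) >= 1L,
            all(vapply(libraries, inherits, logical(1), "ccl_library")))
  if (length(query$variants) == 0L) {
    warning("query profile is empty; all calls will be negative", call. = FALSE)
  }
  res <- lapply(libraries, function(lib) {
    idx <- .char_index(lib, params$weight_threshold, params$weight_scheme)
    if (idx$pool_size == 0L) {
      warning(sprintf("library '%s' has no characteristic variants at threshold %g",
                      lib$library_id, params$weight_threshold), call. = FALSE)
    }
    .identify_one(query$variants, idx, params)
  })
  rbindlist(res)
}
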