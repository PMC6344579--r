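# Independent oracles and fixture builders shared across the suite.
# The oracles are deliberate straight-line reimplementations from the
# definitions (explicit pmf summation, counting on raw sets, all-pairs
# interval scans); they share no code path with the package internals.

# P(X >= m_l), X ~ Binomial(m_L, p), by explicit pmf summation
oracle_binom_tail <- function(m_l, m_L, p) {
  if (m_l == 0) return(1)
  sum(dbinom(m_l:m_L, m_L, p))
}

# B(m, n) for positive integers via factorial ratio: B(m, n) = 1/(m * C(m+n-1, m))
oracle_beta_int <- function(m, n) {
  1 / (m * choose(m + n - 1, m))
}

# straight-line reimplementation of the whole decision rule from raw
# variant sets (named list of character vectors, set semantics)
oracle_identify <- function(query_vars, ref_sets, t = 3, k = 2, thr = 0.5) {
  f <- table(unlist(ref_sets, use.names = FALSE))
  w <- 2^(1 - as.numeric(f))
  char_pool <- names(f)[w >= thr]
  char_sets <- lapply(ref_sets, function(s) intersect(s, char_pool))
  m_l <- vapply(char_sets, function(s) length(intersect(s, query_vars)), integer(1))
  m_L <- length(intersect(unique(query_vars), char_pool))
  pool_n <- length(char_pool)
  p_l <- vapply(char_sets, length, integer(1)) / max(pool_n, 1)
  P <- mapply(function(m, p) if (m == 0) 1 else sum(dbinom(m:m_L, m_L, p)),
              m_l, p_l)
  P <- pmax(P, 1e-300)
  cs <- -log(P)
  m_avg <- mean(m_l); m_max <- max(m_l)
  t_thr <- Inf
  if (m_max >= 1 && m_avg > 0) {
    sp <- beta(m_max, m_avg)
    t_thr <- if (sp >= 1 - 1e-12) Inf
             else if (sp == 0) m_avg
             else (m_avg + m_max * sp) / (1 - sp)
  }
  ord <- order(-cs, -m_l, names(ref_sets), method = "radix")
  rk <- integer(length(ord)); rk[ord] <- seq_along(ord)
  data.frame(ccl_id = names(ref_sets), m_l = unname(m_l), cs = unname(cs),
             rank = rk,
             identified = unname((cs >= t) & (rk <= k) & (m_l > t_thr)),
             stringsAsFactors = FALSE)
}

# random variant keys on a compact single-chromosome space
rand_keys <- function(n, space = 5000, chrom = "1") {
  pos <- sample.int(space, n)
  sprintf("%s:%d:%d", chrom, pos, pos)
}

# random small library of profiles over a shared variant space
rand_library <- function(n_profiles, max_vars = 200, space = 5000,
                         library_id = "rnd") {
  profs <- lapply(seq_len(n_profiles), function(i) {
    ccl_profile(sprintf("P%03d", i), library_id,
                rand_keys(sample(5:max_vars, 1), space))
  })
  build_library(profs, library_id = library_id)
}

# brute-force O(n * m) any-base interval overlap scan
oracle_restrict <- function(keys, regions) {
  vt <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  kc <- vt[, 1]; ks <- as.integer(vt[, 2]); ke <- as.integer(vt[, 3])
  keep <- logical(length(keys))
  for (i in seq_along(keys)) {
    for (j in seq_len(nrow(regions))) {
      if (kc[i] == regions$chrom[j] &&
          ks[i] <= regions$end[j] && ke[i] >= regions$start[j]) {
        keep[i] <- TRUE
        break
      }
    }
  }
  sort(keys[keep], method = "radix")
}
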