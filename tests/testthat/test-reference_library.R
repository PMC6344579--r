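test_that("frequency index counts carrying profiles per library", {
  v_shared <- genomic_variant("1", 100)
  p1 <- ccl_profile("A", "L", c(v_shared, genomic_variant("1", 200)))
  p2 <- ccl_profile("B", "L", c(v_shared, genomic_variant("2", 300)))
  lib <- build_library(list(p1, p2))
  fr <- freq_index(lib)
  expect_identical(fr[key == v_shared, f], 2L)
  expect_identical(fr[key != v_shared, sort(f)], c(1L, 1L))
  # single profile: every f = 1
  solo <- build_library(list(ccl_profile("S", "L2", rand_keys(20))))
  expect_true(all(freq_index(solo)$f == 1L))
})

test_that("frequency index matches a brute-force recount on random libraries", {
  set.seed(42)
  lib <- rand_library(50, max_vars = 150, space = 3000)
  fr <- freq_index(lib)
  sizes <- vapply(lib$profiles, function(p) length(p$variants), integer(1))
  expect_identical(sum(fr$f), sum(sizes))
  tab <- table(unlist(lapply(lib$profiles, `[[`, "variants")))
  expect_identical(sort(names(tab)), sort(fr$key))
  expect_identical(as.integer(tab[fr$key]), fr$f)
  # every variant of every profile is indexed
  expect_true(all(unlist(lapply(lib$profiles, `[[`, "variants")) %in% fr$key))
})

test_that("library construction rejects ambiguous identities", {
  p <- ccl_profile("A", "L", rand_keys(5))
  expect_error(build_library(list(p, p)), class = "cclid_data_error")
  q <- ccl_profile("B", "Lother", rand_keys(5))
  expect_error(build_library(list(p, q), library_id = "L"),
               class = "cclid_data_error")
  expect_error(build_library(list()), class = "cclid_data_error")
})

test_that("inclusion weight halves per extra carrier and starts at 1", {
  expect_identical(variant_weight(1:3), c(1, 0.5, 0.25))
  w <- variant_weight(1:20)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_error(variant_weight(0), class = "cclid_data_error")
  # legacy reciprocal scheme differs from f = 3 on
  expect_identical(variant_weight(1:3, scheme = "reciprocal"), c(1, 0.5, 1/3))
})

test_that("characteristic sets follow the weight threshold semantics", {
  set.seed(7)
  lib <- rand_library(12, max_vars = 120, space = 400)  # dense -> high f values
  fr <- freq_index(lib)
  f_of <- structure(fr$f, names = fr$key)
  ch1 <- characteristic_variants(lib, 1.0)
  ch05 <- characteristic_variants(lib, 0.5)
  ch0 <- characteristic_variants(lib, 0.0)
  for (id in names(lib$profiles)) {
    vars <- lib$profiles[[id]]$variants
    expect_identical(ch1[[id]], sort(vars[f_of[vars] == 1L], method = "radix"))
    expect_identical(ch05[[id]], sort(vars[f_of[vars] <= 2L], method = "radix"))
    expect_identical(ch0[[id]], vars)  # threshold 0 retains everything
  }
})

test_that("characteristic sets nest monotonically across thresholds", {
  set.seed(8)
  for (rep in 1:3) {
    lib <- rand_library(10, max_vars = 100, space = 500)
    chs <- lapply(c(1.0, 0.5, 0.25, 0.0), characteristic_variants, lib = lib)
    for (id in names(lib$profiles)) {
      for (i in 1:3) {
        expect_true(all(chs[[i]][[id]] %in% chs[[i + 1L]][[id]]))
      }
    }
  }
})

test_that("library store round-trips losslessly and rejects corruption", {
  set.seed(9)
  profs <- c(lapply(1:5, function(i) ccl_profile(sprintf("C%d", i), "LS",
                                                 rand_keys(sample(10:50, 1)))),
             list(ccl_profile("EMPTY", "LS", character(0))))
  lib <- build_library(profs)
  prefix <- file.path(tempdir(), "store_test")
  save_library(lib, prefix)
  lib2 <- load_library(prefix)
  expect_identical(lib2$library_id, lib$library_id)
  expect_setequal(names(lib2$profiles), names(lib$profiles))
  for (id in names(lib$profiles)) {
    expect_identical(lib2$profiles[[id]]$variants, lib$profiles[[id]]$variants)
  }
  expect_identical(freq_index(lib)[order(key)], freq_index(lib2)[order(key)])
  expect_length(lib2$profiles[["EMPTY"]]$variants, 0L)

  # truncated index -> load error, not a silent partial library
  vfile <- paste0(prefix, ".variants.tsv")
  lines <- readLines(vfile)
  writeLines(head(lines, max(2L, length(lines) - 5L)), vfile)
  expect_error(load_library(prefix), class = "cclid_format_error")
  expect_error(load_library(file.path(tempdir(), "nonexistent_prefix")),
               class = "cclid_format_error")
})

test_that("incremental index maintenance equals a full rebuild", {
  set.seed(10)
  for (rep in 1:5) {
    lib <- rand_library(sample(3:10, 1), max_vars = 60, space = 800)
    extra <- ccl_profile("EXTRA", "rnd", rand_keys(40, space = 800))
    inc <- add_profile(lib, extra)
    full <- build_library(c(lib$profiles, list(extra)), library_id = "rnd")
    expect_identical(freq_index(inc)[order(key)], freq_index(full)[order(key)])
    # add then remove is the identity
    back <- remove_profile(inc, "EXTRA")
    expect_identical(freq_index(back)[order(key)], freq_index(lib)[order(key)])
    expect_setequal(names(back$profiles), names(lib$profiles))
  }
})

test_that("removing a profile decrements exactly its variants", {
  lib <- rand_library(6, max_vars = 50, space = 300)
  victim <- lib$profiles[[3]]
  fr_before <- freq_index(lib)
  fr_after <- freq_index(remove_profile(lib, victim$ccl_id))
  merged <- merge(fr_before, fr_after, by = "key", all.x = TRUE, suffixes = c("", "_after"))
  merged[is.na(f_after), f_after := 0L]
  dec <- merged[f != f_after]
  expect_setequal(dec$key, victim$variants)
  expect_true(all(dec$f - dec$f_after == 1L))
  expect_error(remove_profile(lib, "NOSUCH"), class = "cclid_data_error")
  expect_error(add_profile(lib, victim), class = "cclid_data_error")
})
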