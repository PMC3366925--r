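test_that("canonical tokens parse to the documented structures", {
  v <- parse_variants(c("16360", "106-111d", "309.1C", "64@", "16182C",
                        "152Y", "522-523d", "247d"))
  expect_equal(v$kind, c("transition", "deletion", "insertion", "transition",
                         "transversion", "heteroplasmy", "deletion", "deletion"))
  expect_equal(v$position, c(16360L, 106L, 309L, 64L, 16182L, 152L, 522L, 247L))
  expect_equal(v$span_end[2], 111L)   # 6-bp deletion spans 106..111
  expect_equal(v$span_end[2] - v$position[2] + 1L, 6L)
  expect_equal(v$insert_index[3], 1L)
  expect_equal(v$derived_base[3], "C")
  expect_true(v$reversion[4])
  expect_equal(v$derived_base[5], "C")
})

test_that("en-dash spans are accepted and normalised to hyphen", {
  v <- parse_variants("106–111d")
  expect_equal(v$token, "106-111d")
  expect_equal(v$span_end, 111L)
})

test_that("malformed and out-of-range tokens are rejected by name", {
  expect_error(parse_variants("abc"), "abc")
  expect_error(parse_variants("16570"), "16570")
  expect_error(parse_variants("0"), "position")
  expect_error(parse_variants("309.0C"), "309.0C")
  expect_error(parse_variants("100-90d"), "100-90d")
  expect_error(parse_variants("123Z"), "123Z")
})

test_that("parse/serialize round-trips over generated token space", {
  set.seed(11)
  for (rep in 1:20) {
    toks <- unique(random_tokens(40))
    v <- parse_variants(toks)
    out <- serialize_variants(v)
    v2 <- parse_variants(out)
    expect_identical(v, v2)
    # canonical form is a fixpoint
    expect_identical(serialize_variants(v2), out)
  }
})

test_that("circular covered-range membership wraps the origin", {
  rng <- c(16000L, 580L)
  expect_true(all(in_circular_range(c(16000L, 16569L, 1L, 580L, 73L), rng)))
  expect_false(any(in_circular_range(c(581L, 15999L, 8000L), rng)))
  # non-wrapping interval
  expect_true(in_circular_range(100L, c(50L, 200L)))
  expect_false(in_circular_range(300L, c(50L, 200L)))
})

test_that("haplotype constructor enforces range and duplicate invariants", {
  expect_error(haplotype("x", "8000"), "covered_range")
  expect_error(haplotype("x", c("73", "73")), "duplicate")
  h <- haplotype("x", c("73", "16360"))
  expect_s3_class(h, "mt_haplotype")
})

test_that("network filter keeps the 6-bp deletion but drops other indels", {
  v <- parse_variants(c("106-111d", "522-523d", "309.1C", "315.1C", "152Y",
                        "16519", "16182C", "73", "16189"))
  f <- filter_variants(v, site_filter("network"))
  expect_setequal(f$token, c("106-111d", "73", "16189"))
})

test_that("haplotype distances follow the network filtering conventions", {
  # identity
  a <- mk_hap("a", c("16360", "89"))
  expect_equal(haplotype_distance(a, a), 0)
  # one-step difference
  b <- mk_hap("b", "16360")
  expect_equal(haplotype_distance(a, b), 1)
  # 16519 excluded, 6-bp deletion kept as a single character
  c1 <- mk_hap("c1", c("106-111d", "16519"))
  c2 <- mk_hap("c2", character())
  expect_equal(haplotype_distance(c1, c2), 1)
  # heteroplasmies and insertions never count under the network profile
  d1 <- mk_hap("d1", c("152Y", "309.1C", "16360"))
  d2 <- mk_hap("d2", "16360")
  expect_equal(haplotype_distance(d1, d2), 0)
})

test_that("haplotype distance is a metric on filtered variant sets", {
  set.seed(21)
  pool <- c("16093", "16189", "16217", "16290", "16360", "73", "146", "263",
            "106-111d", "16311")
  haps <- lapply(1:8, function(i) {
    mk_hap(paste0("h", i), sample(pool, sample(0:6, 1)))
  })
  for (i in 1:8) {
    expect_equal(haplotype_distance(haps[[i]], haps[[i]]), 0)
    for (j in seq_len(8)) {
      dij <- haplotype_distance(haps[[i]], haps[[j]])
      expect_equal(dij, haplotype_distance(haps[[j]], haps[[i]]))
      for (k in seq_len(8)) {
        expect_lte(dij, haplotype_distance(haps[[i]], haps[[k]]) +
                        haplotype_distance(haps[[k]], haps[[j]]))
      }
    }
  }
})

test_that("disjoint covered ranges are an error", {
  a <- haplotype("a", "100", covered_range = c(50L, 200L))
  b <- haplotype("b", "5000", covered_range = c(4000L, 6000L))
  expect_error(haplotype_distance(a, b), "disjoint")
})
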