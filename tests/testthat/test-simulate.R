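small_counts <- function() {
  data.frame(
    region = rep(c("R1", "R2", "C1x"), times = c(3, 2, 2)),
    type = rep(c("province", "province", "comarca"), times = c(3, 2, 2)),
    haplogroup = c("A2", "B2", "L2", "A2", "HV", "A2", "C1"),
    count = c(10L, 5L, 3L, 8L, 2L, 6L, 4L),
    stringsAsFactors = FALSE
  )
}

test_that("age zero reproduces founding motifs exactly", {
  cfg <- sim_config(seed = 2, region_counts = small_counts(),
                    clade_ages = c(A2 = 1e-9, B2 = 1e-9, L2 = 1e-9,
                                   HV = 1e-9, C1 = 1e-9),
                    n_foreign = 0L, n_pairs = 0L, n_triplets = 0L)
  sim <- simulate_cohort(cfg)
  for (h in sim$cohort) {
    motif <- panmito:::founding_motif(cfg$tree, h$haplogroup)
    expect_setequal(h$variants$token, motif)
  }
  expect_equal(sum(sim$truth$n_private), 0L)
})

test_that("identical seeds give bit-identical cohorts; seeds matter", {
  cfg <- function(s) sim_config(seed = s, region_counts = small_counts(),
                                n_foreign = 3L, n_pairs = 2L, n_triplets = 1L)
  s1 <- simulate_cohort(cfg(5))
  s2 <- simulate_cohort(cfg(5))
  expect_identical(s1$truth, s2$truth)
  expect_identical(
    lapply(s1$cohort, function(h) h$variants$token),
    lapply(s2$cohort, function(h) h$variants$token)
  )
  s3 <- simulate_cohort(cfg(6))
  expect_false(identical(s1$truth$n_private, s3$truth$n_private))
})

test_that("exact mode hits the configured composition; truth scores it", {
  cfg <- sim_config(seed = 3, region_counts = small_counts(),
                    n_foreign = 4L, n_pairs = 2L, n_triplets = 1L)
  sim <- simulate_cohort(cfg)
  core <- sim$truth[sim$truth$tma_origin == "Panama" &
                      !grepl("r[0-9]+$", sim$truth$sample_id), ]
  got <- table(core$region, core$haplogroup)
  for (i in seq_len(nrow(small_counts()))) {
    rc <- small_counts()[i, ]
    expect_equal(unname(got[rc$region, rc$haplogroup]), rc$count)
  }
  # classification recovers every true haplogroup (motifs are disjoint
  # from the private-site pool)
  calls <- classify_cohort(sim$cohort, cfg$tree)
  expect_identical(calls$haplogroup, sim$truth$haplogroup)
  # cluster members share their seed's haplotype
  for (cl in unique(stats::na.omit(sim$truth$cluster_id))) {
    mem <- sim$truth$sample_id[!is.na(sim$truth$cluster_id) &
                                 sim$truth$cluster_id == cl]
    toks <- lapply(sim$cohort[mem], function(h) sort(h$variants$token))
    expect_length(unique(toks), 1L)
  }
})

test_that("private mutation counts are Poisson at the configured rate", {
  cfg <- sim_config(seed = 4,
                    region_counts = data.frame(region = "R1",
                                               type = "province",
                                               haplogroup = "A2",
                                               count = 2000L),
                    clade_ages = c(A2 = 18116),  # lambda = 2 at 9058 yr/mut
                    n_foreign = 0L, n_pairs = 0L, n_triplets = 0L)
  sim <- simulate_cohort(cfg)
  m <- sim$truth$n_private
  expect_equal(mean(m), 2, tolerance = 0.1)
  expect_equal(stats::var(m), 2, tolerance = 0.25)
})

test_that("star-clade simulation feeds the rho estimator unbiasedly", {
  set.seed(91)
  ages <- replicate(60, {
    sc <- simulate_star_clade(100, 23240, 3624)
    to_years(rho_sigma(sc$tree), clock_config(), "whole_molecule")$age_years
  })
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - 23240), 3 * se + 1e-9)
})

test_that("cohort and metadata TSVs round-trip", {
  cfg <- sim_config(seed = 8, region_counts = small_counts(),
                    n_foreign = 2L, n_pairs = 1L, n_triplets = 1L)
  sim <- simulate_cohort(cfg)
  hp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_haplotypes(sim$cohort, hp)
  write_metadata(sim$metadata, mp)
  back <- read_haplotypes(hp)
  expect_equal(length(back), length(sim$cohort))
  expect_identical(
    lapply(back, function(h) h$variants$token),
    lapply(sim$cohort, function(h) h$variants$token)
  )
  meta <- read_metadata(mp)
  expect_identical(meta$cluster_id, sim$metadata$cluster_id)
  expect_identical(meta$tma_origin, sim$metadata$tma_origin)
  tp <- withr::local_tempfile(fileext = ".json")
  write_truth(sim, tp)
  truth <- jsonlite::read_json(tp)
  expect_equal(length(truth$samples), nrow(sim$truth))
  expect_equal(truth$config$seed, 8L)
})
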