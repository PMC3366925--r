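no_gamma_cfg <- function(...) {
  ml_model_config(estimate_kappa = FALSE, gamma_shape = NA,
                  estimate_gamma = FALSE, n_rate_categories = 1L,
                  partitions = NULL, excluded_positions = integer(), ...)
}

test_that("discrete gamma categories have mean one and mean-per-bin rates", {
  for (alpha in c(0.1, 0.5, 2, 10)) {
    for (K in c(4L, 8L, 32L)) {
      r <- panmito:::discrete_gamma_rates(alpha, K)
      expect_length(r, K)
      expect_equal(mean(r), 1, tolerance = 1e-10)
      expect_true(all(diff(r) > 0))
    }
  }
})

test_that("HKY transition probabilities are proper and reversible", {
  pi <- c(0.31, 0.31, 0.13, 0.25)
  eig <- panmito:::hky_eigen(8, pi)
  for (t in c(0, 0.01, 0.3, 5)) {
    P <- panmito:::hky_P(eig, t)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
    # detailed balance: pi_i P_ij = pi_j P_ji
    for (i in 1:4) for (j in 1:4) {
      expect_equal(pi[i] * P[i, j], pi[j] * P[j, i], tolerance = 1e-12)
    }
  }
  expect_equal(panmito:::hky_P(eig, 0), diag(4), tolerance = 1e-12)
})

test_that("pruning likelihood equals exhaustive state summation", {
  set.seed(71)
  pi <- c(0.3, 0.2, 0.2, 0.3)
  for (i in 1:6) {
    ntip <- sample(3:5, 1)
    tree <- ape::rtree(ntip)
    tree$edge.length <- runif(nrow(tree$edge), 0.01, 0.5)
    nsites <- sample(10:50, 1)
    aln <- simulate_alignment(tree, nsites, kappa = 6, base_freq = pi)
    cfg <- no_gamma_cfg(base_freq = pi)
    ll <- hky_loglik(aln, tree, cfg, kappa = 6)
    ll_ex <- exhaustive_loglik(tree, aln, kappa = 6, pi = pi)
    expect_equal(ll, ll_ex, tolerance = 1e-10)
  }
})

test_that("pruning likelihood with discrete gamma matches rate-averaged oracle", {
  set.seed(72)
  pi <- rep(0.25, 4)
  tree <- ape::rtree(4)
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.4)
  aln <- simulate_alignment(tree, 30, kappa = 4, base_freq = pi)
  cfg <- ml_model_config(estimate_kappa = FALSE, gamma_shape = 0.5,
                         estimate_gamma = FALSE, n_rate_categories = 4L,
                         partitions = NULL, excluded_positions = integer(),
                         base_freq = pi)
  ll <- hky_loglik(aln, tree, cfg, kappa = 4, alpha = 0.5)
  rates <- panmito:::discrete_gamma_rates(0.5, 4L)
  ll_ex <- exhaustive_loglik(tree, aln, kappa = 4, pi = pi, rates = rates)
  expect_equal(ll, ll_ex, tolerance = 1e-8)
})

test_that("two-sequence fit reproduces the Jukes-Cantor closed form", {
  # kappa = 1 and equal frequencies reduce HKY to JC; the ML total path
  # length between two sequences with difference fraction p must equal
  # -(3/4) log(1 - 4p/3)
  n <- 1000L
  p <- 0.1
  a <- rep(c("A", "C", "G", "T"), length.out = n)
  b <- a
  flip <- seq_len(n * p)
  b[flip] <- c(A = "C", C = "G", G = "T", T = "A")[a[flip]]
  aln <- rbind(a = a, b = b)
  tree <- ape::read.tree(text = "(a:0.05,b:0.05);")
  cfg <- no_gamma_cfg(kappa = 1, base_freq = rep(0.25, 4))
  fit <- ml_branch_lengths(aln, tree, cfg)
  expect_true(fit$converged)
  jc <- -0.75 * log(1 - 4 * p / 3)
  expect_equal(sum(fit$tree$edge.length), jc, tolerance = 1e-6)
})

test_that("identical sequences give zero branch lengths", {
  a <- rep(c("A", "C", "G", "T"), 25)
  aln <- rbind(s1 = a, s2 = a)
  tree <- ape::read.tree(text = "(s1:0.01,s2:0.01);")
  fit <- ml_branch_lengths(aln, tree, no_gamma_cfg(kappa = 2,
                                                   base_freq = rep(0.25, 4)))
  expect_lt(sum(fit$tree$edge.length), 1e-6)
})

test_that("likelihood agrees with an independent phylogenetic implementation", {
  skip_if_not_installed("phangorn")
  set.seed(73)
  pi <- c(0.35, 0.25, 0.15, 0.25)
  tree <- ape::rtree(5)
  tree$edge.length <- runif(nrow(tree$edge), 0.02, 0.3)
  aln <- simulate_alignment(tree, 200, kappa = 7, base_freq = pi)
  ll <- hky_loglik(aln, tree, no_gamma_cfg(base_freq = pi), kappa = 7)
  dat <- phangorn::phyDat(aln, type = "DNA")
  # GTR rate order AC, AG, AT, CG, CT, GT; HKY sets the transitions to kappa
  fit <- phangorn::pml(tree, dat, bf = pi, Q = c(1, 7, 1, 1, 7, 1))
  expect_equal(ll, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})

test_that("simulated data recover the generating parameters", {
  set.seed(74)
  tree <- ape::rtree(6)
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.25)
  aln <- simulate_alignment(tree, 4000, kappa = 10, base_freq = rep(0.25, 4),
                            alpha = 0.5, n_rate_categories = 8L)
  cfg <- ml_model_config(kappa = 4, estimate_kappa = TRUE, gamma_shape = 1,
                         estimate_gamma = TRUE, n_rate_categories = 8L,
                         partitions = NULL, excluded_positions = integer(),
                         base_freq = rep(0.25, 4))
  fit <- ml_branch_lengths(aln, tree, cfg)
  expect_true(fit$converged)
  expect_gt(fit$kappa, 6); expect_lt(fit$kappa, 16)
  expect_gt(fit$alpha, 0.3); expect_lt(fit$alpha, 0.9)
  expect_equal(sum(fit$tree$edge.length), sum(tree$edge.length),
               tolerance = 0.15)
})

test_that("partition multipliers are recovered with site-weighted mean one", {
  set.seed(75)
  tree <- ape::rtree(5)
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.3)
  parts <- list(fast = 1:300)
  aln <- simulate_alignment(tree, 900, kappa = 5, base_freq = rep(0.25, 4),
                            partitions = parts,
                            multipliers = c(fast = 2, remainder = 0.5))
  cfg <- ml_model_config(kappa = 5, estimate_kappa = FALSE, gamma_shape = NA,
                         estimate_gamma = FALSE, n_rate_categories = 1L,
                         partitions = parts, excluded_positions = integer(),
                         base_freq = rep(0.25, 4))
  fit <- ml_branch_lengths(aln, tree, cfg)
  m <- fit$multipliers
  expect_equal(sum(m * c(300, 600)) / 900, 1, tolerance = 1e-8)
  expect_gt(m[["fast"]], m[["remainder"]])
  expect_equal(m[["fast"]] / m[["remainder"]], 4, tolerance = 0.5)
})

test_that("simulated alignments respect degenerate limits", {
  tree <- ape::read.tree(text = "(a:0,b:0);")
  aln <- simulate_alignment(tree, 100, kappa = 2, base_freq = rep(0.25, 4))
  expect_identical(aln["a", ], aln["b", ])
  # kappa >> 1: essentially only transitions on a long branch
  set.seed(76)
  tree2 <- ape::read.tree(text = "(a:0.5,b:0.5);")
  aln2 <- simulate_alignment(tree2, 2000, kappa = 5000,
                             base_freq = rep(0.25, 4))
  diff <- aln2["a", ] != aln2["b", ]
  is_ts <- (aln2["a", ] %in% c("A", "G") & aln2["b", ] %in% c("A", "G")) |
    (aln2["a", ] %in% c("C", "T") & aln2["b", ] %in% c("C", "T"))
  expect_gt(sum(diff), 0)
  expect_gte(mean(is_ts[diff]), 0.99)
})

test_that("zero empirical base frequency is a diagnostic error", {
  aln <- rbind(a = rep("A", 10), b = rep("C", 10))
  tree <- ape::read.tree(text = "(a:0.1,b:0.1);")
  cfg <- no_gamma_cfg()
  expect_error(hky_loglik(aln, tree, cfg, kappa = 2), "frequency")
})
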