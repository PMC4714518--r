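test_that("size factors reproduce hand-computed median-of-ratios values", {
  # identical columns
  m <- matrix(c(3L, 7L, 3L, 7L), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # column b = 2 x column a: geometric-mean-1 convention gives (1/sqrt2, sqrt2)
  m2 <- matrix(c(4L, 10L, 8L, 20L), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  s <- size_factors(m2)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(s["b"] / s["a"]), 2)
  # single gene (4, 9): geometric mean 6, ratios 2/3 and 3/2
  m3 <- matrix(c(4L, 9L), 1, 2, dimnames = list("g1", c("a", "b")))
  expect_equal(unname(size_factors(m3)), c(2 / 3, 3 / 2))
})

test_that("size factors are scale-equivariant under the fixed convention", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(rpois(40, 50) + 1L, 10, 4,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
    s0 <- size_factors(m)
    c_mult <- 3
    m2 <- m; m2[, 2] <- m2[, 2] * c_mult
    s1 <- size_factors(m2)
    # ratios to the common geometric-mean normalization are preserved
    expect_equal(unname(s1[2] / s1[1]), unname(c_mult * s0[2] / s0[1]),
                 tolerance = 1e-10)
  }
})

test_that("size factors demand a usable reference or the fallback flag", {
  m <- matrix(c(0L, 5L, 4L, 0L), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(size_factors(m), "pseudo_reference")
  expect_silent(s <- size_factors(m, pseudo_reference = TRUE))
  expect_true(all(s > 0))
})

test_that("dispersion estimation recovers the generative dispersion", {
  set.seed(11)
  n <- 2000; ns <- 5
  mu <- rlnorm(n, log(100), 0.5)
  pois <- matrix(rpois(n * 2 * ns, rep(mu, 2 * ns)), n, 2 * ns,
                 dimnames = list(paste0("g", 1:n), paste0("s", 1:(2 * ns))))
  sf <- rep(1, 2 * ns)
  groups <- list(1:ns, ns + 1:ns)
  a_pois <- estimate_dispersion(pois, sf, groups)$alpha
  expect_lte(median(a_pois), 0.01)
  nb <- matrix(rnbinom(n * 2 * ns, mu = rep(mu, 2 * ns), size = 1 / 0.2),
               n, 2 * ns, dimnames = dimnames(pois))
  a_nb <- estimate_dispersion(nb, sf, groups)$alpha
  expect_gte(median(a_nb), 0.1)
  expect_lte(median(a_nb), 0.4)
  # zero within-group variance floors the estimate
  const <- matrix(5L, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  a_const <- estimate_dispersion(const, rep(1, 4), list(1:2, 3:4))$alpha
  expect_true(all(a_const == 1e-8))
  expect_error(estimate_dispersion(const, rep(1, 4), list(1, 2:4)),
               ">= 2 samples")
})

test_that("NB exact test honours its boundary identities", {
  expect_equal(nb_exact_test(7, 7, 1, 1, 0.1), 1)
  expect_equal(nb_exact_test(0, 0, 1, 1, 0.1), 1)
  expect_equal(nb_exact_test(3, 3, c(1, 1), c(1, 1), 0), 1)
  # symmetry under group swap
  for (al in c(0, 0.05, 0.3)) {
    expect_equal(nb_exact_test(3, 17, 1.2, 0.9, al),
                 nb_exact_test(17, 3, 0.9, 1.2, al))
  }
  expect_error(nb_exact_test(1, 1, 1, 1, -0.1), "alpha")
})

test_that("NB exact test equals an independent enumeration oracle", {
  # plain-loop oracle, written against the definition only
  oracle <- function(k_a, k_b, sf_a, sf_b, alpha) {
    K <- k_a + k_b
    q <- K / (sum(sf_a) + sum(sf_b))
    pmf <- function(x, sf) {
      mu <- q * sum(sf)
      v <- sum(q * sf + alpha * q^2 * sf^2)
      if (v <= mu) dpois(x, mu) else dnbinom(x, mu = mu, size = mu^2 / (v - mu))
    }
    probs <- numeric(K + 1)
    for (a in 0:K) probs[a + 1] <- pmf(a, sf_a) * pmf(K - a, sf_b)
    obs <- probs[k_a + 1]
    sum(probs[probs <= obs * (1 + 1e-10)]) / sum(probs)
  }
  grid <- expand.grid(k_a = c(0, 1, 5, 12, 25), K = c(1, 10, 30, 50),
                      alpha = c(0, 0.01, 0.2, 1))
  for (i in seq_len(nrow(grid))) {
    k_a <- grid$k_a[i]; K <- grid$K[i]
    if (k_a > K) next
    sf_a <- c(1, 1.3, 0.8); sf_b <- c(0.9, 1.1)
    expect_equal(nb_exact_test(k_a, K - k_a, sf_a, sf_b, grid$alpha[i]),
                 oracle(k_a, K - k_a, sf_a, sf_b, grid$alpha[i]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 1.0)), c(0.04, 0.04, 0.04, 1.0))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.5, 0.001, 0.9)
  expect_true(all(bh_fdr(p) >= p))           # q >= p
  expect_equal(order(bh_fdr(p)), order(p))   # ranking-consistent
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH controls the false discovery fraction under the global null", {
  fracs <- vapply(1:100, function(s) {
    set.seed(s)
    mean(bh_fdr(runif(2000)) <= 0.1)
  }, 0)
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lte(mean(fracs), 0.1 + 3 * se)
})

test_that("Wilcoxon exact path enumerates the rank-assignment null", {
  expect_equal(wilcoxon_one_sided(c(1, 2), c(3, 4), "less"), 1 / 6)
  # same multiset: one-sided p >= 0.5 by symmetry
  expect_gte(wilcoxon_one_sided(c(1, 2, 3), c(1, 2, 3), "greater"), 0.5)
  # untied data: the two one-sided p-values overlap at the observed statistic
  set.seed(3)
  for (i in 1:5) {
    x <- sample(1:100, 5); y <- sample(101:200, 4)
    pg <- wilcoxon_one_sided(x, y, "greater", exact = TRUE)
    pl <- wilcoxon_one_sided(x, y, "less", exact = TRUE)
    expect_gte(pg + pl, 1)
  }
})

test_that("Wilcoxon agrees with the base-R oracle on untied data", {
  set.seed(21)
  for (i in 1:10) {
    x <- runif(6); y <- runif(7) + 0.2
    expect_equal(wilcoxon_one_sided(x, y, "greater", exact = TRUE),
                 wilcox.test(x, y, alternative = "greater",
                             exact = TRUE)$p.value, tolerance = 1e-12)
    # approximate path matches the tie-corrected continuity-corrected normal
    expect_equal(wilcoxon_one_sided(x, y, "less", exact = FALSE),
                 wilcox.test(x, y, alternative = "less", exact = FALSE,
                             correct = TRUE)$p.value, tolerance = 1e-12)
  }
  # with ties the exact path still enumerates; midranks match wilcox.test W
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  expect_silent(p <- wilcoxon_one_sided(x, y, "less", exact = TRUE))
  expect_true(p > 0 && p <= 1)
  expect_error(wilcoxon_one_sided(numeric(0), 1), "non-empty")
})

test_that("chi-square goodness-of-fit matches hand computation", {
  r <- chi_square_gof(c(10, 10), c(1, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- chi_square_gof(c(10, 0), c(5, 5))
  expect_equal(r2$statistic, 10)
  expect_equal(r2$p_value, pchisq(10, 1, lower.tail = FALSE))
  expect_error(chi_square_gof(c(1, 2), c(0, 3)), "positive")
  expect_error(chi_square_gof(c(0, 0), c(1, 1)), "sum to zero")
})

test_that("chi-square p-values are calibrated under a multinomial null", {
  set.seed(99)
  draws <- rmultinom(10000, size = 500, prob = rep(1 / 6, 6))
  ps <- apply(draws, 2, function(o) chi_square_gof(o, rep(1, 6))$p_value)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
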