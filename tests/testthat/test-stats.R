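# exhaustive draw-enumeration oracle for the hypergeometric tail:
# all C(N, n) draws from a universe with K marked elements
enum_hyper_sf <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)      # elements 1..K are the category
  mean(hits >= k)
}

# direct tail sum from the pmf definition (independent of phyper's code path)
sum_hyper_sf <- function(N, K, n, k) {
  kk <- k:min(n, K)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

test_that("hypergeom_sf matches exhaustive enumeration on small universes", {
  expect_equal(hypergeom_sf(10, 5, 4, 2), 155 / 210, tolerance = 1e-12)
  expect_equal(enum_hyper_sf(10, 5, 4, 2), 155 / 210, tolerance = 1e-12)
  set.seed(1)
  for (rep in 1:20) {
    N <- sample(4:11, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_sf(N, K, n, k), enum_hyper_sf(N, K, n, k),
                 tolerance = 1e-12,
                 label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
  # larger universes against the direct tail sum
  for (rep in 1:30) {
    N <- sample(12:60, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(0:min(n, K), 1)
    expected <- sum_hyper_sf(N, K, n, max(k, 1))
    if (k == 0) expected <- 1
    expect_equal(hypergeom_sf(N, K, n, k), expected, tolerance = 1e-12)
  }
})

test_that("hypergeom pmf sums to one and the tail is monotone in k", {
  for (N in c(7, 20, 113, 200)) {
    K <- max(1, N %/% 3); n <- max(1, N %/% 4)
    kk <- 0:min(n, K)
    pmf <- stats::dhyper(kk, K, N - K, n)
    expect_lt(abs(sum(pmf) - 1), 1e-12)
    sf <- vapply(kk, function(k) hypergeom_sf(N, K, n, k), numeric(1))
    expect_true(all(diff(sf) <= 1e-15))
  }
  expect_equal(hypergeom_sf(100, 10, 10, 0), 1.0)
  expect_error(hypergeom_sf(10, 2, 3, 5), "impossible")
})

test_that("hypergeom_sf stays finite in log space for extreme tails", {
  lp <- hypergeom_sf(40000, 4000, 2000, 2000, log.p = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp, -2000)  # far below what a plain double could represent
  # log and linear scales agree where both are representable
  expect_equal(exp(hypergeom_sf(4140, 414, 216, 99, log.p = TRUE)),
               hypergeom_sf(4140, 414, 216, 99), tolerance = 1e-12)
})

test_that("overlap_enrichment logs all four parameters and handles edges", {
  u <- paste0("g", 1:100)
  r <- overlap_enrichment(u[1:20], u[11:40], u)
  expect_equal(unname(r$parameter), c(100, 30, 20))
  expect_equal(unname(r$statistic), 10)
  expect_equal(r$expected, 20 * 30 / 100)
  expect_equal(unname(r$estimate), 10 / 6)
  expect_equal(r$p.value, hypergeom_sf(100, 30, 20, 10))

  # degenerate certainty: A = B = universe, X is constant at n
  expect_equal(overlap_enrichment(u, u, u)$p.value, 1.0)
  # disjoint sets: k = 0 so P(X >= 0) = 1
  expect_equal(overlap_enrichment(u[1:10], u[11:20], u)$p.value, 1.0)
  expect_error(overlap_enrichment(c(u[1:3], "zz"), u[1:5], u), "zz")
})

test_that("complementary-tail cross-check on the 99-of-216 overlap", {
  p <- hypergeom_sf(4140, 414, 216, 99)
  # lower tail of the complement, summed independently in log space
  kk <- 0:98
  lower <- sum(exp(lchoose(414, kk) + lchoose(4140 - 414, 216 - kk) -
                     lchoose(4140, 216)))
  expect_equal(p, 1 - lower, tolerance = 1e-9)
})

test_that("KS enrichment matches hand-walked ECDFs and transforms", {
  scores <- setNames(c(10, 20, 30, 1, 2, 3), paste0("g", 1:6))
  r <- ks_rank_enrichment(scores, paste0("g", 1:3))
  expect_equal(unname(r$statistic), 1.0)     # disjoint supports

  s2 <- setNames(c(1, 3, 2, 4), c("a", "b", "c", "d"))
  r2 <- ks_rank_enrichment(s2, c("a", "b"))
  expect_equal(unname(r2$statistic), 0.5)    # hand-walked ECDF gap

  # D is invariant under strictly monotone transforms
  set.seed(4)
  s3 <- setNames(rnorm(40), paste0("g", 1:40))
  sub <- paste0("g", sample(40, 15))
  d1 <- ks_rank_enrichment(s3, sub)$statistic
  d2 <- ks_rank_enrichment(exp(2 * s3) + 5, sub)$statistic
  expect_equal(d1, d2)

  expect_error(ks_rank_enrichment(s3, character()), "non-empty")
  expect_error(ks_rank_enrichment(s3, names(s3)), "non-empty")
})

test_that("KS p is approximately uniform under a null subset", {
  set.seed(77)
  p <- replicate(1000, {
    scores <- setNames(rnorm(200), paste0("g", 1:200))
    ks_rank_enrichment(scores, sample(names(scores), 60))$p.value
  })
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("location tests match small-sample permutation oracles", {
  a <- c(1, 2); b <- c(3, 4)
  lt <- location_tests(a, b)
  expect_equal(unname(lt$wilcox$statistic), 0)

  # exact two-sided Mann-Whitney p by full enumeration of group assignments
  perm_wilcox_p <- function(a, b) {
    pool <- c(a, b); na <- length(a)
    obs <- sum(rank(pool)[seq_len(na)]) - na * (na + 1) / 2
    combs <- utils::combn(length(pool), na)
    U <- apply(combs, 2, function(idx)
      sum(rank(pool)[idx]) - na * (na + 1) / 2)
    mu <- na * length(b) / 2
    mean(abs(U - mu) >= abs(obs - mu) - 1e-9)
  }
  set.seed(6)
  for (rep in 1:5) {
    a <- rnorm(4); b <- rnorm(5) + 0.5   # continuous: tie-free, exact U

    expect_equal(location_tests(a, b)$wilcox$p.value, perm_wilcox_p(a, b),
                 tolerance = 1e-10)
  }

  # symmetric case: identical samples give U = n^2/2 and p ~ 1
  x <- c(1.1, 2.2, 3.3, 4.4)
  lt2 <- location_tests(x, x)
  expect_equal(unname(lt2$wilcox$statistic), length(x)^2 / 2)
  expect_gt(lt2$wilcox$p.value, 0.9)

  expect_error(location_tests(rep(1, 3), rep(1, 3)), "Mann-Whitney")
})

test_that("exact small-sample KS p matches its permutation oracle", {
  perm_ks_p <- function(scores, subset_idx) {
    pool <- scores; n <- length(subset_idx)
    obs <- unname(stats::ks.test(pool[subset_idx], pool[-subset_idx])$statistic)
    combs <- utils::combn(length(pool), n)
    D <- apply(combs, 2, function(idx)
      unname(stats::ks.test(pool[idx], pool[-idx])$statistic))
    mean(D >= obs - 1e-12)
  }
  set.seed(14)
  scores <- setNames(round(rnorm(8), 3), paste0("g", 1:8))
  sub <- c(1, 3, 5, 7)
  r <- ks_rank_enrichment(scores, names(scores)[sub], exact = TRUE)
  expect_equal(r$p.value, perm_ks_p(unname(scores), sub), tolerance = 1e-10)
})
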