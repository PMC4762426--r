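panel_fixture <- function() {
  mutation_panel(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 301, 250), c(200, 400, 320))))
}

test_that("panel size merges overlapping amplicons", {
  p <- panel_fixture()
  # [101,200] and [250,400] after merging [250,320] into [301,400]
  expect_equal(p$L, 100 + 151)
  expect_equal(length(p$intervals), 2)
})

test_that("de novo counting matches on chrom/pos/ref/alt within the panel", {
  p <- panel_fixture()
  base <- data.frame(chrom = "chr1", pos = 120L, ref = "A", alt = "T")
  ep <- rbind(base,
              data.frame(chrom = "chr1", pos = c(150L, 310L), ref = "C",
                         alt = "G"),
              data.frame(chrom = "chr1", pos = 500L, ref = "G", alt = "A"))
  r <- count_de_novo(base, ep, p)
  expect_equal(r$k, 2)                       # pos 500 outside the panel
  expect_equal(sort(r$novel$pos), c(150L, 310L))

  expect_equal(count_de_novo(base, base, p)$k, 0)

  # same position, different allele, is a new event
  ep2 <- rbind(base, data.frame(chrom = "chr1", pos = 120L, ref = "A",
                                alt = "G"))
  expect_equal(count_de_novo(base, ep2, p)$k, 1)
})

test_that("unnormalised indel representations are rejected", {
  p <- panel_fixture()
  bad <- data.frame(chrom = "chr1", pos = 150L, ref = "AT", alt = "GT")
  expect_error(count_de_novo(bad, bad, p), "normalis")
  ok <- data.frame(chrom = "chr1", pos = 150L, ref = "AT", alt = "A")
  expect_silent(count_de_novo(ok, ok, p))
})

test_that("burden_test matches exhaustive outcome enumeration for tiny L", {
  # brute force: enumerate all 2^L site outcomes
  enum_burden_p <- function(k, L, p_site) {
    outcomes <- expand.grid(rep(list(c(0, 1)), L))
    counts <- rowSums(outcomes)
    probs <- apply(outcomes, 1, function(o)
      prod(ifelse(o == 1, p_site, 1 - p_site)))
    sum(probs[counts >= k])
  }
  set.seed(10)
  for (rep in 1:5) {
    L <- sample(3:10, 1)
    mu <- runif(1, 0.01, 0.2); g <- sample(1:5, 1)
    k <- sample(0:L, 1)
    p_site <- 1 - (1 - mu)^g
    expect_equal(burden_test(k, L, mu, g)$p.value,
                 if (k == 0) 1 else enum_burden_p(k, L, p_site),
                 tolerance = 1e-10)
  }
  # direct binomial sum for L up to 30
  for (L in c(20, 30)) {
    p_site <- 1 - (1 - 0.05)^3
    for (k in c(0, 1, 3, 7)) {
      direct <- sum(choose(L, k:L) * p_site^(k:L) * (1 - p_site)^(L - k:L))
      expect_equal(burden_test(k, L, 0.05, 3)$p.value,
                   if (k == 0) 1 else direct, tolerance = 1e-10)
    }
  }
})

test_that("burden p agrees with the Poisson limit at panel scale", {
  L <- 5e4; mu <- 6e-8; g <- 45
  p_site <- 1 - (1 - mu)^g
  lambda <- L * p_site
  expect_equal(lambda, 0.135, tolerance = 0.001)
  for (k in 1:4) {
    b <- burden_test(k, L, mu, g)$p.value
    pois <- stats::ppois(k - 1, lambda, lower.tail = FALSE)
    expect_lt(abs(b - pois) / pois, 0.01)
  }
  # one observed mutation against this null: p ~ 0.126
  expect_equal(burden_test(1, L, mu, g)$p.value, 0.126, tolerance = 0.005)
})

test_that("burden p is monotone in k and in L", {
  ps <- vapply(0:6, function(k) burden_test(k, 1e4, 1e-6, 45)$p.value,
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  pL <- vapply(c(1e3, 1e4, 1e5), function(L)
    burden_test(2, L, 1e-6, 45)$p.value, numeric(1))
  expect_true(all(diff(pL) >= 0))
  expect_equal(burden_test(0, 100, 0.01, 5)$p.value, 1.0)
  expect_error(burden_test(-1, 100, 0.01, 5), ">= 0")
  expect_error(burden_test(1, 100, 2, 5), "mu")
})

test_that("simulated mutation counts follow the analytic expectation", {
  # mu = 0: no de novo events; mu = 1, g = 1: every site mutated
  ann <- generate_annotation(small_config(seed = 3, n_genes = 60))
  m0 <- simulate_mutations(small_config(seed = 3, n_genes = 60, mu = 0), ann)
  expect_equal(nrow(m0$de_novo), 0)
  cfg1 <- small_config(seed = 3, n_genes = 60, mu = 1, generations = 1,
                       n_baseline_variants = 0)
  m1 <- simulate_mutations(cfg1, ann)
  expect_equal(nrow(m1$de_novo), m1$panel$L)

  # analytic mean: L * (1 - (1 - mu)^g); panel pinned to the histone class
  # so its size does not vary across seeds
  cfg <- small_config(seed = 3, n_genes = 60, mu = 1e-4, generations = 10,
                      panel_n_other = 0)
  counts <- vapply(1:300, function(s) {
    c2 <- cfg; c2$seed <- s
    nrow(simulate_mutations(c2, ann)$de_novo)
  }, numeric(1))
  L <- simulate_mutations(cfg, ann)$panel$L
  expected <- (L - cfg$n_baseline_variants) * (1 - (1 - 1e-4)^10)
  se <- sqrt(expected) / sqrt(300)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("VCF round trip preserves calls and the full loop counts truth", {
  cfg <- small_config(seed = 17, n_genes = 80, mu = 1e-4, generations = 20)
  ann <- generate_annotation(cfg)
  m <- simulate_mutations(cfg, ann)
  dir <- tempfile()
  dir.create(dir)
  write_vcf(m$baseline, file.path(dir, "b.vcf"), ann$layout)
  write_vcf(m$endpoint, file.path(dir, "e.vcf"), ann$layout)
  base <- read_variants(file.path(dir, "b.vcf"))
  ep <- read_variants(file.path(dir, "e.vcf"))
  expect_equal(nrow(base), nrow(m$baseline))
  expect_equal(nrow(ep), nrow(m$endpoint))
  r <- count_de_novo(base, ep, m$panel)
  expect_equal(r$k, nrow(m$de_novo))
})
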