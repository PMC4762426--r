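test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(fraction_damaged = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(mu = -1e-8), "\\[0, 1\\]")
  expect_error(synthetic_config(damage_ratio = 0), "> 0")
  expect_error(synthetic_config(chrom_length = 1.00001e6, bin_width = 50),
               "multiple")
})

test_that("planted flag counts equal the configured fractions", {
  cfg <- small_config(seed = 5, n_genes = 100)
  tr <- generate_annotation(cfg)$truth
  expect_equal(sum(tr$damaged), 10)          # 0.10 x 100
  expect_equal(sum(tr$stressed), 10)         # stressed = damaged by default
  expect_equal(sum(tr$histone), 5)           # 0.05 x 100

  cfg2 <- small_config(seed = 5, n_genes = 100, fraction_stressed = 0.2)
  tr2 <- generate_annotation(cfg2)$truth
  expect_equal(sum(tr2$stressed), 20)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 31, n_genes = 60)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$annotation$truth, d2$annotation$truth)
  expect_identical(lapply(d1$tracks, `[[`, "signal"),
                   lapply(d2$tracks, `[[`, "signal"))
  expect_identical(d1$mutations$mutant$endpoint,
                   d2$mutations$mutant$endpoint)

  d3 <- generate_dataset(small_config(seed = 32, n_genes = 60))
  expect_false(identical(d1$annotation$truth, d3$annotation$truth))
})

test_that("genes do not overlap and stay within chromosome bounds", {
  for (seed in c(1, 2, 3)) {
    ann <- generate_annotation(small_config(seed = seed, n_genes = 150))
    g <- ann$genes
    expect_true(all(GenomicRanges::start(g) >= 1))
    expect_true(all(GenomicRanges::end(g) <=
                      GenomeInfoDb::seqlengths(g)[
                        as.character(GenomicRanges::seqnames(g))]))
    expect_true(IRanges::isDisjoint(g, ignore.strand = TRUE))
  }
  # infeasible packing raises the configured error
  expect_error(
    generate_annotation(synthetic_config(
      seed = 1, n_chroms = 1, chrom_length = 1e5, n_genes = 200)),
    "chrom_length|overlap")
})

test_that("gene-length medians hit the planted targets", {
  tr <- generate_annotation(synthetic_config(seed = 2))$truth
  expect_equal(median(tr$length[tr$damaged]) / 1000, 4.1, tolerance = 0.1)
  expect_equal(median(tr$length) / 1000, 10.6, tolerance = 0.08)
  # damaged genes are also more highly expressed
  expect_gt(median(tr$expression[tr$damaged]),
            median(tr$expression[!tr$damaged]))
})

test_that("fragile-site enrichment follows the configured odds", {
  # odds ratio 1: coverage of damaged vs undamaged equal within MC error
  hits <- matrix(0, nrow = 200, ncol = 2)
  for (s in 1:200) {
    cfg <- small_config(seed = s, n_genes = 100, erfs_enrichment = 1)
    tr <- generate_annotation(cfg)$truth
    hits[s, ] <- c(mean(tr$erfs_overlap[tr$damaged]),
                   mean(tr$erfs_overlap[!tr$damaged]))
  }
  rates <- colMeans(hits)
  # both estimate the same coverage probability; flanked intervals can
  # also catch a close neighbour, so compare the two rates to each other
  expect_lt(abs(rates[1] - rates[2]), 3 * sqrt(0.15 * 0.85 / (200 * 10)))

  # strong enrichment separates the rates
  tr2 <- generate_annotation(synthetic_config(
    seed = 9, n_chroms = 4, chrom_length = 3e6, n_genes = 300,
    erfs_enrichment = 8))$truth
  expect_gt(mean(tr2$erfs_overlap[tr2$damaged]),
            mean(tr2$erfs_overlap[!tr2$damaged]))
})

test_that("noiseless tracks carry exactly the planted densities", {
  cfg <- small_config(seed = 12, n_genes = 50, noise = FALSE)
  ds <- generate_dataset(cfg)
  tr <- ds$annotation$truth
  g <- ds$annotation$genes
  dmg <- which(tr$damaged)[1]
  und <- which(!tr$damaged)[1]
  d_ff <- gene_density(ds$tracks$gH2AX_FF, g[dmg], flank = 0)
  d_fc <- gene_density(ds$tracks$gH2AX_FCFC, g[dmg], flank = 0)
  expect_equal(unname(d_fc / d_ff), cfg$damage_ratio, tolerance = 1e-12)
  u_ff <- gene_density(ds$tracks$gH2AX_FF, g[und], flank = 0)
  u_fc <- gene_density(ds$tracks$gH2AX_FCFC, g[und], flank = 0)
  expect_equal(unname(u_fc / u_ff), 1.0, tolerance = 1e-12)
})

test_that("noisy per-gene damage ratios are centred on the planted effect", {
  # Monte-Carlo over seeds: mean mutant:control gH2AX/H3 ratio of damaged
  # genes approaches damage_ratio
  means <- vapply(1:25, function(s) {
    ds <- generate_dataset(small_config(seed = 100 + s, n_genes = 40))
    dens <- density_table(ds$tracks, ds$annotation$genes)
    r <- ratio_table(dens, pseudocount = 0)
    m <- merge(r, ds$annotation$truth, by = "gene_id")
    mean(m$gH2AX_H3[m$damaged])
  }, numeric(1))
  expect_equal(mean(means), 1.5, tolerance = 0.02)
})

test_that("GRO tracks are sense-strand only", {
  ds <- generate_dataset(small_config(seed = 19, n_genes = 40,
                                      noise = FALSE))
  tr <- ds$annotation$truth
  g <- ds$annotation$genes
  plus_gene <- g[which(tr$strand == "+")[1]]
  d_plus <- gene_density(ds$tracks$GRO_FF_plus, plus_gene, flank = 0)
  d_minus <- gene_density(ds$tracks$GRO_FF_minus, plus_gene, flank = 0)
  expect_gt(unname(d_plus), 0)
  expect_equal(unname(d_minus), 0)
})

test_that("a written dataset reloads consistently from standard formats", {
  cfg <- small_config(seed = 23, n_genes = 40)
  ds <- generate_dataset(cfg)
  dir <- tempfile()
  write_synthetic_dataset(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genome.chrom.sizes", "genes.bed", "erfs.bed", "truth.tsv",
           "gH2AX_FF.bedGraph", "GRO_FCFC_minus.bedGraph", "config.yaml",
           "control_baseline.vcf", "mutant_endpoint.vcf")))))
  layout <- read_chrom_sizes(file.path(dir, "genome.chrom.sizes"))
  expect_equal(unname(layout), unname(ds$annotation$layout))
  genes <- read_genes(file.path(dir, "genes.bed"), layout = layout)
  expect_equal(genes$gene_id, ds$annotation$genes$gene_id)
  expect_equal(GenomicRanges::start(genes),
               GenomicRanges::start(ds$annotation$genes))
  tr <- read_coverage(file.path(dir, "gH2AX_FCFC.bedGraph"), layout,
                      "gH2AX", "FCFC")
  expect_equal(as.numeric(S4Vectors::window(tr$signal$chr1, 1, 2e5)),
               as.numeric(S4Vectors::window(
                 ds$tracks$gH2AX_FCFC$signal$chr1, 1, 2e5)))
  ep <- read_variants(file.path(dir, "mutant_endpoint.vcf"))
  expect_equal(nrow(ep), nrow(ds$mutations$mutant$endpoint))
})
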