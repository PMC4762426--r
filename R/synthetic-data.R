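#' Synthetic study configuration
#'
#' Parameters of the synthetic two-condition study the generator emulates: a
#' control ("FF") and a perturbed ("FCFC") condition with coverage tracks for
#' gamma-H2AX, H2AX, H3, RNAPII and strand-resolved GRO; a planted ~10%
#' subset of short, highly expressed genes whose gamma-H2AX/H3 ratio rises
#' ~1.5-fold and whose RNAPII accumulates (x1.3) without a nascent
#' transcription increase (x0.95); a histone-like gene class concentrated in
#' the damaged subset; fragile-site intervals enriched over damaged genes;
#' and per-site mutation accumulation at rate `mu` over `g` generations in a
#' targeted panel.
#'
#' All randomness is derived from `seed`; one RNG stream per generator stage
#' so adding a stage does not perturb earlier draws. Identical configs give
#' bit-identical outputs.
#'
#' @param seed master seed (integer).
#' @param n_chroms,chrom_length genome shape; `chrom_length` must be a
#'   multiple of `bin_width`.
#' @param bin_width coverage bin size in bp; Poisson counts are drawn per
#'   bin and densities are counts/width. Gene coordinates are aligned to
#'   this grid so noiseless ratios equal planted effects exactly.
#' @param n_genes number of genes.
#' @param fraction_damaged planted damaged fraction (default 0.10).
#' @param fraction_stressed planted stressed fraction; `NULL` (default)
#'   makes the stressed set identical to the damaged set.
#' @param fraction_histone histone-like gene fraction (default 0.0147,
#'   i.e. 61 of 4140).
#' @param histone_damage_weight sampling weight of damaged genes when the
#'   histone-like class is drawn (default 6.8, putting roughly 40% of
#'   histone-like genes in the damaged set).
#' @param length_meanlog,length_sdlog log-normal gene-length parameters for
#'   undamaged genes (defaults target an overall median of ~10.6 kb).
#' @param damaged_length_meanlog,damaged_length_sdlog the same for damaged
#'   genes (median ~4.1 kb).
#' @param min_gene_length,min_gap floors on gene length and intergenic gap
#'   (bp); the gap keeps +/-500 bp windows of neighbours disjoint.
#' @param expression_shape,expression_scale gamma parameters of baseline
#'   expression density (signal per bp) for undamaged genes.
#' @param damaged_expression_shape,damaged_expression_scale the same for
#'   damaged genes (higher: damaged genes are highly expressed).
#' @param damage_ratio planted gamma-H2AX/H3 case:control ratio at damaged
#'   genes (default 1.5).
#' @param stress_rnapii_ratio,stress_gro_ratio planted RNAPII and GRO
#'   case:control ratios at stressed genes (defaults 1.3 and 0.95).
#' @param h3_level,h2ax_level flat genome-wide densities of the control
#'   histone tracks.
#' @param gammah2ax_base control-condition gamma-H2AX density within genes
#'   (zero intergenic).
#' @param tss_peak_height,tss_peak_len relative height and width (bp) of
#'   the promoter-proximal RNAPII peak.
#' @param noise draw per-bin Poisson counts (TRUE) or emit expected
#'   densities exactly (FALSE).
#' @param erfs_rate probability an undamaged gene is covered by a
#'   fragile-site interval.
#' @param erfs_enrichment odds ratio of fragile-site coverage, damaged vs
#'   undamaged genes (default 2.5, giving ~25% coverage of damaged genes).
#' @param erfs_flank fragile-site interval flank around a covered gene (bp).
#' @param panel_n_histone,panel_n_other panel composition: histone-like
#'   genes targetable at high coverage plus a few other genes (~50 kb
#'   total).
#' @param n_baseline_variants pre-existing variants in the panel.
#' @param mu per-site per-generation mutation rate (default 6e-8).
#' @param generations number of cell doublings g (default 45).
#' @param mutant_rate_multiplier fold increase of `mu` in the perturbed
#'   condition (default 50, a hypermutator phenotype).
#' @param mutation_type_mix probabilities of substitution / insertion /
#'   deletion for simulated events.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_chroms = 8, chrom_length = 1.2e7,
                             bin_width = 50, n_genes = 4140,
                             fraction_damaged = 0.10,
                             fraction_stressed = NULL,
                             fraction_histone = 0.0147,
                             histone_damage_weight = 6.8,
                             length_meanlog = log(11470),
                             length_sdlog = 0.6,
                             damaged_length_meanlog = log(4100),
                             damaged_length_sdlog = 0.5,
                             min_gene_length = 200, min_gap = 2000,
                             expression_shape = 2, expression_scale = 2,
                             damaged_expression_shape = 4,
                             damaged_expression_scale = 2,
                             damage_ratio = 1.5,
                             stress_rnapii_ratio = 1.3,
                             stress_gro_ratio = 0.95,
                             h3_level = 2, h2ax_level = 2,
                             gammah2ax_base = 2,
                             tss_peak_height = 1, tss_peak_len = 500,
                             noise = TRUE,
                             erfs_rate = 0.12, erfs_enrichment = 2.5,
                             erfs_flank = 1000,
                             panel_n_histone = 8, panel_n_other = 1,
                             n_baseline_variants = 5,
                             mu = 6e-8, generations = 45,
                             mutant_rate_multiplier = 50,
                             mutation_type_mix = c(sub = 0.7, ins = 0.15,
                                                   del = 0.15)) {
  cfg <- as.list(environment())
  props <- c("fraction_damaged", "fraction_histone")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (!is.null(fraction_stressed) &&
      (fraction_stressed < 0 || fraction_stressed > 1))
    stop("fraction_stressed must be in [0, 1]")
  for (p in c("damage_ratio", "stress_rnapii_ratio", "stress_gro_ratio",
              "erfs_enrichment"))
    if (cfg[[p]] <= 0) stop(p, " must be > 0")
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  if (chrom_length %% bin_width != 0)
    stop("chrom_length must be a multiple of bin_width")
  cfg$mutation_type_mix <- mutation_type_mix / sum(mutation_type_mix)
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_config> seed=%d | %d genes on %d x %s bp chromosomes\n",
    "  damaged %.0f%% (gH2AX x%.2f), stress x%.2f/x%.2f, noise=%s\n",
    "  mu=%.2g, g=%d, mutant rate x%g\n"),
    x$seed, x$n_genes, x$n_chroms, format(x$chrom_length, scientific = FALSE),
    100 * x$fraction_damaged, x$damage_ratio, x$stress_rnapii_ratio,
    x$stress_gro_ratio, x$noise, x$mu, x$generations,
    x$mutant_rate_multiplier))
  invisible(x)
}

# one derived RNG stream per generator stage
stage_seed <- function(config, stage) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(config$seed)
  s <- sample.int(.Machine$integer.max - 1L, 10L)[stage]
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s
}

align_bin <- function(x, bw) pmax(bw, round(x / bw) * bw)

#' Generate the synthetic gene annotation, fragile sites and truth table
#'
#' Places non-overlapping genes (lengths log-normal; the damaged subset
#' short and highly expressed), assigns histone-like labels and fragile-site
#' coverage with the configured enrichment over damaged genes, and returns
#' the per-gene truth table the tests score against.
#'
#' @param config a [synthetic_config()].
#' @return List of class `synthetic_annotation`: `genes` (GRanges),
#'   `erfs` (GRanges, merged fragile-site intervals), `truth` (data.frame),
#'   `layout` ([genome_layout()]) and `config`.
#' @export
generate_annotation <- function(config) {
  set.seed(stage_seed(config, 1))
  n <- config$n_genes
  bw <- config$bin_width
  layout <- genome_layout(sprintf("chr%d", seq_len(config$n_chroms)),
                          rep(config$chrom_length, config$n_chroms))
  n_dmg <- as.integer(round_half_up(config$fraction_damaged * n))
  damaged <- logical(n)
  damaged[sample.int(n, n_dmg)] <- TRUE

  len <- numeric(n)
  len[damaged] <- rlnorm(n_dmg, config$damaged_length_meanlog,
                         config$damaged_length_sdlog)
  len[!damaged] <- rlnorm(n - n_dmg, config$length_meanlog,
                          config$length_sdlog)
  len <- align_bin(pmax(len, config$min_gene_length), bw)

  expr <- numeric(n)
  expr[damaged] <- rgamma(n_dmg, config$damaged_expression_shape,
                          scale = config$damaged_expression_scale)
  expr[!damaged] <- rgamma(n - n_dmg, config$expression_shape,
                           scale = config$expression_scale)
  expr <- pmax(expr, 0.05)

  # assign genes to chromosomes greedily by remaining capacity
  need <- len + config$min_gap
  cap <- unname(layout) - config$min_gap
  chrom_idx <- integer(n)
  ord <- sample.int(n)                    # random placement order
  for (i in ord) {
    j <- which.max(cap)
    if (cap[j] < need[i])
      stop("cannot place genes without overlap; increase chrom_length ",
           "or n_chroms, or reduce n_genes")
    chrom_idx[i] <- j
    cap[j] <- cap[j] - need[i]
  }
  start <- integer(n)
  for (j in seq_len(config$n_chroms)) {
    idx <- ord[chrom_idx[ord] == j]       # file order = placement order
    if (!length(idx)) next
    slack <- unname(layout[j]) - sum(len[idx]) -
      (length(idx) + 1) * config$min_gap
    u <- runif(length(idx) + 1)
    extra <- floor(slack * u / sum(u))
    gaps <- config$min_gap + extra        # one leading gap per gene + trailing
    s <- cumsum(gaps[seq_along(idx)]) +
      c(0, cumsum(len[idx]))[seq_along(idx)]
    start[idx] <- floor(s / bw) * bw + 1L # 1-based, bin-aligned
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("g%05d", seq_len(n))

  n_hist <- as.integer(round_half_up(config$fraction_histone * n))
  histone <- logical(n)
  if (n_hist > 0) {
    w <- ifelse(damaged, config$histone_damage_weight, 1)
    histone[sample.int(n, n_hist, prob = w)] <- TRUE
  }

  if (is.null(config$fraction_stressed)) {
    stressed <- damaged
  } else {
    n_str <- as.integer(round_half_up(config$fraction_stressed * n))
    stressed <- logical(n)
    stressed[sample.int(n, n_str, prob = expr)] <- TRUE
  }

  # fragile-site intervals with configured odds over damaged genes
  odds_u <- config$erfs_rate / (1 - config$erfs_rate)
  p_dmg <- config$erfs_enrichment * odds_u /
    (1 + config$erfs_enrichment * odds_u)
  p_cov <- ifelse(damaged, p_dmg, config$erfs_rate)
  covered <- runif(n) < p_cov
  genes <- GRanges(names(layout)[chrom_idx],
                   IRanges(start = start, width = len), strand = strand,
                   gene_id = gene_id,
                   gene_class = ifelse(histone, "histone", ""),
                   seqinfo = as_seqinfo(layout))
  erfs <- GRanges()
  if (any(covered)) {
    g <- genes[covered]
    erfs <- reduce(GRanges(
      seqnames(g),
      IRanges(pmax(1, start(g) - config$erfs_flank),
              pmin(seqlengths(g)[as.character(seqnames(g))],
                   end(g) + config$erfs_flank)),
      seqinfo = as_seqinfo(layout)), ignore.strand = TRUE)
  }
  erfs_overlap <- countOverlaps(genes, erfs, ignore.strand = TRUE) > 0

  truth <- data.frame(
    gene_id = gene_id, chrom = names(layout)[chrom_idx],
    start = start, end = start + as.integer(len) - 1L, strand = strand,
    length = as.integer(len), expression = expr,
    damaged = damaged, stressed = stressed, histone = histone,
    erfs_overlap = erfs_overlap,
    true_damage_ratio = ifelse(damaged, config$damage_ratio, 1),
    true_rnapii_ratio = ifelse(stressed, config$stress_rnapii_ratio, 1),
    true_gro_ratio = ifelse(stressed, config$stress_gro_ratio, 1))

  structure(list(genes = genes, erfs = erfs, truth = truth,
                 layout = layout, config = config),
            class = "synthetic_annotation")
}

# expected per-bin density vectors for one chromosome
expected_bins <- function(ann, chrom) {
  config <- ann$config
  bw <- config$bin_width
  nbins <- config$chrom_length %/% bw
  tr <- ann$truth[ann$truth$chrom == chrom, ]
  base <- list(
    H3_FF = rep(config$h3_level, nbins), H2AX_FF = rep(config$h2ax_level, nbins),
    gH2AX_FF = numeric(nbins), RNAPII_FF = numeric(nbins),
    GRO_FF_plus = numeric(nbins), GRO_FF_minus = numeric(nbins))
  base$H3_FCFC <- base$H3_FF; base$H2AX_FCFC <- base$H2AX_FF
  base$gH2AX_FCFC <- base$gH2AX_FF; base$RNAPII_FCFC <- base$RNAPII_FF
  base$GRO_FCFC_plus <- base$GRO_FF_plus
  base$GRO_FCFC_minus <- base$GRO_FF_minus
  if (!nrow(tr)) return(base)
  peak_bins <- config$tss_peak_len %/% bw
  for (i in seq_len(nrow(tr))) {
    b0 <- (tr$start[i] - 1L) %/% bw + 1L
    b1 <- tr$end[i] %/% bw
    bins <- b0:b1
    e <- tr$expression[i]
    base$gH2AX_FF[bins] <- config$gammah2ax_base
    base$gH2AX_FCFC[bins] <- config$gammah2ax_base * tr$true_damage_ratio[i]
    pol <- rep(e, length(bins))
    if (peak_bins > 0 && length(bins) > peak_bins) {
      pk <- if (tr$strand[i] == "+") seq_len(peak_bins) else
        length(bins) - seq_len(peak_bins) + 1L
      pol[pk] <- pol[pk] * (1 + config$tss_peak_height)
    }
    base$RNAPII_FF[bins] <- pol
    base$RNAPII_FCFC[bins] <- pol * tr$true_rnapii_ratio[i]
    gro_key <- if (tr$strand[i] == "+") "plus" else "minus"
    base[[paste0("GRO_FF_", gro_key)]][bins] <- e
    base[[paste0("GRO_FCFC_", gro_key)]][bins] <- e * tr$true_gro_ratio[i]
  }
  base
}

#' Generate coverage tracks for both conditions
#'
#' Control condition: flat H3/H2AX, baseline gamma-H2AX within genes,
#' RNAPII and sense-strand GRO proportional to expression (RNAPII with a
#' promoter-proximal peak). Perturbed condition: damaged genes scale
#' gamma-H2AX by `damage_ratio`; stressed genes scale RNAPII by
#' `stress_rnapii_ratio` and GRO by `stress_gro_ratio`. With `noise = TRUE`
#' per-bin counts are Poisson around expected density x bin width.
#'
#' @param config a [synthetic_config()].
#' @param annotation a [generate_annotation()] result (generated from
#'   `config` if missing).
#' @return Named list of 12 [coverage_track()] objects
#'   (`gH2AX/H2AX/H3/RNAPII` x `FF/FCFC`, plus `GRO` x condition x strand).
#' @export
generate_tracks <- function(config, annotation = NULL) {
  if (is.null(annotation)) annotation <- generate_annotation(config)
  set.seed(stage_seed(config, 2))
  bw <- config$bin_width
  layout <- annotation$layout
  keys <- c("gH2AX_FF", "gH2AX_FCFC", "H2AX_FF", "H2AX_FCFC",
            "H3_FF", "H3_FCFC", "RNAPII_FF", "RNAPII_FCFC",
            "GRO_FF_plus", "GRO_FF_minus", "GRO_FCFC_plus", "GRO_FCFC_minus")
  sig <- lapply(keys, function(k) list())
  names(sig) <- keys
  for (chrom in names(layout)) {
    exp_d <- expected_bins(annotation, chrom)
    for (k in keys) {
      d <- exp_d[[k]]
      if (config$noise) d <- rpois(length(d), d * bw) / bw
      sig[[k]][[chrom]] <- Rle(d, rep(bw, length(d)))
    }
  }
  out <- lapply(keys, function(k) {
    parts <- strsplit(k, "_", fixed = TRUE)[[1]]
    strand <- if (length(parts) == 3)
      c(plus = "+", minus = "-")[[parts[3]]] else "*"
    coverage_track(methods::as(sig[[k]], "SimpleRleList"), layout,
                   assay = parts[1], condition = parts[2], strand = strand)
  })
  names(out) <- keys
  out
}

# map linear panel offsets (1..L) to genomic positions
panel_positions <- function(panel, idx) {
  iv <- panel$intervals
  w <- width(iv)
  cum <- cumsum(w)
  j <- findInterval(idx - 1, c(0, cum), rightmost.closed = FALSE)
  data.frame(chrom = as.character(seqnames(iv))[j],
             pos = start(iv)[j] + (idx - c(0, cum)[j] - 1L))
}

random_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)
other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
}

#' Simulate mutation accumulation in the targeted panel
#'
#' Each panel site mutates independently with probability
#' `1 - (1 - mu * rate_multiplier)^g` across `g` generations. The endpoint
#' call set is the union of the baseline (pre-existing variants) and the de
#' novo records; event types follow the configured
#' substitution/insertion/deletion mix.
#'
#' @param config a [synthetic_config()].
#' @param annotation a [generate_annotation()] result.
#' @param rate_multiplier fold change of `mu` (1 = control condition).
#' @param stream RNG stream index (kept distinct per condition).
#' @return List of class `synthetic_mutations`: `panel`
#'   ([mutation_panel()]), `panel_gene_ids`, `baseline`, `de_novo` (with
#'   `generation` of origin), `endpoint` call tables.
#' @export
simulate_mutations <- function(config, annotation, rate_multiplier = 1,
                               stream = 3) {
  # panel composition and pre-existing variants are shared across
  # conditions (same starting population): dedicated stream
  set.seed(stage_seed(config, 5))
  tr <- annotation$truth
  hist_ids <- tr$gene_id[tr$histone]
  other_ids <- tr$gene_id[!tr$histone]
  sel <- c(
    if (length(hist_ids))
      sample(hist_ids, min(config$panel_n_histone, length(hist_ids))),
    sample(other_ids, min(config$panel_n_other, length(other_ids))))
  g <- annotation$genes[annotation$genes$gene_id %in% sel]
  panel <- mutation_panel(g)
  L <- panel$L

  n_base <- min(config$n_baseline_variants, L)
  base_idx <- sample.int(L, n_base)
  bpos <- panel_positions(panel, sort(base_idx))
  ref <- random_base(n_base)
  baseline <- data.frame(chrom = bpos$chrom, pos = bpos$pos, ref = ref,
                         alt = other_base(ref), stringsAsFactors = FALSE)

  set.seed(stage_seed(config, stream))
  mu_eff <- min(1, config$mu * rate_multiplier)
  gens <- config$generations
  p_site <- -expm1(gens * log1p(-mu_eff))
  free <- setdiff(seq_len(L), base_idx)
  k <- rbinom(1, length(free), p_site)
  de_novo <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        type = character(), generation = integer())
  if (k > 0) {
    idx <- sort(sample(free, k))
    dpos <- panel_positions(panel, idx)
    type <- sample(names(config$mutation_type_mix), k, replace = TRUE,
                   prob = config$mutation_type_mix)
    b1 <- random_base(k); b2 <- random_base(k)
    ref <- ifelse(type == "del", paste0(b1, b2), b1)
    alt <- ifelse(type == "sub", other_base(b1),
                  ifelse(type == "ins", paste0(b1, b2), b1))
    gen_prob <- mu_eff * (1 - mu_eff)^(seq_len(gens) - 1)
    generation <- if (gens > 0)
      sample.int(gens, k, replace = TRUE, prob = gen_prob) else integer(k)
    de_novo <- data.frame(chrom = dpos$chrom, pos = dpos$pos, ref = ref,
                          alt = alt, type = type, generation = generation,
                          stringsAsFactors = FALSE)
  }
  endpoint <- rbind(baseline, de_novo[, c("chrom", "pos", "ref", "alt")])
  structure(list(panel = panel, panel_gene_ids = sort(sel),
                 baseline = baseline, de_novo = de_novo,
                 endpoint = endpoint, rate_multiplier = rate_multiplier),
            class = "synthetic_mutations")
}

#' Generate a complete synthetic dataset
#'
#' Annotation, truth table, 12 coverage tracks, and mutation call sets for
#' the control (`rate_multiplier = 1`) and perturbed
#' (`mutant_rate_multiplier`) conditions.
#'
#' @param config a [synthetic_config()].
#' @return List of class `synthetic_dataset` with elements `annotation`,
#'   `tracks`, `mutations` (list `control`, `mutant`) and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  ann <- generate_annotation(config)
  tracks <- generate_tracks(config, ann)
  mut <- list(
    control = simulate_mutations(config, ann, 1, stream = 3),
    mutant = simulate_mutations(config, ann, config$mutant_rate_multiplier,
                                stream = 4))
  structure(list(annotation = ann, tracks = tracks, mutations = mut,
                 config = config), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  tr <- x$annotation$truth
  cat(sprintf(paste0(
    "<synthetic_dataset> %d genes (%d damaged, %d stressed, %d histone-like)\n",
    "  %d tracks | panel %d bp | de novo: control %d, mutant %d\n"),
    nrow(tr), sum(tr$damaged), sum(tr$stressed), sum(tr$histone),
    length(x$tracks), x$mutations$control$panel$L,
    nrow(x$mutations$control$de_novo), nrow(x$mutations$mutant$de_novo)))
  invisible(x)
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Emits chrom sizes, BED6 genes, BED fragile-site intervals and panel, 12
#' bedGraph tracks, baseline/endpoint VCFs per condition, the truth table
#' (TSV) and the configuration (YAML), each with a provenance header.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- dataset$annotation
  prov <- sprintf("stresscan synthetic dataset, seed=%d",
                  dataset$config$seed)
  write_chrom_sizes(ann$layout, file.path(dir, "genome.chrom.sizes"))
  write_genes(ann$genes, file.path(dir, "genes.bed"), header = prov)
  write_intervals(ann$erfs, file.path(dir, "erfs.bed"), header = prov)
  write_intervals(dataset$mutations$control$panel$intervals,
                  file.path(dir, "panel.bed"), header = prov)
  for (k in names(dataset$tracks))
    write_coverage(dataset$tracks[[k]],
                   file.path(dir, paste0(k, ".bedGraph")), header = prov)
  for (cond in names(dataset$mutations)) {
    m <- dataset$mutations[[cond]]
    write_vcf(m$baseline, file.path(dir, paste0(cond, "_baseline.vcf")),
              ann$layout, source = prov)
    write_vcf(m$endpoint, file.path(dir, paste0(cond, "_endpoint.vcf")),
              ann$layout, source = prov)
  }
  con <- file(file.path(dir, "truth.tsv"), "w")
  writeLines(paste0("#", prov), con)
  write.table(ann$truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  cfg <- dataset$config
  cfg$mutation_type_mix <- as.list(cfg$mutation_type_mix)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
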