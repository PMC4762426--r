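#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults reproduce the
#' standard analysis windows and fractions: gene body +/- 500 bp
#' quantification, TSS +/- 2 kb promoter profiles, top decile 0.10.
#'
#' @param synthetic a [synthetic_config()] describing the simulated inputs,
#'   or `NULL` when `paths` are given.
#' @param paths optional named list of input files for a real dataset:
#'   `chrom_sizes`, `genes` (BED6/GTF), `tracks` (named bedGraph paths,
#'   keys `<assay>_<condition>[_plus|_minus]`), optional `erfs`,
#'   `histone_ids` (text file of gene ids), `panel`,
#'   `baseline_vcf`, `endpoint_vcf`.
#' @param flank gene-body window flank in bp (default 500).
#' @param promoter_span promoter metagene half-window (default 2000).
#' @param fraction top-decile fraction (default 0.10).
#' @param pseudocount `"auto"` or a number; see [ratio_table()].
#' @param activity_threshold,activity_min_total see [active_genes()].
#' @param library_norm `"none"` (default; tracks already depth-calibrated)
#'   or `"spm"` (signal-per-million scaling via [library_scale()]).
#' @param universe enrichment universe: `"active"` (default) or `"all"`.
#' @param mu,generations burden-test null parameters (defaults 6e-8, 45).
#' @param body_bins,scaled_flank scaled metagene geometry.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), paths = NULL,
                            flank = 500, promoter_span = 2000,
                            fraction = 0.10, pseudocount = "auto",
                            activity_threshold = 0, activity_min_total = 10,
                            library_norm = c("none", "spm"),
                            universe = c("active", "all"),
                            mu = 6e-8, generations = 45,
                            body_bins = 100, scaled_flank = 500) {
  library_norm <- match.arg(library_norm)
  universe <- match.arg(universe)
  if (is.null(synthetic) && is.null(paths))
    stop("either a synthetic config or input paths must be given")
  structure(as.list(environment()), class = "pipeline_config")
}

read_pipeline_inputs <- function(paths) {
  layout <- read_chrom_sizes(paths$chrom_sizes)
  genes <- read_genes(paths$genes, layout = layout)
  tracks <- lapply(names(paths$tracks), function(k) {
    parts <- strsplit(k, "_", fixed = TRUE)[[1]]
    strand <- if (length(parts) == 3)
      c(plus = "+", minus = "-")[[parts[3]]] else "*"
    read_coverage(paths$tracks[[k]], layout, assay = parts[1],
                  condition = parts[2], strand = strand)
  })
  names(tracks) <- names(paths$tracks)
  erfs <- if (!is.null(paths$erfs)) read_intervals(paths$erfs, layout)
  histone_ids <- if (!is.null(paths$histone_ids))
    readLines(paths$histone_ids)
  if (!is.null(histone_ids))
    genes$gene_class <- ifelse(genes$gene_id %in% histone_ids, "histone", "")
  list(layout = layout, genes = genes, tracks = tracks, erfs = erfs)
}

#' Run the full stress/damage analysis
#'
#' Orchestrates the stages end to end: (synthetic) data generation or input
#' loading, per-gene density quantification over gene-body +/- flank
#' windows, case:control ratio tables, active-gene selection, damage/stress
#' classification with top-decile sets, overlap and enrichment statistics
#' (stress within damage: hypergeometric and rank KS; histone-class and
#' fragile-site enrichment; gene-length and expression location tests),
#' promoter and scaled metagene profiles, and — when variant data are
#' available — the de novo mutation-burden test per condition.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Object of class `stress_scan`; see [summary.stress_scan()].
#'   Components: `data`, `densities`, `ratios`, `calls`, `enrichment`,
#'   `profiles`, `burden`, `truth_recovery` (synthetic runs only) and
#'   `summary` (the flat record [write_report()] serialises).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  synthetic <- !is.null(config$synthetic)
  if (synthetic) {
    say("generating synthetic dataset (seed ", config$synthetic$seed, ")")
    ds <- generate_dataset(config$synthetic)
    layout <- ds$annotation$layout
    genes <- ds$annotation$genes
    tracks <- ds$tracks
    erfs <- ds$annotation$erfs
    truth <- ds$annotation$truth
  } else {
    say("reading inputs")
    inp <- read_pipeline_inputs(config$paths)
    layout <- inp$layout; genes <- inp$genes; tracks <- inp$tracks
    erfs <- inp$erfs; truth <- NULL
    ds <- NULL
  }

  say("quantifying per-gene densities (flank ", config$flank, " bp)")
  sf <- if (config$library_norm == "spm") library_scale(tracks) else NULL
  dens <- density_table(tracks, genes, flank = config$flank,
                        scale_factors = sf)
  ratios <- ratio_table(dens, pseudocount = config$pseudocount)

  gro_ctl <- dens[dens$assay == "GRO" & dens$condition == "FF", ]
  win_len <- width(gene_window(genes, config$flank, layout))
  names(win_len) <- genes$gene_id
  act <- active_genes(setNames(gro_ctl$density, gro_ctl$gene_id),
                      win_len[gro_ctl$gene_id],
                      threshold = config$activity_threshold,
                      min_total = config$activity_min_total)
  active_ids <- names(act)[act]
  say(length(active_ids), " active genes of ", length(genes))

  calls <- classify_stress_damage(ratios, active = active_ids,
                                  fraction = config$fraction)
  top_damage <- calls$gene_id[calls$top_damage]
  stress_ids <- calls$gene_id[calls$stress]
  top_stress <- calls$gene_id[calls$top_stress]

  universe <- if (config$universe == "active") active_ids else
    genes$gene_id
  histone_ids <- genes$gene_id[genes$gene_class == "histone"]
  erfs_ids <- if (!is.null(erfs) && length(erfs))
    genes$gene_id[countOverlaps(genes, erfs, ignore.strand = TRUE) > 0]
  else character()

  say("testing overlap and enrichment")
  enrich <- list(
    stress_top_vs_damage_top = overlap_enrichment(top_stress, top_damage,
                                                  universe),
    stress_vs_damage_ks = ks_rank_enrichment(
      setNames(calls$damage_ratio, calls$gene_id), stress_ids),
    histone_vs_damage_top = overlap_enrichment(
      top_damage, intersect(histone_ids, universe), universe),
    erfs_vs_damage_top = if (length(erfs_ids)) overlap_enrichment(
      top_damage, intersect(erfs_ids, universe), universe),
    erfs_vs_stress_top = if (length(erfs_ids)) overlap_enrichment(
      top_stress, intersect(erfs_ids, universe), universe))

  glen <- setNames(width(genes), genes$gene_id)
  rnap <- dens[dens$assay == "RNAPII" & dens$condition == "FF", ]
  rnap <- setNames(rnap$density, rnap$gene_id)
  other_active <- setdiff(active_ids, top_damage)
  enrich$length_damage_vs_active <- location_tests(glen[top_damage],
                                                   glen[other_active])
  enrich$expression_damage_vs_active <- location_tests(rnap[top_damage],
                                                       rnap[other_active])

  say("building metagene profiles")
  tgt <- genes[genes$gene_id %in% top_damage]
  prof_genes <- if (length(tgt)) tgt else genes
  profiles <- list(
    gH2AX_FF = metagene_promoter(track_for(tracks, "gH2AX", "FF"),
                                 prof_genes, span = config$promoter_span),
    gH2AX_FCFC = metagene_promoter(track_for(tracks, "gH2AX", "FCFC"),
                                   prof_genes, span = config$promoter_span),
    RNAPII_FF = metagene_promoter(track_for(tracks, "RNAPII", "FF"),
                                  prof_genes, span = config$promoter_span),
    RNAPII_FCFC = metagene_promoter(track_for(tracks, "RNAPII", "FCFC"),
                                    prof_genes, span = config$promoter_span),
    gH2AX_FCFC_scaled = suppressMessages(
      metagene_scaled(track_for(tracks, "gH2AX", "FCFC"), prof_genes,
                      body_bins = config$body_bins,
                      flank = config$scaled_flank)))

  burden <- NULL
  if (synthetic) {
    say("testing mutation burden")
    burden <- lapply(ds$mutations, function(m) {
      cnt <- count_de_novo(m$baseline, m$endpoint, m$panel)
      list(count = cnt,
           test = burden_test(cnt$k, m$panel, mu = config$mu,
                              g = config$generations))
    })
  } else if (!is.null(config$paths$baseline_vcf)) {
    panel <- mutation_panel(read_intervals(config$paths$panel, layout))
    cnt <- count_de_novo(read_variants(config$paths$baseline_vcf),
                         read_variants(config$paths$endpoint_vcf), panel)
    burden <- list(sample = list(
      count = cnt, test = burden_test(cnt$k, panel, mu = config$mu,
                                      g = config$generations)))
  }

  recovery <- NULL
  if (synthetic) recovery <- truth_recovery(calls, truth)

  smry <- build_summary(config, genes, active_ids, calls, enrich, burden,
                        recovery, glen, top_damage)
  structure(list(config = config, data = ds, genes = genes, layout = layout,
                 densities = dens, ratios = ratios, active = act,
                 calls = calls, enrichment = enrich, profiles = profiles,
                 burden = burden, truth = truth,
                 truth_recovery = recovery, summary = smry),
            class = "stress_scan")
}

# sensitivity/specificity of planted-set recovery; the recovered damage and
# stress sets are the truth-sized top slices of the respective rankings
truth_recovery <- function(calls, truth) {
  tr <- truth[truth$gene_id %in% calls$gene_id, ]
  sens_spec <- function(called, planted) {
    tp <- sum(called & planted); tn <- sum(!called & !planted)
    c(sensitivity = if (sum(planted)) tp / sum(planted) else NA,
      specificity = if (sum(!planted)) tn / sum(!planted) else NA)
  }
  m <- merge(calls, tr, by = "gene_id")
  k_d <- sum(m$damaged)
  dmg_called <- m$damage_rank <= k_d
  k_s <- sum(m$stressed)
  score_rank <- integer(nrow(m))
  score_rank[order(-m$stress_score, m$gene_id)] <- seq_len(nrow(m))
  str_called <- score_rank <= k_s
  list(damage = sens_spec(dmg_called, m$damaged),
       stress = sens_spec(str_called, m$stressed),
       stress_flag = sens_spec(m$stress, m$stressed))
}

build_summary <- function(config, genes, active_ids, calls, enrich, burden,
                          recovery, glen, top_damage) {
  s <- list(
    schema = "stresscan-summary-1",
    parameters = list(
      flank = config$flank, promoter_span = config$promoter_span,
      fraction = config$fraction,
      pseudocount = as.character(config$pseudocount),
      activity_threshold = config$activity_threshold,
      activity_min_total = config$activity_min_total,
      library_norm = config$library_norm, universe = config$universe,
      mu = config$mu, generations = config$generations,
      seed = if (!is.null(config$synthetic)) config$synthetic$seed),
    n_genes = length(genes),
    n_active = length(active_ids),
    top_damage_size = sum(calls$top_damage),
    n_stress = sum(calls$stress),
    top_stress_size = sum(calls$top_stress),
    top_damage_geomean_ratio =
      geometric_mean_ratio(calls$damage_ratio[calls$top_damage]),
    all_active_geomean_ratio = geometric_mean_ratio(calls$damage_ratio),
    stress_top_in_damage_top =
      unname(enrich$stress_top_vs_damage_top$statistic),
    stress_top_overlap_p = enrich$stress_top_vs_damage_top$p.value,
    stress_damage_ks_D = unname(enrich$stress_vs_damage_ks$statistic),
    stress_damage_ks_p = enrich$stress_vs_damage_ks$p.value,
    histone_in_damage_top = unname(enrich$histone_vs_damage_top$statistic),
    histone_overlap_p = enrich$histone_vs_damage_top$p.value,
    median_length_active = unname(median(glen[active_ids])),
    median_length_top_damage = unname(median(glen[top_damage])))
  if (!is.null(enrich$erfs_vs_damage_top)) {
    s$erfs_in_damage_top <- unname(enrich$erfs_vs_damage_top$statistic)
    s$erfs_damage_p <- enrich$erfs_vs_damage_top$p.value
    s$erfs_in_stress_top <- unname(enrich$erfs_vs_stress_top$statistic)
    s$erfs_stress_p <- enrich$erfs_vs_stress_top$p.value
  }
  if (!is.null(burden)) {
    s$burden <- lapply(burden, function(b) list(
      k = unname(b$test$statistic), L = unname(b$test$parameter[["L"]]),
      expected = unname(b$test$estimate[["expected count"]]),
      p = b$test$p.value))
  }
  if (!is.null(recovery)) {
    s$recovery <- lapply(recovery, as.list)
  }
  s
}

#' @export
print.stress_scan <- function(x, ...) {
  s <- x$summary
  cat("<stress_scan>\n")
  cat(sprintf("  genes: %d (%d active)\n", s$n_genes, s$n_active))
  cat(sprintf("  top damage set: %d genes, geometric-mean gH2AX/H3 ratio %.3f\n",
              s$top_damage_size, s$top_damage_geomean_ratio))
  cat(sprintf("  stress genes: %d (top set %d); %d of top stress in top damage (p = %.3g)\n",
              s$n_stress, s$top_stress_size, s$stress_top_in_damage_top,
              s$stress_top_overlap_p))
  cat(sprintf("  KS rank enrichment: D = %.3f, p = %.3g\n",
              s$stress_damage_ks_D, s$stress_damage_ks_p))
  cat(sprintf("  median gene length: top damage %.0f bp vs active %.0f bp\n",
              s$median_length_top_damage, s$median_length_active))
  if (!is.null(s$burden))
    for (nm in names(s$burden))
      cat(sprintf("  burden [%s]: k = %d, expected %.3g, p = %.3g\n", nm,
                  s$burden[[nm]]$k, s$burden[[nm]]$expected,
                  s$burden[[nm]]$p))
  invisible(x)
}

#' @export
summary.stress_scan <- function(object, ...) {
  str(object$summary, give.attr = FALSE)
  invisible(object$summary)
}

#' Write the machine-readable report bundle
#'
#' Persists the density, ratio and call tables (TSV), metagene profiles
#' (TSV) and the JSON summary. Identical config + seed give byte-identical
#' outputs.
#'
#' @param scan a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(scan$densities, "densities.tsv")
  wt(scan$ratios, "ratios.tsv")
  wt(as.data.frame(scan$calls), "calls.tsv")
  for (nm in names(scan$profiles))
    wt(as.data.frame(scan$profiles[[nm]]),
       paste0("profile_", nm, ".tsv"))
  jsonlite::write_json(scan$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
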