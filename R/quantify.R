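#' Mean signal density over gene windows
#'
#' Computes, for each gene, the mean per-bp signal of a track over the
#' gene body extended by `flank` bp each side (clamped at chromosome ends).
#'
#' @param track a [coverage_track()].
#' @param genes GRanges with `gene_id`.
#' @param flank flank in bp (default 500, the standard analysis window).
#' @return Named numeric vector of densities (signal per bp), one per gene.
#' @export
gene_density <- function(track, genes, flank = 500) {
  win <- gene_window(genes, flank, track$layout)
  if (any(width(win) == 0)) stop("zero-length quantification window")
  out <- numeric(length(win))
  for (chrom in as.character(unique(seqnames(win)))) {
    idx <- which(as.character(seqnames(win)) == chrom)
    v <- Views(track$signal[[chrom]],
               start = start(win)[idx], end = end(win)[idx])
    out[idx] <- viewMeans(v)
  }
  names(out) <- genes$gene_id
  out
}

# pick the track for an assay/condition (GRO: sense strand of each gene)
track_for <- function(tracks, assay, condition, strand = "*") {
  for (t in tracks) {
    if (t$assay == assay && t$condition == condition && t$strand == strand)
      return(t)
  }
  stop(sprintf("no track for assay=%s condition=%s strand=%s",
               assay, condition, strand))
}

#' Per-gene density table across assays and conditions
#'
#' For unstranded assays the single track is quantified directly; for the
#' strand-resolved nascent-transcription assay (`"GRO"`) each gene is
#' quantified on its sense strand only.
#'
#' @param tracks list of [coverage_track()] objects covering every
#'   assay/condition (and both strands for stranded assays).
#' @param genes GRanges with `gene_id`.
#' @param flank window flank in bp.
#' @param assays assay labels to quantify (default: all present).
#' @param scale_factors optional named numeric, names
#'   `"<assay>_<condition>"`; densities are multiplied by them (see
#'   [library_scale()]).
#' @return A long-format data.frame: `gene_id`, `assay`, `condition`,
#'   `density`, with attributes `flank` and `scale_factors` recording
#'   provenance.
#' @export
density_table <- function(tracks, genes, flank = 500, assays = NULL,
                          scale_factors = NULL) {
  info <- data.frame(
    assay = vapply(tracks, `[[`, "", "assay"),
    condition = vapply(tracks, `[[`, "", "condition"),
    strand = vapply(tracks, `[[`, "", "strand"))
  if (is.null(assays)) assays <- unique(info$assay)
  conditions <- unique(info$condition)
  out <- list()
  for (assay in assays) {
    stranded <- any(info$assay == assay & info$strand != "*")
    for (cond in conditions) {
      if (stranded) {
        d <- numeric(length(genes))
        for (s in c("+", "-")) {
          idx <- which(as.character(strand(genes)) == s)
          if (!length(idx)) next
          tr <- track_for(tracks, assay, cond, s)
          d[idx] <- unname(gene_density(tr, genes[idx], flank))
        }
        names(d) <- genes$gene_id
      } else {
        d <- gene_density(track_for(tracks, assay, cond), genes, flank)
      }
      if (!is.null(scale_factors)) {
        key <- paste(assay, cond, sep = "_")
        if (!key %in% names(scale_factors))
          stop("missing scale factor for ", key)
        d <- d * scale_factors[[key]]
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = names(d), assay = assay, condition = cond,
        density = unname(d))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "flank") <- flank
  attr(res, "scale_factors") <- scale_factors
  res
}

#' Library-size scaling factors (signal per million)
#'
#' Returns one multiplicative factor per track such that every scaled track
#' has the same genome-wide total signal (`target`, default 1e6).
#'
#' @param tracks named list of [coverage_track()] objects; when unnamed,
#'   names are built as `<assay>_<condition>` (with strand suffix where
#'   applicable, and per-assay/condition totals pool both strands).
#' @param target common total signal after scaling.
#' @return Named numeric vector of factors keyed by `<assay>_<condition>`.
#' @export
library_scale <- function(tracks, target = 1e6) {
  keys <- vapply(tracks, function(t) paste(t$assay, t$condition, sep = "_"), "")
  totals <- tapply(vapply(tracks, track_total, numeric(1)), keys, sum)
  if (any(totals <= 0))
    stop("zero total signal in track(s): ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  setNames(target / as.numeric(totals), names(totals))
}

#' Fold change and H3 normalisation
#'
#' `ratio()` computes `(case + pseudocount) / (control + pseudocount)`.
#' With a zero pseudocount, 0/0 yields `NaN` (flagged, not dropped).
#' `normalize_to_h3()` divides a signal density by the matching histone H3
#' density with the same guard, the normalisation applied to the
#' histone-mark assays before cross-condition ratios.
#'
#' @param case,control non-negative densities (vectorised).
#' @param pseudocount non-negative stabiliser added to both terms.
#' @return Numeric vector of ratios.
#' @export
ratio <- function(case, control, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(case < 0) || any(control < 0)) stop("densities must be >= 0")
  num <- case + pseudocount
  den <- control + pseudocount
  out <- ifelse(num == 0 & den == 0, NaN, num / den)
  if (any(is.nan(out)))
    warning("ratio undefined (0/0 with zero pseudocount) for ",
            sum(is.nan(out)), " entr(y/ies); returned NaN")
  out
}

#' @param signal,h3 densities of the mark of interest and of histone H3.
#' @rdname ratio
#' @export
normalize_to_h3 <- function(signal, h3, pseudocount = 0) {
  ratio(signal, h3, pseudocount)
}

#' Z-score transform
#'
#' Centers and scales with the sample standard deviation. Applied in the
#' pipeline to log2 damage ratios of active genes.
#'
#' @param x numeric vector, `length(x) >= 2`, non-constant.
#' @return Z-scores with mean 0 and sample sd 1.
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("standard deviation is zero")
  (x - mean(x)) / s
}

#' Geometric mean of ratios
#'
#' The summary used for fold-change panels: `exp(mean(log(r)))`.
#'
#' @param r positive ratios.
#' @return The geometric mean.
#' @export
geometric_mean_ratio <- function(r) {
  r <- r[!is.na(r)]
  if (any(r <= 0)) stop("all ratios must be > 0")
  exp(mean(log(r)))
}

#' Per-gene case:control ratio table
#'
#' Builds the four analysis ratios from a [density_table()]:
#' \describe{
#'   \item{gH2AX_H3, H2AX_H3}{H3-normalised within condition, then
#'     case:control (normalisation mode `"to_H3"`).}
#'   \item{RNAPII, GRO}{direct case:control density ratios (mode `"none"`).}
#' }
#' The pseudocount defaults to 1% of the median per-gene density of each
#' assay (pooled over conditions), a scale-free guard against silent genes.
#'
#' @param dens a [density_table()].
#' @param case,control condition labels (case = perturbed).
#' @param pseudocount `"auto"` for the 1%-of-median policy, or a single
#'   non-negative number applied to every assay.
#' @return data.frame `gene_id` x ratio columns, with attributes
#'   `pseudocounts` (per assay) and `normalization` recording provenance.
#' @export
ratio_table <- function(dens, case = "FCFC", control = "FF",
                        pseudocount = "auto") {
  get <- function(assay, cond) {
    sub <- dens[dens$assay == assay & dens$condition == cond, ]
    setNames(sub$density, sub$gene_id)
  }
  assays <- unique(dens$assay)
  eps <- sapply(assays, function(a) {
    if (identical(pseudocount, "auto"))
      0.01 * median(dens$density[dens$assay == a])
    else as.numeric(pseudocount)
  })
  names(eps) <- assays
  ids <- unique(dens$gene_id)
  need <- c("gH2AX", "H2AX", "H3", "RNAPII", "GRO")
  missing <- setdiff(need, assays)
  if (length(missing))
    stop("density table lacks assay(s): ", paste(missing, collapse = ", "))
  h3_case <- get("H3", case)[ids]; h3_ctl <- get("H3", control)[ids]
  norm_ratio <- function(assay) {
    ratio(normalize_to_h3(get(assay, case)[ids], h3_case, eps[["H3"]]),
          normalize_to_h3(get(assay, control)[ids], h3_ctl, eps[["H3"]]),
          pseudocount = 0)
  }
  out <- data.frame(
    gene_id = ids,
    gH2AX_H3 = norm_ratio("gH2AX"),
    H2AX_H3 = norm_ratio("H2AX"),
    RNAPII = ratio(get("RNAPII", case)[ids], get("RNAPII", control)[ids],
                   eps[["RNAPII"]]),
    GRO = ratio(get("GRO", case)[ids], get("GRO", control)[ids],
                eps[["GRO"]]))
  attr(out, "pseudocounts") <- eps
  attr(out, "normalization") <- c(gH2AX_H3 = "to_H3", H2AX_H3 = "to_H3",
                                  RNAPII = "none", GRO = "none")
  attr(out, "conditions") <- c(case = case, control = control)
  out
}

#' Active-gene selection
#'
#' A gene is called transcriptionally active when its control-condition
#' sense-strand nascent-transcription (GRO) density exceeds `threshold`
#' and its window total signal (density x window length) reaches
#' `min_total`. Downstream decile selections operate on active genes only.
#'
#' @param gro_density named control-condition GRO densities (per bp).
#' @param window_length window lengths in bp (recycled if scalar).
#' @param threshold density threshold (default 0: any sense signal).
#' @param min_total minimum window total signal (default 10).
#' @return Named logical vector.
#' @export
active_genes <- function(gro_density, window_length, threshold = 0,
                         min_total = 10) {
  if (threshold < 0) stop("threshold must be >= 0")
  act <- gro_density > threshold & gro_density * window_length >= min_total
  setNames(act, names(gro_density))
}
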