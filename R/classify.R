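#' Top-fraction set size (round half up)
#'
#' The number of genes in a "top decile" selection: `fraction * n`, rounded
#' half up, never less than 1. This rounding reproduces both 414 of 4140 and
#' 216 of 2158.
#'
#' @param n number of eligible genes.
#' @param fraction top fraction (default 0.10).
#' @return Integer set size.
#' @export
decile_size <- function(n, fraction = 0.10) {
  if (n < 1) return(0L)
  if (n < 10) warning("fewer than 10 eligible genes; top set clamped to >= 1")
  max(1L, as.integer(round_half_up(fraction * n)))
}

# deterministic descending order: by score, ties broken by gene_id
order_desc <- function(score, gene_id) order(-score, gene_id)

#' Rank genes by DNA-damage ratio and flag the top decile
#'
#' Sorts active genes by their histone-H3-normalised gamma-H2AX
#' case:control ratio (descending; ties broken lexicographically by gene
#' identifier for reproducibility) and flags the top
#' `round-half-up(fraction * n)` genes as the high-damage set.
#'
#' @param damage_ratio named numeric vector (names = gene ids) of
#'   case:control gamma-H2AX/H3 ratios for active genes.
#' @param fraction top fraction (default 0.10).
#' @param statistic rank by the raw `"ratio"` (default) or by the
#'   `"zscore"` of the log2 ratio (identical ordering; exposed because the
#'   choice is a free parameter of the analysis).
#' @return data.frame `gene_id`, `damage_ratio`, `damage_z` (Z-score of the
#'   log2 ratio), `damage_rank` (1 = most damaged), `top_damage` (logical).
#' @export
damage_rank <- function(damage_ratio, fraction = 0.10,
                        statistic = c("ratio", "zscore")) {
  statistic <- match.arg(statistic)
  if (any(!is.finite(damage_ratio)) || any(damage_ratio <= 0))
    stop("damage ratios must be finite and > 0")
  ids <- names(damage_ratio)
  if (is.null(ids)) stop("damage_ratio must be named by gene_id")
  z <- zscore(log2(damage_ratio))
  score <- if (statistic == "ratio") damage_ratio else z
  ord <- order_desc(score, ids)
  rank <- integer(length(ids)); rank[ord] <- seq_along(ids)
  k <- decile_size(length(ids), fraction)
  data.frame(gene_id = ids, damage_ratio = unname(damage_ratio),
             damage_z = unname(z), damage_rank = rank,
             top_damage = rank <= k, row.names = NULL)
}

#' Transcription-stress call
#'
#' A gene is under transcription stress when chromatin-bound RNAPII
#' increases without a matching increase in nascent transcription:
#' RNAPII case:control ratio strictly greater than 1 AND nascent
#' (GRO) ratio strictly less than 1.
#'
#' @param rnapii_ratio,gro_ratio finite positive case:control ratios.
#' @return Logical vector.
#' @export
stress_call <- function(rnapii_ratio, gro_ratio) {
  if (any(!is.finite(rnapii_ratio)) || any(!is.finite(gro_ratio)))
    stop("ratios must be finite")
  rnapii_ratio > 1 & gro_ratio < 1
}

#' Rank stress genes and flag the top decile
#'
#' Among genes flagged by [stress_call()], ranks by the stress score
#' `rnapii_ratio / gro_ratio` (the degree of RNAPII/nascent-RNA
#' uncoupling, monotone in both defining criteria) and flags the top
#' `round-half-up(fraction * n_stress)` genes.
#'
#' @param rnapii_ratio,gro_ratio named positive ratio vectors (same genes).
#' @param fraction top fraction of stress genes (default 0.10).
#' @return data.frame `gene_id`, `rnapii_ratio`, `gro_ratio`, `stress`
#'   (flag), `stress_score`, `stress_rank` (NA for non-stress genes),
#'   `top_stress`.
#' @export
stress_rank <- function(rnapii_ratio, gro_ratio, fraction = 0.10) {
  ids <- names(rnapii_ratio)
  if (is.null(ids) || !identical(ids, names(gro_ratio)))
    stop("ratio vectors must be named identically by gene_id")
  flag <- stress_call(rnapii_ratio, gro_ratio)
  score <- rnapii_ratio / gro_ratio
  rank <- rep(NA_integer_, length(ids))
  top <- logical(length(ids))
  if (any(flag)) {
    ord <- order_desc(score[flag], ids[flag])
    r <- integer(sum(flag)); r[ord] <- seq_len(sum(flag))
    rank[flag] <- r
    k <- decile_size(sum(flag), fraction)
    top[flag] <- r <= k
  } else {
    message("no transcription-stress genes called")
  }
  data.frame(gene_id = ids, rnapii_ratio = unname(rnapii_ratio),
             gro_ratio = unname(gro_ratio), stress = flag,
             stress_score = unname(score), stress_rank = rank,
             top_stress = top, row.names = NULL)
}

#' Full stress/damage call table for active genes
#'
#' Combines [damage_rank()] and [stress_rank()] on a [ratio_table()]
#' restricted to active genes. The result is invariant to gene input order
#' (rows are returned sorted by gene_id).
#'
#' @param ratios a [ratio_table()].
#' @param active optional character vector of active gene ids (default: all
#'   genes in the table).
#' @param fraction top fraction for both decile sets.
#' @param damage_statistic passed to [damage_rank()].
#' @return data.frame of class `stress_damage_calls` with one row per
#'   active gene: damage ratio/Z/rank/top flag and stress
#'   ratios/flag/score/rank/top flag.
#' @export
classify_stress_damage <- function(ratios, active = NULL, fraction = 0.10,
                                   damage_statistic = "ratio") {
  if (is.null(active)) active <- ratios$gene_id
  sub <- ratios[ratios$gene_id %in% active, ]
  sub <- sub[order(sub$gene_id), ]
  dmg <- damage_rank(setNames(sub$gH2AX_H3, sub$gene_id), fraction,
                     damage_statistic)
  str <- stress_rank(setNames(sub$RNAPII, sub$gene_id),
                     setNames(sub$GRO, sub$gene_id), fraction)
  out <- merge(dmg, str, by = "gene_id", sort = TRUE)
  attr(out, "fraction") <- fraction
  class(out) <- c("stress_damage_calls", "data.frame")
  out
}

#' @export
print.stress_damage_calls <- function(x, ...) {
  cat(sprintf(
    "<stress_damage_calls> %d active genes | top damage: %d | stress: %d | top stress: %d\n",
    nrow(x), sum(x$top_damage), sum(x$stress), sum(x$top_stress)))
  invisible(x)
}
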