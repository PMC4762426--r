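#' Targeted mutation panel
#'
#' A set of genomic intervals targeted by deep sequencing. Overlapping
#' intervals are merged before the panel size `L` is computed, so
#' overlapping amplicons are not double-counted.
#'
#' @param intervals GRanges (or a [read_intervals()] result).
#' @return Object of class `mutation_panel`: merged `intervals` and total
#'   size `L` in bp.
#' @export
mutation_panel <- function(intervals) {
  merged <- reduce(intervals, ignore.strand = TRUE)
  structure(list(intervals = merged, L = sum(width(merged))),
            class = "mutation_panel")
}

#' @export
print.mutation_panel <- function(x, ...) {
  cat(sprintf("<mutation_panel> %d merged interval(s), L = %d bp\n",
              length(x$intervals), x$L))
  invisible(x)
}

#' Read variant calls from a VCF
#'
#' Parses a VCF 4.x file into a minimal call table (one row per ALT
#' allele). Genotype and allele-fraction fields are ignored: the analysis
#' compares presence/absence of mutation events.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return data.frame `chrom`, `pos` (1-based), `ref`, `alt`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n <- lengths(alts)
  data.frame(chrom = rep(fix$CHROM, n), pos = rep(as.integer(fix$POS), n),
             ref = rep(fix$REF, n), alt = unlist(alts),
             stringsAsFactors = FALSE, row.names = NULL)
}

# minimal representation check: a record whose REF and ALT share a common
# trailing (or leading beyond the anchor) base is not normalised
is_minimal <- function(ref, alt) {
  both_long <- nchar(ref) > 1 & nchar(alt) > 1
  last_eq <- substr(ref, nchar(ref), nchar(ref)) ==
    substr(alt, nchar(alt), nchar(alt))
  !(both_long & last_eq)
}

variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Count de novo mutations between two call sets
#'
#' De novo events are endpoint records inside the panel that are absent
#' from the baseline, matched on (chrom, pos, ref, alt). Calls must be in
#' minimal left-aligned representation; records that are detectably
#' unnormalised raise an error.
#'
#' @param baseline,endpoint call tables from [read_variants()] (or
#'   data.frames with the same columns).
#' @param panel a [mutation_panel()].
#' @return List: `k` (de novo count) and `novel` (the de novo records).
#' @export
count_de_novo <- function(baseline, endpoint, panel) {
  for (df in list(baseline, endpoint)) {
    if (nrow(df) && !all(is_minimal(df$ref, df$alt)))
      stop("unnormalised indel representation detected; left-align and trim ",
           "calls (e.g. `bcftools norm`) before comparison")
  }
  in_panel <- function(df) {
    if (!nrow(df)) return(df)
    gr <- GRanges(df$chrom, IRanges(df$pos, df$pos + nchar(df$ref) - 1L))
    df[countOverlaps(gr, panel$intervals) > 0, , drop = FALSE]
  }
  ep <- in_panel(endpoint)
  novel <- ep[!variant_key(ep) %in% variant_key(baseline), , drop = FALSE]
  list(k = nrow(novel), novel = novel)
}

#' Mutation-burden test
#'
#' Tests an observed de novo mutation count against the expectation from a
#' per-site per-generation mutation rate: each of the `L` panel sites
#' mutates with probability `p_site = 1 - (1 - mu)^g` over `g`
#' generations, so the count is Binomial(L, p_site) under the null and the
#' reported p-value is the upper tail `P(X >= k)` (1 when `k = 0`),
#' evaluated in log space for very small tails.
#'
#' @param k observed de novo count (>= 0).
#' @param panel a [mutation_panel()], or a single number taken as `L`.
#' @param mu per-site per-generation mutation rate in `[0, 1]`
#'   (default 6e-8, a standard estimate for cultured mouse cells).
#' @param g number of cell generations (default 45).
#' @return Object of classes `burden_test` and `htest`: `statistic` (k),
#'   `parameter` (L, mu, g), `estimate` (`p_site` and expected count
#'   lambda), `p.value` and `log_p`.
#' @export
burden_test <- function(k, panel, mu = 6e-8, g = 45) {
  L <- if (inherits(panel, "mutation_panel")) panel$L else as.numeric(panel)
  if (k < 0) stop("k must be >= 0")
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  if (g < 0) stop("g must be >= 0")
  if (L < 1) stop("panel size L must be >= 1")
  p_site <- -expm1(g * log1p(-mu))   # 1 - (1 - mu)^g, precise for tiny mu
  lambda <- L * p_site
  p <- if (k == 0) 1 else pbinom(k - 1, L, p_site, lower.tail = FALSE)
  log_p <- if (k == 0) 0 else
    pbinom(k - 1, L, p_site, lower.tail = FALSE, log.p = TRUE)
  structure(list(
    statistic = c(`de novo mutations` = k),
    parameter = c(L = L, mu = mu, g = g),
    estimate = c(p_site = p_site, `expected count` = lambda),
    p.value = p, log_p = log_p,
    alternative = "greater",
    method = "Binomial mutation-burden test, upper tail P(X >= k)",
    data.name = sprintf("%d de novo mutation(s) in %g bp over %g generations",
                        k, L, g)),
    class = c("burden_test", "htest"))
}

#' Write a minimal VCF 4.2 call set
#'
#' @param calls data.frame `chrom`, `pos`, `ref`, `alt`.
#' @param path output path (plain text).
#' @param layout optional [genome_layout()] for contig header lines.
#' @param source free-text provenance string for the header.
#' @export
write_vcf <- function(calls, path, layout = NULL, source = "stresscan") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(paste0("##source=", source), con)
  if (!is.null(layout))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(layout),
                       as.integer(unname(layout))), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(calls)) {
    calls <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt), ]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", calls$chrom,
                       as.integer(calls$pos), calls$ref, calls$alt), con)
  }
  invisible(path)
}
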