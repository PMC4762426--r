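# Metagene profiling: promoter-anchored (TSS +/- span) and scaled-gene-body
# averages over many genes, strand-flipped so downstream is always rightward.

new_metagene_profile <- function(coord, mean, n, anchor, bin_width = NA) {
  structure(data.frame(coord = coord, mean = mean, n = n),
            anchor = anchor, bin_width = bin_width,
            class = c("metagene_profile", "data.frame"))
}

# per-gene window extraction as a numeric vector, NA outside chromosome
extract_signal <- function(rle, chrom_len, from, to) {
  lo <- max(1, from); hi <- min(chrom_len, to)
  v <- rep(NA_real_, to - from + 1)
  if (lo <= hi)
    v[(lo - from + 1):(hi - from + 1)] <-
      as.numeric(S4Vectors::window(rle, lo, hi))
  v
}

#' Promoter-anchored metagene profile
#'
#' Averages a track over all genes in a window centred on the transcription
#' start site (TSS; gene start on plus strand, gene end on minus strand).
#' Minus-strand genes are orientation-flipped before aggregation so positive
#' offsets always point downstream. Genes truncated by a chromosome edge
#' contribute only their covered bins.
#'
#' @param track a [coverage_track()] (for stranded assays pass the sense
#'   track per strand and combine, or use [density_table()] instead).
#' @param genes GRanges with `gene_id`; must be non-empty.
#' @param span half-window in bp (default 2000: TSS +/- 2 kb).
#' @param bin_width bin size in bp; must divide `2 * span`.
#' @return A `metagene_profile` data.frame: `coord` (bin-centre offset from
#'   the TSS, bp), `mean` signal, `n` genes contributing per bin.
#' @export
metagene_promoter <- function(track, genes, span = 2000, bin_width = 50) {
  if (!length(genes)) stop("empty gene set")
  if ((2 * span) %% bin_width != 0)
    stop("bin_width must divide the window span")
  nbins <- (2 * span) %/% bin_width
  acc <- numeric(nbins); cnt <- numeric(nbins)
  minus <- as.character(strand(genes)) == "-"
  tss <- ifelse(minus, end(genes), start(genes))
  chroms <- as.character(seqnames(genes))
  for (i in seq_along(genes)) {
    len <- unname(track$layout[chroms[i]])
    # window placed so the TSS is the first position of the downstream
    # half on both strands after orientation flipping
    from <- tss[i] - span + as.integer(minus[i])
    v <- extract_signal(track$signal[[chroms[i]]], len,
                        from, from + 2 * span - 1)
    if (minus[i]) v <- rev(v)
    m <- matrix(v, nrow = bin_width)
    bm <- colMeans(m)                      # NA where bin partly off-chromosome
    ok <- !is.na(bm)
    acc[ok] <- acc[ok] + bm[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  if (any(cnt == 0)) warning("bins with no covered genes read as NA")
  new_metagene_profile(
    coord = seq(-span, span - bin_width, by = bin_width) + bin_width / 2,
    mean = ifelse(cnt > 0, acc / cnt, NA_real_), n = cnt,
    anchor = "TSS", bin_width = bin_width)
}

#' Scaled gene-body metagene profile
#'
#' Rescales every gene body to a fixed number of bins, with fixed-width
#' flanks upstream of the TSS and downstream of the transcription
#' termination site, and averages a track across genes (strand-flipped).
#' Genes shorter than `min_length` are skipped with a message.
#'
#' @inheritParams metagene_promoter
#' @param body_bins number of bins the gene body is rescaled to.
#' @param flank flank size in bp on each side.
#' @param flank_bin_width bin size within the flanks; must divide `flank`.
#' @param min_length minimum gene length in bp (default `body_bins`, one bp
#'   per bin).
#' @return A `metagene_profile`; `coord` is the bin index, negative in the
#'   upstream flank, `1..body_bins` over the body (percent-like scale),
#'   and `> body_bins` downstream.
#' @export
metagene_scaled <- function(track, genes, body_bins = 100, flank = 500,
                            flank_bin_width = 50, min_length = body_bins) {
  if (!length(genes)) stop("empty gene set")
  if (flank %% flank_bin_width != 0)
    stop("flank_bin_width must divide flank")
  short <- width(genes) < min_length
  if (any(short)) {
    message(sum(short), " gene(s) shorter than ", min_length, " bp skipped")
    genes <- genes[!short]
  }
  if (!length(genes)) stop("all genes below minimum length")
  fbins <- flank %/% flank_bin_width
  nbins <- body_bins + 2 * fbins
  acc <- numeric(nbins); cnt <- numeric(nbins)
  minus <- as.character(strand(genes)) == "-"
  chroms <- as.character(seqnames(genes))
  for (i in seq_along(genes)) {
    len <- unname(track$layout[chroms[i]])
    v <- extract_signal(track$signal[[chroms[i]]], len,
                        start(genes)[i] - flank, end(genes)[i] + flank)
    if (minus[i]) v <- rev(v)
    w <- length(v) - 2 * flank            # gene length
    up <- colMeans(matrix(v[seq_len(flank)], nrow = flank_bin_width))
    dn <- colMeans(matrix(v[(length(v) - flank + 1):length(v)],
                          nrow = flank_bin_width))
    body <- v[(flank + 1):(flank + w)]
    # near-equal partition of the body into body_bins segments
    bounds <- round(seq(0, w, length.out = body_bins + 1))
    cs <- c(0, cumsum(ifelse(is.na(body), 0, body)))
    nn <- c(0, cumsum(!is.na(body)))
    seg_n <- nn[bounds[-1] + 1] - nn[bounds[-length(bounds)] + 1]
    seg_sum <- cs[bounds[-1] + 1] - cs[bounds[-length(bounds)] + 1]
    bmean <- c(up, ifelse(seg_n > 0, seg_sum / seg_n, NA_real_), dn)
    ok <- !is.na(bmean)
    acc[ok] <- acc[ok] + bmean[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  new_metagene_profile(
    coord = c(seq(-fbins, -1), seq_len(body_bins),
              body_bins + seq_len(fbins)),
    mean = ifelse(cnt > 0, acc / cnt, NA_real_), n = cnt,
    anchor = "scaled_body", bin_width = NA)
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> anchor=%s, %d bins, %d gene(s)\n",
              attr(x, "anchor"), nrow(x), max(x$n)))
  invisible(x)
}

#' Plot a metagene profile
#'
#' @param x a `metagene_profile`.
#' @param y optionally a second profile drawn for comparison (dashed).
#' @param ... passed to [graphics::plot()].
#' @export
plot.metagene_profile <- function(x, y = NULL, ...) {
  args <- list(...)
  if (is.null(args$type)) args$type <- "l"
  if (is.null(args$xlab))
    args$xlab <- if (attr(x, "anchor") == "TSS")
      "distance from TSS (bp)" else "scaled gene-body bin"
  if (is.null(args$ylab)) args$ylab <- "mean signal"
  do.call(plot, c(list(x = x$coord, y = x$mean), args))
  if (!is.null(y)) graphics::lines(y$coord, y$mean, lty = 2)
  invisible(x)
}
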