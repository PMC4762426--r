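#' Genome layout
#'
#' A minimal description of the reference the tracks and annotations live on:
#' chromosome names and lengths. All readers clamp and validate against it.
#'
#' @param chroms character vector of unique chromosome names.
#' @param lengths integer vector of chromosome lengths in bp, all > 0.
#' @return A named numeric vector of class `genome_layout`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("chroms and lengths must have equal length")
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive")
  structure(setNames(lengths, chroms), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x), " chromosome(s), ",
      format(sum(x), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Read / write a two-column chrom-sizes file
#'
#' @param path file path; tab- or space-separated `name length` lines.
#' @return [read_chrom_sizes()] returns a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  genome_layout(tab$chrom, tab$length)
}

#' @param layout a [genome_layout()].
#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(layout, path) {
  writeLines(paste(names(layout), format(unname(layout), scientific = FALSE,
                                         trim = TRUE), sep = "\t"), path)
  invisible(path)
}

as_seqinfo <- function(layout) {
  Seqinfo(seqnames = names(layout), seqlengths = as.integer(unname(layout)))
}

# Pre-scan a BED-like file so parse errors can name the offending line.
# Returns indices of data lines (skipping comments/track/browser lines).
scan_bed_lines <- function(path, min_fields) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < min_fields)
      stop(sprintf("%s: line %d: expected >= %d fields, found %d",
                   path, i, min_fields, length(f)))
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("%s: line %d: start/end not numeric", path, i))
    if (e <= s)
      stop(sprintf("%s: line %d: end (%s) <= start (%s)", path, i, f[3], f[2]))
    if (min_fields >= 6 && !(f[6] %in% c("+", "-")))
      stop(sprintf("%s: line %d: strand must be + or -, found '%s'",
                   path, i, f[6]))
  }
  invisible(TRUE)
}

#' Read gene models from BED6 or GTF
#'
#' BED input is 0-based half-open, GTF 1-based inclusive; both are converted
#' to the in-memory GRanges convention on read. For GTF, rows with
#' `type == "gene"` are used when present (all rows otherwise).
#'
#' @param path path to a BED6 or GTF/GFF file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @param layout optional [genome_layout()]; when supplied, seqlengths are set
#'   and out-of-bounds genes raise an error.
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id` and
#'   `gene_class` (empty string when unclassified), in file order.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gtf"), layout = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  if (format == "bed") {
    scan_bed_lines(path, min_fields = 6)
    gr <- rtracklayer::import(path, format = "BED")
    mcols(gr) <- S4Vectors::DataFrame(gene_id = gr$name)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    if ("type" %in% names(mcols(gr)) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    ids <- if ("gene_id" %in% names(mcols(gr))) gr$gene_id else
      paste0("gene", seq_along(gr))
    mcols(gr) <- S4Vectors::DataFrame(gene_id = ids)
  }
  gr$gene_class <- ""
  if (!all(as.character(strand(gr)) %in% c("+", "-")))
    stop("all gene models must carry an explicit +/- strand")
  if (!is.null(layout)) {
    bad <- setdiff(as.character(unique(seqnames(gr))), names(layout))
    if (length(bad))
      stop("chromosomes absent from layout: ", paste(bad, collapse = ", "))
    seqlevels(gr) <- names(layout)
    seqinfo(gr) <- as_seqinfo(layout)
    oob <- end(gr) > seqlengths(gr)[as.character(seqnames(gr))]
    if (any(oob))
      stop("gene(s) extend beyond chromosome end: ",
           paste(head(gr$gene_id[oob]), collapse = ", "))
  }
  gr
}

#' Write gene models as BED6
#'
#' @param genes GRanges with a `gene_id` metadata column.
#' @param path output path.
#' @param header optional comment line(s) written before the records.
#' @export
write_genes <- function(genes, path, header = NULL) {
  df <- data.frame(chrom = as.character(seqnames(genes)),
                   start = start(genes) - 1L, end = end(genes),
                   name = genes$gene_id, score = 0L,
                   strand = as.character(strand(genes)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write an interval set (BED3+)
#'
#' Used for fragile-site interval lists and targeted-panel regions.
#'
#' @param path BED file path (0-based half-open; converted on read).
#' @param layout optional [genome_layout()] for bounds checking.
#' @return GRanges (unstranded).
#' @export
read_intervals <- function(path, layout = NULL) {
  scan_bed_lines(path, min_fields = 3)
  gr <- rtracklayer::import(path, format = "BED")
  strand(gr) <- "*"
  mcols(gr) <- NULL
  if (!is.null(layout)) {
    seqlevels(gr) <- union(names(layout), seqlevels(gr))
    seqinfo(gr) <- as_seqinfo(layout)
  }
  gr
}

#' @param intervals GRanges.
#' @param header optional comment line written first.
#' @rdname read_intervals
#' @export
write_intervals <- function(intervals, path, header = NULL) {
  df <- data.frame(chrom = as.character(seqnames(intervals)),
                   start = start(intervals) - 1L, end = end(intervals))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coverage track
#'
#' A piecewise-constant, non-negative signal over a genome, for one assay in
#' one condition. Backed by a per-chromosome run-length encoding
#' ([S4Vectors::Rle]); positions not covered by any interval read as 0.
#'
#' @param signal an `RleList` (one Rle per chromosome, lengths matching the
#'   layout) or a GRanges with a `score` column.
#' @param layout a [genome_layout()].
#' @param assay assay label, e.g. `"gH2AX"`, `"H3"`, `"RNAPII"`, `"GRO"`.
#' @param condition condition label, e.g. `"FF"` (control) or `"FCFC"`.
#' @param strand `"*"` for unstranded ChIP tracks; `"+"`/`"-"` for
#'   strand-resolved nascent-transcription tracks.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(signal, layout, assay, condition, strand = "*") {
  if (methods::is(signal, "GRanges")) {
    if (!IRanges::isDisjoint(signal))
      stop("coverage intervals overlap; bedGraph intervals must be disjoint")
    if (any(signal$score < 0)) stop("coverage values must be >= 0")
    seqlevels(signal) <- names(layout)
    seqinfo(signal) <- as_seqinfo(layout)
    signal <- coverage(signal, weight = "score")
  }
  if (!setequal(names(signal), names(layout)))
    signal <- signal[names(layout)]
  stopifnot(strand %in% c("*", "+", "-"))
  structure(list(signal = signal, layout = layout, assay = assay,
                 condition = condition, strand = strand),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s / %s (strand %s), %d chromosome(s), total signal %.4g\n",
              x$assay, x$condition, x$strand, length(x$signal),
              track_total(x)))
  invisible(x)
}

track_total <- function(track) sum(vapply(track$signal, sum, numeric(1)))

#' Read a bedGraph coverage file
#'
#' bedGraph is 0-based half-open; intervals must be non-overlapping and
#' non-negative. Regions not listed read as 0 signal.
#'
#' @inheritParams coverage_track
#' @param path bedGraph file path.
#' @return A [coverage_track()].
#' @export
read_coverage <- function(path, layout, assay = "signal",
                          condition = "cond", strand = "*") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  bad <- setdiff(as.character(unique(seqnames(gr))), names(layout))
  if (length(bad))
    stop("chromosomes absent from layout: ", paste(bad, collapse = ", "))
  coverage_track(gr, layout, assay, condition, strand)
}

#' Write a coverage track as bedGraph
#'
#' Zero-signal runs are omitted (absent coverage reads as 0 on re-import).
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @param header optional comment line written before the records.
#' @export
write_coverage <- function(track, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  for (chrom in names(track$signal)) {
    r <- track$signal[[chrom]]
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r)      # 0-based starts
    vals <- runValue(r)
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom,
                       as.integer(starts[keep]), as.integer(ends[keep]),
                       vals[keep]), con)
  }
  invisible(path)
}

#' Gene-body window with flanks
#'
#' Extends each gene by `flank` bp on both sides and clamps the result to the
#' chromosome bounds. The default analysis window is the gene body +/- 500 bp.
#'
#' @param genes GRanges.
#' @param flank non-negative flank size in bp.
#' @param layout a [genome_layout()].
#' @return GRanges of the same length, clamped windows.
#' @export
gene_window <- function(genes, flank, layout) {
  if (flank < 0) stop("flank must be >= 0")
  lens <- unname(layout[as.character(seqnames(genes))])
  if (any(is.na(lens)))
    stop("gene chromosome(s) missing from layout")
  gr <- genes
  GenomicRanges::ranges(gr) <- IRanges(
    start = pmax(1, start(genes) - flank),
    end = pmin(lens, end(genes) + flank))
  gr
}
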