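# Shared fixtures: small genomes, tracks and configs built in code.

tiny_layout <- function() genome_layout(c("chr1", "chr2"), c(1e5, 8e4))

# a coverage track from explicit (chrom, start0, end0, value) pieces
track_from_pieces <- function(pieces, layout = tiny_layout(),
                              assay = "signal", condition = "FF",
                              strand = "*") {
  gr <- GenomicRanges::GRanges(
    pieces$chrom,
    IRanges::IRanges(start = pieces$start + 1L, end = pieces$end))
  gr$score <- pieces$value
  coverage_track(gr, layout, assay, condition, strand)
}

uniform_track <- function(value, layout = tiny_layout(), assay = "signal",
                          condition = "FF", strand = "*") {
  pieces <- data.frame(chrom = names(layout), start = 0,
                       end = unname(layout), value = value)
  track_from_pieces(pieces, layout, assay, condition, strand)
}

genes_gr <- function(chrom, start1, end1, strand = "+",
                     id = sprintf("g%03d", seq_along(start1)),
                     layout = tiny_layout()) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1),
                         strand = strand, gene_id = id, gene_class = "",
                         seqinfo = stresscan:::as_seqinfo(layout))
}

small_config <- function(seed = 42, n_genes = 120, noise = TRUE,
                         fraction_histone = 0.05, panel_n_histone = 4,
                         panel_n_other = 1, ...) {
  synthetic_config(seed = seed, n_chroms = 2, chrom_length = 2e6,
                   n_genes = n_genes, noise = noise,
                   fraction_histone = fraction_histone,
                   panel_n_histone = panel_n_histone,
                   panel_n_other = panel_n_other, ...)
}
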