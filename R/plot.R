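#' Plot a stress/damage scan
#'
#' Draws the damage Z-scores of all active genes in rank order, with the
#' top-stress genes highlighted — the standard way to visualise how the
#' transcription-stress set concentrates at the damaged end of the genome.
#'
#' @param x a [run_pipeline()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stress_scan <- function(x, ...) {
  calls <- x$calls
  ord <- order(calls$damage_rank)
  z <- calls$damage_z[ord]
  top_stress <- calls$top_stress[ord]
  args <- list(...)
  if (is.null(args$xlab)) args$xlab <- "genes ranked by gamma-H2AX damage"
  if (is.null(args$ylab)) args$ylab <- "damage Z-score (log2 ratio)"
  if (is.null(args$col)) args$col <- "firebrick"
  if (is.null(args$type)) args$type <- "l"
  do.call(plot, c(list(x = seq_along(z), y = z), args))
  graphics::rug(which(top_stress), col = "steelblue")
  graphics::legend("topright", bty = "n",
                   legend = c("active genes", "top transcription stress"),
                   col = c("firebrick", "steelblue"),
                   lty = c(1, 1))
  invisible(x)
}
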