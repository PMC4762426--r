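#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the number of category members in a draw of `n` from a
#' universe of `N` containing `K` category members. Evaluated in log space
#' (stable far below 1e-300 when `log.p = TRUE`); `k = 0` gives exactly 1.
#'
#' @param N universe size.
#' @param K category size within the universe.
#' @param n draw size.
#' @param k observed overlap.
#' @param log.p return the natural log of the tail probability.
#' @return The tail probability (or its log).
#' @export
hypergeom_sf <- function(N, K, n, k, log.p = FALSE) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0,
            K <= N, n <= N,
            N == round(N), K == round(K), n == round(n), k == round(k))
  if (k > min(n, K))
    stop("impossible overlap: k exceeds min(n, K); P(X >= k) would be 0")
  if (k == 0) return(if (log.p) 0 else 1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = log.p)
}

#' Gene-set overlap enrichment (hypergeometric test)
#'
#' Tests whether the overlap of two gene sets drawn from a common universe
#' exceeds the hypergeometric expectation `n * K / N`.
#'
#' @param setA,setB character vectors of gene ids; must be subsets of
#'   `universe`.
#' @param universe character vector, the eligible genes (the analysis uses
#'   the active-gene set by default).
#' @return An object of classes `overlap_test` and `htest` with the four
#'   hypergeometric parameters (`N`, `K`, `n`, `k`), `expected`, fold
#'   `estimate`, `p.value` and `log_p`.
#' @export
overlap_enrichment <- function(setA, setB, universe) {
  universe <- unique(universe)
  offA <- setdiff(setA, universe); offB <- setdiff(setB, universe)
  if (length(offA) || length(offB))
    stop("set members outside the universe: ",
         paste(head(c(offA, offB), 5), collapse = ", "))
  setA <- unique(setA); setB <- unique(setB)
  N <- length(universe); K <- length(setB); n <- length(setA)
  k <- length(intersect(setA, setB))
  expected <- n * K / N
  structure(list(
    statistic = c(overlap = k),
    parameter = c(N = N, K = K, n = n),
    expected = expected,
    estimate = c(`fold enrichment` = if (expected > 0) k / expected else NA),
    p.value = hypergeom_sf(N, K, n, k),
    log_p = hypergeom_sf(N, K, n, k, log.p = TRUE),
    alternative = "greater",
    method = "Hypergeometric gene-set overlap test (upper tail, P(X >= k))",
    data.name = sprintf("overlap of %d- and %d-gene sets in a %d-gene universe",
                        n, K, N)),
    class = c("overlap_test", "htest"))
}

#' Rank enrichment of a gene subset (two-sample Kolmogorov-Smirnov)
#'
#' Compares the score distribution of a gene subset against its complement
#' with the two-sample KS statistic `D = sup |ECDF difference|`. The
#' default p-value is the asymptotic one (effective size `mn/(m+n)`),
#' appropriate at genome scale; `exact = TRUE` is available for small sets.
#'
#' @param scores named numeric vector of per-gene scores (e.g. damage
#'   ratios) for the whole universe.
#' @param subset character vector of gene ids, a proper non-empty subset of
#'   `names(scores)`.
#' @param exact logical passed to [stats::ks.test()] (default FALSE:
#'   asymptotic p).
#' @return Object of classes `ks_enrichment` and `htest` with `statistic`
#'   (D), `p.value`, and the subset/complement sizes in `parameter`.
#' @export
ks_rank_enrichment <- function(scores, subset, exact = FALSE) {
  ids <- names(scores)
  if (is.null(ids)) stop("scores must be named by gene_id")
  bad <- setdiff(subset, ids)
  if (length(bad))
    stop("subset members without scores: ", paste(head(bad, 5), collapse = ", "))
  inset <- ids %in% subset
  if (!any(inset) || all(inset))
    stop("both the subset and its complement must be non-empty")
  kt <- suppressWarnings(
    ks.test(scores[inset], scores[!inset], exact = exact))
  structure(list(
    statistic = kt$statistic,
    parameter = c(m = sum(inset), n = sum(!inset)),
    p.value = kt$p.value,
    alternative = "two-sided",
    method = "Two-sample Kolmogorov-Smirnov rank enrichment",
    data.name = sprintf("%d-gene subset vs %d-gene complement",
                        sum(inset), sum(!inset))),
    class = c("ks_enrichment", "htest"))
}

#' Location tests for gene properties
#'
#' Runs both tests the analysis reports for group comparisons of gene
#' properties (length, expression): the Mann-Whitney U test (exact for
#' small samples without ties, normal approximation with tie correction
#' otherwise — [stats::wilcox.test()] semantics) and the Welch t-test.
#'
#' @param a,b numeric samples.
#' @return List of class `location_tests` with elements `wilcox` and `t`
#'   (both `htest`).
#' @export
location_tests <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  w <- suppressWarnings(wilcox.test(a, b))
  tt <- tryCatch(t.test(a, b),
                 error = function(e)
                   stop("t-test degenerate (constant data); ",
                        "use the Mann-Whitney result", call. = FALSE))
  structure(list(wilcox = w, t = tt), class = "location_tests")
}

#' @export
print.location_tests <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.3g | Welch t = %.3g, p = %.3g\n",
              x$wilcox$statistic, x$wilcox$p.value,
              x$t$statistic, x$t$p.value))
  invisible(x)
}
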