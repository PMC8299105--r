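#' Pairwise association measures for abundance vectors
#'
#' The five measures the ensemble network combines: Pearson and Spearman
#' correlation, Bray-Curtis dissimilarity, symmetrised Kullback-Leibler
#' divergence (with pseudocount), and equal-frequency-binned mutual
#' information (nats). Each returns `NA` when the measure is undefined
#' (constant input for the correlations); all are symmetric in `x` and `y`.
#'
#' @param x,y equal-length numeric vectors (non-negative for the
#'   dissimilarities).
#' @param pseudocount added to every entry before normalisation for the KL
#'   divergence (default 1).
#' @param bins number of equal-frequency bins for mutual information;
#'   default `mi_default_bins(length(x))`.
#' @return A scalar score (`NA` if undefined).
#' @name pair_measures
NULL

measure_names <- c("pearson", "spearman", "bray_curtis",
                   "kullback_leibler", "mutual_information")

#' @rdname pair_measures
#' @export
pair_pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' @rdname pair_measures
#' @export
pair_spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' @rdname pair_measures
#' @export
pair_bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  den <- sum(x) + sum(y)
  if (den == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / den
}

#' @rdname pair_measures
#' @export
pair_kl <- function(x, y, pseudocount = 1) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  p <- x + pseudocount; q <- y + pseudocount
  if (sum(p) == 0 || sum(q) == 0) stop("zero-sum vector after pseudocount")
  p <- p / sum(p); q <- q / sum(q)
  if (any(p == 0) || any(q == 0))
    stop("zero probabilities; use a positive pseudocount")
  sum((p - q) * (log(p) - log(q)))
}

#' Default number of mutual-information bins
#'
#' ceiling(sqrt(n)) capped at 10 equal-frequency bins.
#' @param n sample size.
#' @export
mi_default_bins <- function(n) min(10L, max(2L, ceiling(sqrt(n))))

# equal-frequency bin codes with tie-collapsing quantile breaks: break
# points sit at the sorted positions t*n/bins and equal values always share
# a bin (zero-heavy count vectors put all zeros in one bin; a constant
# vector collapses to a single bin with zero entropy)
equal_freq_codes <- function(x, bins) {
  n <- length(x)
  s <- sort(x)
  breaks <- s[pmax(1L, floor(seq_len(bins - 1L) * n / bins) + 1L)]
  codes <- integer(n)
  for (b in breaks) codes <- codes + (x >= b)
  codes
}

#' @rdname pair_measures
#' @export
pair_mutual_info <- function(x, y, bins = mi_default_bins(length(x))) {
  stopifnot(length(x) == length(y))
  if (bins < 2L) stop("bins must be >= 2")
  if (length(x) < bins) stop("need at least `bins` observations")
  n <- length(x)
  cx <- equal_freq_codes(x, bins)
  cy <- equal_freq_codes(y, bins)
  joint <- table(factor(cx, levels = 0:(bins - 1L)),
                 factor(cy, levels = 0:(bins - 1L)))
  p <- joint / n
  px <- rowSums(p); py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / outer(px, py)[pos]))
}

measure_fun <- function(measure, mi_bins = NULL, kl_pseudocount = 1) {
  switch(measure,
         pearson = pair_pearson,
         spearman = pair_spearman,
         bray_curtis = pair_bray_curtis,
         kullback_leibler = function(x, y) pair_kl(x, y, kl_pseudocount),
         mutual_information = function(x, y) {
           b <- if (is.null(mi_bins)) mi_default_bins(length(x)) else mi_bins
           pair_mutual_info(x, y, b)
         },
         stop("unknown measure: ", measure))
}

is_dissimilarity <- function(measure)
  measure %in% c("bray_curtis", "kullback_leibler")
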