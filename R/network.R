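#' Configuration for ensemble network inference
#'
#' Defaults follow the published procedure: all five association measures,
#' 1,000 permutations and bootstraps, support from at least two measures,
#' Brown-merged p-values adjusted by Benjamini-Hochberg at alpha = 0.001.
#'
#' @param measures subset of `c("pearson","spearman","bray_curtis",
#'   "kullback_leibler","mutual_information")`.
#' @param n_permutations,n_bootstraps permutation/bootstrap replicates.
#' @param min_support measures that must independently support an edge.
#' @param alpha significance level on the BH-adjusted merged p.
#' @param measure_support_p raw per-measure p counting as support.
#' @param mi_bins mutual-information bins (`NULL` = ceiling(sqrt(n)) capped
#'   at 10).
#' @param kl_pseudocount pseudocount for the KL divergence.
#' @param min_consensus_score optional minimum absolute correlation-family
#'   score for an edge (`NULL` = off).
#' @param p_method how per-measure permutation p-values are computed.
#'   `"pooled"` (default) standardizes every pair's null scores by that
#'   pair's null mean and sd and pools the standardized deviations across
#'   all pairs, so each p-value is an empirical tail probability with
#'   resolution 1/(pairs x permutations) rather than 1/permutations --
#'   the pooled-null device that lets permutation p-values survive deep
#'   multiple-testing correction while keeping the (possibly heavy) tail of
#'   the null estimated from the data itself; `"empirical"` uses the
#'   per-pair count-based p, floored at 1/(permutations+1); `"gaussian"`
#'   uses a normal tail on the per-pair z-score.
#' @param filter_input apply [prevalence_filter()] internally.
#' @param min_occurrence,min_total_reads prevalence-filter thresholds.
#' @param seed integer seed for permutations and bootstraps.
#' @return A `network_config` list.
#' @export
network_config <- function(measures = measure_names,
                           n_permutations = 1000L, n_bootstraps = 1000L,
                           min_support = 2L, alpha = 0.001,
                           measure_support_p = 0.05, mi_bins = NULL,
                           kl_pseudocount = 1, min_consensus_score = NULL,
                           p_method = c("pooled", "empirical", "gaussian"),
                           filter_input = TRUE, min_occurrence = 4L,
                           min_total_reads = 10L, seed = 1L) {
  measures <- match.arg(measures, measure_names, several.ok = TRUE)
  p_method <- match.arg(p_method)
  stopifnot(min_support >= 1, alpha > 0, alpha < 1,
            n_permutations >= 1, n_bootstraps >= 1,
            measure_support_p > 0, measure_support_p < 1)
  structure(list(measures = measures,
                 n_permutations = as.integer(n_permutations),
                 n_bootstraps = as.integer(n_bootstraps),
                 min_support = as.integer(min_support), alpha = alpha,
                 measure_support_p = measure_support_p, mi_bins = mi_bins,
                 kl_pseudocount = kl_pseudocount,
                 min_consensus_score = min_consensus_score,
                 p_method = p_method,
                 filter_input = filter_input,
                 min_occurrence = as.integer(min_occurrence),
                 min_total_reads = as.integer(min_total_reads),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()]).
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values), all(p_values >= 0 & p_values <= 1,
                                      na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Brown's combination of dependent p-values
#'
#' Extends Fisher's method to dependent tests: with psi = -2 sum(log p),
#' E = 2k and V = sum of the covariance matrix of the -2 log p statistics,
#' the merged p is the upper tail of a scaled chi-square with scale
#' `c = V/(2E)` and degrees of freedom `f = 2E^2/V`. A diagonal covariance
#' (all 4) recovers Fisher's method exactly.
#'
#' @param p_values vector of k raw p-values in (0, 1].
#' @param covariance k x k covariance of the -2 log p statistics (diagonal
#'   4, the variance of -2 log U); defaults to independence.
#' @return The merged p-value.
#' @export
brown_merge <- function(p_values, covariance = NULL) {
  k <- length(p_values)
  stopifnot(k >= 1, is.numeric(p_values))
  if (any(p_values > 1 | p_values < 0))
    stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("p-value of 0 clamped to machine minimum")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  if (is.null(covariance)) covariance <- diag(4, k)
  covariance <- as.matrix(covariance)
  stopifnot(nrow(covariance) == k, ncol(covariance) == k)
  psi <- -2 * sum(log(p_values))
  E <- 2 * k
  V <- sum(covariance)
  if (!is.finite(V) || V <= 0) V <- 4 * k  # fall back to independence
  cc <- V / (2 * E)
  f <- 2 * E^2 / V
  stats::pchisq(psi / cc, df = f, lower.tail = FALSE)
}

#' Estimate the covariance of -2 log p statistics from shared nulls
#'
#' Given null score matrices from the same permutation replicates (one
#' column per measure), each replicate's pseudo p-value is its
#' extremeness rank within that measure's null distribution; the returned
#' matrix is the empirical covariance of the -2 log pseudo-p statistics
#' with the diagonal rescaled to 4 (preserving correlations).
#'
#' @param null_scores numeric matrix, permutations x measures.
#' @return Symmetric covariance matrix with diagonal 4.
#' @export
estimate_p_covariance <- function(null_scores) {
  null_scores <- as.matrix(null_scores)
  B <- nrow(null_scores); k <- ncol(null_scores)
  if (B < 30L) stop("need at least 30 permutations for a stable estimate")
  tmat <- matrix(NA_real_, B, k)
  for (m in seq_len(k)) {
    e <- abs(null_scores[, m] - mean(null_scores[, m]))
    es <- sort(e)
    nless <- findInterval(e, es, left.open = TRUE)  # strictly smaller
    tmat[, m] <- -2 * log((B - nless) / B)
  }
  C <- stats::cov(tmat)
  v <- diag(C)
  out <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) out[a, b] <- 4
    else if (v[a] > 0 && v[b] > 0)
      out[a, b] <- 4 * C[a, b] / sqrt(v[a] * v[b])
  }
  out
}

# shared internal: observed + permutation-null scores of one measure
null_scores_for <- function(x, y, measure, perms, mi_bins = NULL,
                            kl_pseudocount = 1) {
  f <- measure_fun(measure, mi_bins, kl_pseudocount)
  obs <- f(x, y)
  nul <- apply(perms, 1L, function(ix) f(x, y[ix]))
  list(observed = obs, null = nul)
}

perm_matrix <- function(n, B) {
  t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
}

measure_direction <- function(measure, obs, null_mean, x = NULL, y = NULL) {
  if (is.na(obs)) return(NA_character_)
  if (measure %in% c("pearson", "spearman"))
    return(if (obs >= 0) "positive" else "negative")
  if (is_dissimilarity(measure))
    return(if (obs < null_mean) "positive" else "negative")
  # mutual information is sign-blind: borrow the rank-correlation sign
  s <- if (!is.null(x)) pair_spearman(x, y) else NA_real_
  if (is.na(s)) "positive" else if (s >= 0) "positive" else "negative"
}

#' Permutation p-value for one association measure
#'
#' Null scores come from shuffling the sample order of `y`;
#' p = (1 + number of null scores at least as extreme as observed) /
#' (n_permutations + 1), where extremeness is the absolute deviation from
#' the null mean. Direction is positive when the observed score indicates
#' co-presence (positive correlation, or dissimilarity below the null mean).
#'
#' @param x,y abundance vectors.
#' @param measure one of the five measure names.
#' @param n_permutations replicates (default 1000).
#' @param seed integer seed.
#' @param mi_bins,kl_pseudocount measure parameters.
#' @return list with `p`, `direction`, `observed`, `null_mean`.
#' @export
permutation_pvalue <- function(x, y, measure, n_permutations = 1000L,
                               seed = 1L, mi_bins = NULL,
                               kl_pseudocount = 1) {
  measure <- match.arg(measure, measure_names)
  set.seed(as.integer(seed))
  perms <- perm_matrix(length(x), n_permutations)
  ns <- null_scores_for(x, y, measure, perms, mi_bins, kl_pseudocount)
  if (is.na(ns$observed))
    return(list(p = NA_real_, direction = NA_character_,
                observed = NA_real_, null_mean = NA_real_))
  nm <- mean(ns$null)
  e <- abs(ns$null - nm)
  p <- (1 + sum(e >= abs(ns$observed - nm))) / (n_permutations + 1)
  list(p = p,
       direction = measure_direction(measure, ns$observed, nm, x, y),
       observed = ns$observed, null_mean = nm)
}

#' Bootstrap stability of one association
#'
#' Resamples the samples with replacement and declares the association
#' stable when the central 95% percentile interval of the bootstrap scores
#' excludes the permutation-null mean score. Degenerate resamples (constant
#' vectors) are skipped; more than 50% degenerate means unstable.
#'
#' @inheritParams permutation_pvalue
#' @param n_bootstraps bootstrap replicates.
#' @param null_mean the permutation-null mean score of the measure.
#' @return logical: stable or not.
#' @export
bootstrap_stability <- function(x, y, measure, n_bootstraps = 1000L,
                                null_mean = 0, seed = 1L, mi_bins = NULL,
                                kl_pseudocount = 1) {
  measure <- match.arg(measure, measure_names)
  f <- measure_fun(measure, mi_bins, kl_pseudocount)
  set.seed(as.integer(seed))
  n <- length(x)
  sc <- vapply(seq_len(n_bootstraps), function(b) {
    ix <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(f(x[ix], y[ix]), error = function(e) NA_real_)
    if (is.finite(v)) v else NA_real_
  }, numeric(1L))
  stable_from_scores(sc, null_mean)
}

stable_from_scores <- function(scores, null_mean) {
  fin <- is.finite(scores)
  if (mean(!fin) > 0.5) return(FALSE)
  ci <- stats::quantile(scores[fin], c(0.025, 0.975), type = 7, names = FALSE)
  null_mean < ci[1L] || null_mean > ci[2L]
}

cov15_expand <- function(row15) {
  C <- matrix(NA_real_, 5L, 5L)
  c <- 1L
  for (a in 1:5) for (b in a:5) {
    C[a, b] <- C[b, a] <- row15[c]
    c <- c + 1L
  }
  C
}

#' Infer an ensemble co-occurrence network
#'
#' For every OTU pair the five measures are evaluated on the observed table
#' and on a shared permutation stream; pairs supported by at least
#' `min_support` measures (raw p below `measure_support_p`) in a consistent
#' direction become candidates, their per-measure p-values are merged by
#' Brown's method using the permutation-estimated covariance, the merged
#' p-values are BH-adjusted across candidates, and surviving edges must
#' additionally be bootstrap-stable. Deterministic under `config$seed`.
#'
#' @param table an [otu_table()].
#' @param config a [network_config()].
#' @return An object of class `cooccur_net`: list with `edges` (data.frame),
#'   `nodes`, `candidates` (all screened pairs with statistics), counts and
#'   the config.
#' @export
infer_network <- function(table, config = network_config()) {
  stopifnot(is_otu_table(table), inherits(config, "network_config"))
  if (config$filter_input)
    table <- prevalence_filter(table, config$min_occurrence,
                               config$min_total_reads)
  p <- nrow(table); n <- ncol(table)
  if (n < 3L) stop("need at least 3 samples")
  if (p < 2L) stop("fewer than 2 OTUs after filtering")
  # canonical row order: pair statistics permute the second member's
  # samples, so orientation must not depend on the input row order
  table <- table[order(rownames(table)), , drop = FALSE]
  bins <- if (is.null(config$mi_bins)) mi_default_bins(n) else
    as.integer(config$mi_bins)
  set.seed(config$seed)
  perms <- perm_matrix(n, config$n_permutations)
  boots <- matrix(sample.int(n, n * config$n_bootstraps, replace = TRUE),
                  config$n_bootstraps, n)
  counts <- matrix(as.numeric(table), p, n)
  eng <- cpp_pair_engine(counts, perms, bins, config$kl_pseudocount)
  mset <- match(config$measures, measure_names)
  npairs <- length(eng$i)
  if (identical(config$p_method, "gaussian")) {
    z <- abs(eng$obs - eng$null_mean) / eng$null_sd
    pg <- 2 * stats::pnorm(-z)
    pg[!is.finite(pg)] <- NA_real_
    pg <- pmax(pg, .Machine$double.xmin)
    eng$pval <- matrix(pg, npairs, 5L)
  } else if (identical(config$p_method, "pooled")) {
    zw <- eng$zhist_width
    zobs <- abs(eng$obs - eng$null_mean) / eng$null_sd
    for (m in 1:5) {
      tot <- sum(eng$zhist[, m])
      if (tot == 0) next
      # count of pooled standardized null deviations >= each bin start
      n_ge <- rev(cumsum(rev(eng$zhist[, m])))
      zb <- pmin(floor(zobs[, m] / zw) + 1L, length(n_ge))
      pm_ <- (1 + n_ge[zb]) / (tot + 1)
      pm_[!is.finite(zobs[, m])] <- NA_real_
      eng$pval[, m] <- pm_
    }
  }

  # per-measure directions (+1 co-presence / -1 exclusion)
  dir <- matrix(NA_integer_, npairs, 5L)
  dir[, 1] <- ifelse(is.na(eng$obs[, 1]), NA, ifelse(eng$obs[, 1] >= 0, 1L, -1L))
  dir[, 2] <- ifelse(is.na(eng$obs[, 2]), NA, ifelse(eng$obs[, 2] >= 0, 1L, -1L))
  dir[, 3] <- ifelse(eng$obs[, 3] < eng$null_mean[, 3], 1L, -1L)
  dir[, 4] <- ifelse(eng$obs[, 4] < eng$null_mean[, 4], 1L, -1L)
  mi_dir <- ifelse(!is.na(eng$obs[, 2]), sign(eng$obs[, 2]),
                   ifelse(!is.na(eng$obs[, 1]), sign(eng$obs[, 1]), 1))
  dir[, 5] <- ifelse(mi_dir >= 0, 1L, -1L)

  screen <- function() {
    supp <- !is.na(eng$pval[, mset, drop = FALSE]) &
      eng$pval[, mset, drop = FALSE] < config$measure_support_p
    conflict <- vapply(seq_len(npairs), function(r) {
      d <- dir[r, mset][supp[r, ]]
      length(d) > 1L && length(unique(d)) > 1L
    }, logical(1L))
    list(supp = supp, support_count = rowSums(supp), conflict = conflict,
         cand = which(rowSums(supp) >= config$min_support & !conflict))
  }
  sc <- screen()
  supp <- sc$supp; support_count <- sc$support_count
  conflict <- sc$conflict; cand <- sc$cand

  cand_df <- NULL
  edges <- NULL
  if (length(cand)) {
    merged <- vapply(cand, function(r) {
      def <- mset[!is.na(eng$pval[r, mset])]
      C <- cov15_expand(eng$cov[r, ])[def, def, drop = FALSE]
      brown_merge(eng$pval[r, def], C)
    }, numeric(1L))
    adjusted <- bh_adjust(merged)
    consensus <- vapply(cand, function(r) {
      d <- unique(dir[r, mset][supp[r, ]])
      if (d[1L] > 0) "positive" else "negative"
    }, character(1L))

    sig <- adjusted < config$alpha
    stable <- rep(NA, length(cand))
    for (idx in which(sig)) {
      r <- cand[idx]
      sc <- cpp_boot_scores(counts[eng$i[r], ], counts[eng$j[r], ],
                            boots, bins, config$kl_pseudocount)
      ms_sup <- mset[supp[r, ]]
      stab <- vapply(ms_sup, function(m)
        stable_from_scores(sc[, m], eng$null_mean[r, m]), logical(1L))
      stable[idx] <- sum(stab) >= config$min_support
    }

    ids <- rownames(table)
    cand_df <- data.frame(otu_a = ids[eng$i[cand]], otu_b = ids[eng$j[cand]],
                          direction = consensus,
                          support_count = support_count[cand],
                          merged_p = merged, adjusted_p = adjusted,
                          stable = stable, stringsAsFactors = FALSE)
    for (m in mset) {
      nm <- measure_names[m]
      cand_df[[paste0("score_", nm)]] <- eng$obs[cand, m]
      cand_df[[paste0("p_", nm)]] <- eng$pval[cand, m]
    }
    keep <- sig & !is.na(stable) & stable
    if (!is.null(config$min_consensus_score)) {
      cscore <- pmax(abs(cand_df$score_pearson %||% NA),
                     abs(cand_df$score_spearman %||% NA), na.rm = TRUE)
      keep <- keep & !is.na(cscore) & cscore >= config$min_consensus_score
    }
    edges <- cand_df[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(edges))
    edges <- data.frame(otu_a = character(0), otu_b = character(0),
                        direction = character(0), support_count = integer(0),
                        merged_p = numeric(0), adjusted_p = numeric(0),
                        stable = logical(0), stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = rownames(table),
                 candidates = cand_df, n_pairs = npairs,
                 n_candidates = length(cand), n_samples = n,
                 mi_bins = bins, config = config),
            class = "cooccur_net")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cooccur_net <- function(x, ...) {
  cat("Ensemble co-occurrence network: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  cat("  ", x$n_pairs, " pairs tested, ", x$n_candidates,
      " passed the >=", x$config$min_support, "-measure screen; alpha = ",
      x$config$alpha, " (BH on Brown-merged p)\n", sep = "")
  if (nrow(x$edges))
    cat("  directions: ", sum(x$edges$direction == "positive"), " positive / ",
        sum(x$edges$direction == "negative"), " negative\n", sep = "")
  invisible(x)
}

#' @export
summary.cooccur_net <- function(object, ...) {
  deg <- node_degrees(object)
  out <- list(n_nodes = length(object$nodes), n_edges = nrow(object$edges),
              n_pairs = object$n_pairs, n_candidates = object$n_candidates,
              degree_summary = summary(deg),
              prop_positive = if (nrow(object$edges))
                mean(object$edges$direction == "positive") else NA_real_)
  class(out) <- "summary.cooccur_net"
  out
}

#' @export
print.summary.cooccur_net <- function(x, ...) {
  cat("nodes:", x$n_nodes, " edges:", x$n_edges, "\n")
  cat("degree distribution:\n")
  print(x$degree_summary)
  invisible(x)
}

#' @export
plot.cooccur_net <- function(x, ...) {
  g <- as_igraph(x, drop_isolated = TRUE)
  plot(g, vertex.size = 4, vertex.label = NA, ...)
  invisible(x)
}

node_degrees <- function(net) {
  deg <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    t1 <- table(c(net$edges$otu_a, net$edges$otu_b))
    deg[names(t1)] <- as.integer(t1)
  }
  deg
}

#' Convert a network to an igraph object
#' @param net a `cooccur_net`.
#' @param drop_isolated drop zero-degree nodes.
#' @return An undirected igraph graph with edge attributes.
#' @export
as_igraph <- function(net, drop_isolated = FALSE) {
  stopifnot(inherits(net, "cooccur_net"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  if (drop_isolated)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  g
}

#' Write network edges as TSV
#' @param net a `cooccur_net`.
#' @param path output path.
#' @export
write_edges <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the network as GraphML
#' @param net a `cooccur_net`.
#' @param path output path.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
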