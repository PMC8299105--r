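#' Specification for a synthetic fungal community
#'
#' Describes a multi-region OTU table with planted ground truth: broadly
#' occupying, evenly abundant generalists (the most abundant taxa, so a few
#' OTUs hold a large share of all reads); region-restricted, low-occupancy
#' specialists; mid-prevalence "medium" taxa; and latent correlated blocks
#' that act as true network edges. Counts are drawn per sample by
#' multinomial sampling at fixed depth from lognormal relative-abundance
#' weights, mirroring a rarefied amplicon table.
#'
#' @param n_regions number of bioclimatic regions (default 3).
#' @param samples_per_region samples in each region (default 60).
#' @param n_generalists,n_specialists_per_region,n_medium archetype counts
#'   (defaults 20 / 30 / 320, i.e. 430 OTUs over 180 samples).
#' @param depth reads per sample after multinomial sampling (default 10000).
#' @param generalist_occupancy fraction of all samples a generalist is
#'   planted in (default 0.95).
#' @param specialist_occupancy_samples number of within-region samples a
#'   specialist is planted in (default 8).
#' @param lognormal_sigma sd of the log-normal base-abundance weights
#'   (abundance heterogeneity across OTUs; default 1.5).
#' @param sample_jitter_sd sd of the per-sample multiplicative log-normal
#'   noise on every OTU's weight (default 0.3).
#' @param block_spec list of `c(size, rho)` pairs: latent correlated blocks
#'   planted among the generalists (true edges). Default: two blocks of five
#'   OTUs at latent correlation 0.8.
#' @param block_latent_sd sd of the block latent log-abundance (default 1).
#' @param seed integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_regions = 3L, samples_per_region = 60L,
                           n_generalists = 20L, n_specialists_per_region = 30L,
                           n_medium = 320L, depth = 10000L,
                           generalist_occupancy = 0.95,
                           specialist_occupancy_samples = 8L,
                           lognormal_sigma = 1.5, sample_jitter_sd = 0.3,
                           block_spec = list(c(5, 0.8), c(5, 0.8)),
                           block_latent_sd = 1, seed = 1L) {
  spec <- list(n_regions = as.integer(n_regions),
               samples_per_region = as.integer(samples_per_region),
               n_generalists = as.integer(n_generalists),
               n_specialists_per_region = as.integer(n_specialists_per_region),
               n_medium = as.integer(n_medium),
               depth = as.integer(depth),
               generalist_occupancy = generalist_occupancy,
               specialist_occupancy_samples = as.integer(specialist_occupancy_samples),
               lognormal_sigma = lognormal_sigma,
               sample_jitter_sd = sample_jitter_sd,
               block_spec = block_spec,
               block_latent_sd = block_latent_sd,
               seed = as.integer(seed))
  stopifnot(spec$n_regions >= 1, spec$samples_per_region >= 1,
            spec$n_generalists >= 0, spec$n_specialists_per_region >= 0,
            spec$n_medium >= 0, spec$depth >= 1,
            spec$generalist_occupancy > 0, spec$generalist_occupancy <= 1,
            spec$lognormal_sigma >= 0, spec$sample_jitter_sd >= 0)
  for (b in spec$block_spec)
    stopifnot(length(b) == 2L, b[1L] >= 2, abs(b[2L]) < 1)
  class(spec) <- "synthetic_spec"
  spec
}

region_names <- function(n_regions) {
  if (n_regions == 3L) c("subtropical", "warm_temperate", "temperate")
  else paste0("region_", seq_len(n_regions))
}

#' Exchangeable correlated latent abundance block
#'
#' Draws `size` rows from a multivariate normal with exchangeable
#' correlation `rho` (sd `sd`) over `n_samples` columns and exponentiates,
#' giving multiplicative abundance factors whose log-scale pairwise
#' correlation converges to `rho`.
#'
#' @param n_samples number of columns.
#' @param size number of rows (>= 2).
#' @param rho latent correlation, must satisfy `rho > -1/(size-1)`.
#' @param seed integer seed; `NULL` leaves the RNG stream untouched (used
#'   internally by [generate_community()]).
#' @param sd latent standard deviation (default 1).
#' @return `size` x `n_samples` matrix of positive abundance factors.
#' @export
generate_correlated_block <- function(n_samples, size, rho, seed = 1L, sd = 1) {
  stopifnot(size >= 2, abs(rho) < 1)
  if (rho <= -1 / (size - 1))
    stop("rho = ", rho, " makes the exchangeable correlation matrix of size ",
         size, " non positive-definite (requires rho > ", -1 / (size - 1), ")")
  if (!is.null(seed)) set.seed(as.integer(seed))
  R <- matrix(rho, size, size)
  diag(R) <- 1
  L <- chol(R)
  Z <- matrix(stats::rnorm(size * n_samples), size, n_samples)
  exp(sd * crossprod(L, Z))
}

#' Generate a synthetic community with planted ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `table` (an [otu_table()], every column
#'   summing to `spec$depth`), `metadata` (data.frame: sample_id, region)
#'   and `truth` (list: `labels` data.frame of otu_id/archetype,
#'   `true_edges` data.frame of within-block OTU pairs).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_samples <- spec$n_regions * spec$samples_per_region
  regions <- rep(region_names(spec$n_regions), each = spec$samples_per_region)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  n_spec_tot <- spec$n_regions * spec$n_specialists_per_region
  n_otu <- spec$n_generalists + n_spec_tot + spec$n_medium
  if (n_otu < 1L) stop("spec defines no OTUs")
  if (n_otu > spec$depth)
    warning("more OTUs (", n_otu, ") than reads per sample (", spec$depth,
            "); rare taxa will appear as zeros")

  spec_arch <- if (spec$n_specialists_per_region > 0)
    paste0("specialist:", rep(region_names(spec$n_regions),
                              each = spec$n_specialists_per_region))
  else character(0L)
  archetype <- c(rep("generalist", spec$n_generalists), spec_arch,
                 rep("medium", spec$n_medium))
  otu_ids <- sprintf("OTU_%04d", seq_len(n_otu))

  # base abundance weights: heaviest to generalists (they dominate reads),
  # next tier to specialists, remainder to mediums floored at the lognormal
  # median so planted occupancy is not sampling-limited
  w <- sort(stats::rlnorm(n_otu, 0, spec$lognormal_sigma), decreasing = TRUE)
  is_med <- archetype == "medium"
  w[is_med] <- pmax(w[is_med], exp(0))

  # designed occupancy masks
  mask <- matrix(FALSE, n_otu, n_samples)
  gen_idx <- which(archetype == "generalist")
  for (i in gen_idx) {
    k <- ceiling(spec$generalist_occupancy * n_samples)
    mask[i, sample.int(n_samples, k)] <- TRUE
  }
  for (i in which(startsWith(archetype, "specialist:"))) {
    reg <- sub("^specialist:", "", archetype[i])
    in_reg <- which(regions == reg)
    k <- min(spec$specialist_occupancy_samples, length(in_reg))
    mask[i, in_reg[sample.int(length(in_reg), k)]] <- TRUE
  }
  # mediums: occupancy fraction drawn uniformly from the band the
  # classification rules leave between the archetypes, stratified so every
  # region carries the same occupancy count -- region-balanced presence
  # gives mediums no habitat signal (no unplanted network structure) and a
  # within-region niche breadth above the specialist cuts
  spp <- spec$samples_per_region
  for (i in which(is_med)) {
    f <- stats::runif(1L, 0.40, 0.50)
    m <- max(1L, min(spp, round(f * spp)))
    for (reg in region_names(spec$n_regions)) {
      in_reg <- which(regions == reg)
      mask[i, in_reg[sample.int(length(in_reg), m)]] <- TRUE
    }
  }

  # per-sample multiplicative log-normal jitter; correlated blocks replace
  # the jitter of their member OTUs (planted true edges)
  Z <- matrix(stats::rnorm(n_otu * n_samples, 0, spec$sample_jitter_sd),
              n_otu, n_samples)
  edges_a <- character(0L); edges_b <- character(0L)
  # blocks need region-wide presence, so they live on generalists (then
  # mediums); lightest-weight hosts first, so the planted latent swings do
  # not move a large share of each sample's reads (which would induce
  # compositional common-mode correlation across the whole table)
  block_host <- c(rev(gen_idx), which(is_med))
  pos <- 1L
  for (b in spec$block_spec) {
    size <- as.integer(b[1L]); rho <- b[2L]
    if (pos + size - 1L > length(block_host))
      stop("block_spec requires more host OTUs than available")
    members <- block_host[pos:(pos + size - 1L)]
    pos <- pos + size
    Z[members, ] <- log(generate_correlated_block(
      n_samples, size, rho, seed = NULL, sd = spec$block_latent_sd))
    pr <- t(utils::combn(members, 2L))
    edges_a <- c(edges_a, otu_ids[pr[, 1L]])
    edges_b <- c(edges_b, otu_ids[pr[, 2L]])
  }

  W <- (w * exp(Z)) * mask
  counts <- matrix(0L, n_otu, n_samples)
  for (s in seq_len(n_samples)) {
    if (sum(W[, s]) <= 0) stop("sample ", sample_ids[s], " has zero total weight")
    counts[, s] <- stats::rmultinom(1L, spec$depth, W[, s])[, 1L]
  }

  list(table = otu_table(counts, otu_ids, sample_ids),
       metadata = data.frame(sample_id = sample_ids, region = regions,
                             row.names = sample_ids,
                             stringsAsFactors = FALSE),
       truth = list(labels = data.frame(otu_id = otu_ids,
                                        archetype = archetype,
                                        stringsAsFactors = FALSE),
                    true_edges = data.frame(otu_a = edges_a, otu_b = edges_b,
                                            stringsAsFactors = FALSE)))
}

#' Independent Poisson-lognormal OTU table (network null model)
#'
#' Every OTU is sampled independently of every other: cell counts are
#' Poisson with an OTU-specific lognormal mean and independent per-sample
#' lognormal variation, so any inferred edge is a false positive.
#'
#' @param n_otus,n_samples table dimensions.
#' @param mean_reads expected reads per OTU per sample before variation.
#' @param sd_log per-sample log-normal sd (default 1).
#' @param seed integer seed.
#' @return An [otu_table()].
#' @export
simulate_null_table <- function(n_otus = 60L, n_samples = 100L,
                                mean_reads = 50, sd_log = 1, seed = 1L) {
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_otus * n_samples, -sd_log^2 / 2, sd_log),
              n_otus, n_samples)
  lam <- mean_reads * exp(z)
  counts <- matrix(stats::rpois(n_otus * n_samples, lam), n_otus, n_samples)
  otu_table(counts, sprintf("OTU_%03d", seq_len(n_otus)),
            sprintf("S%03d", seq_len(n_samples)))
}

#' OTU table with one planted correlated block
#'
#' A single block of `block_size` OTUs shares an exchangeable latent
#' log-abundance correlation `rho`; all remaining OTUs are mutually
#' independent (as in [simulate_null_table()]).
#'
#' @inheritParams simulate_null_table
#' @param block_size number of correlated OTUs (the first rows).
#' @param rho latent correlation of the block.
#' @return A list: `table` (an [otu_table()]) and `true_edges`
#'   (data.frame of within-block pairs).
#' @export
simulate_block_table <- function(n_otus = 60L, n_samples = 100L,
                                 block_size = 5L, rho = 0.9,
                                 mean_reads = 50, sd_log = 1, seed = 1L) {
  stopifnot(block_size >= 2, block_size <= n_otus)
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_otus * n_samples, 0, sd_log), n_otus, n_samples)
  z[seq_len(block_size), ] <- sd_log * log(generate_correlated_block(
    n_samples, block_size, rho, seed = NULL, sd = 1))
  lam <- mean_reads * exp(z - sd_log^2 / 2)
  counts <- matrix(stats::rpois(n_otus * n_samples, lam), n_otus, n_samples)
  ids <- sprintf("OTU_%03d", seq_len(n_otus))
  pr <- t(utils::combn(seq_len(block_size), 2L))
  list(table = otu_table(counts, ids, sprintf("S%03d", seq_len(n_samples))),
       true_edges = data.frame(otu_a = ids[pr[, 1L]], otu_b = ids[pr[, 2L]],
                               stringsAsFactors = FALSE))
}

#' Simulate data from a standardized linear-Gaussian path model
#'
#' Generates observations in topological order: each node is the
#' coefficient-weighted sum of its parents plus Gaussian noise, and all
#' columns are z-scored. With `noise_sd = "auto"` the noise variance of each
#' endogenous node is set to one minus its explained variance (computed from
#' the implied covariance), so every node has unit variance and the planted
#' coefficients are directly the standardized path coefficients.
#'
#' @param dag a [path_model_skeleton()] or data.frame with columns
#'   `from`, `to`, `coef`.
#' @param n number of samples.
#' @param noise_sd `"auto"` (default), a scalar, or a named vector over
#'   endogenous nodes.
#' @param seed integer seed.
#' @return `n` x variables data.frame of z-scored observations, with the
#'   implied covariance in attribute `"implied_cov"`.
#' @export
generate_sem_dataset <- function(dag, n, noise_sd = "auto", seed = 1L) {
  sk <- as_path_skeleton(dag)
  ord <- topo_sort_dag(sk)   # errors on cycles
  vars <- sk$variables
  set.seed(as.integer(seed))
  # implied covariance under unit-variance nodes, exogenous independent
  S <- diag(length(vars))
  dimnames(S) <- list(vars, vars)
  sig <- stats::setNames(rep(NA_real_, length(vars)), vars)
  for (v in ord) {
    pa <- sk$edges$from[sk$edges$to == v]
    if (!length(pa)) { sig[v] <- 1; next }
    b <- sk$edges$coef[sk$edges$to == v]
    s2 <- drop(t(b) %*% S[pa, pa, drop = FALSE] %*% b)
    if (identical(noise_sd, "auto")) {
      if (s2 >= 1)
        stop("node '", v, "' has explained variance ", round(s2, 3),
             " >= 1; reduce coefficients or give noise_sd explicitly")
      sig[v] <- sqrt(1 - s2)
    } else if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
      sig[v] <- as.numeric(noise_sd)
    } else {
      if (!v %in% names(noise_sd)) stop("noise_sd missing for node '", v, "'")
      sig[v] <- as.numeric(noise_sd[[v]])
    }
    # implied (only exact in the auto, unit-variance case)
    for (u in vars) S[v, u] <- S[u, v] <- sum(b * S[pa, u])
    S[v, v] <- s2 + sig[v]^2
  }
  X <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  for (v in ord) {
    pa <- sk$edges$from[sk$edges$to == v]
    mu <- if (length(pa))
      X[, pa, drop = FALSE] %*% sk$edges$coef[sk$edges$to == v] else 0
    X[, v] <- mu + stats::rnorm(n, 0, sig[v])
  }
  X <- scale(X)
  out <- as.data.frame(X[, , drop = FALSE])
  attr(out, "implied_cov") <- S
  out
}

#' Default driver path diagram for synthetic data
#'
#' A plausible standardized acyclic path model of the drivers the study
#' design interrogates: spatial position drives climate; climate and edaphic
#' condition drive the generalist and specialist community components, with
#' specialists more environmentally sensitive than generalists; both fungal
#' components plus climate drive the coexistence pattern.
#'
#' @return A data.frame with columns `from`, `to`, `coef`.
#' @export
default_path_dag <- function() {
  data.frame(
    from = c("space", "climate", "climate", "edaphic", "edaphic",
             "generalist", "specialist", "climate"),
    to   = c("climate", "generalist", "specialist", "generalist",
             "specialist", "coexistence", "coexistence", "coexistence"),
    coef = c(0.7, 0.2, 0.45, 0.25, 0.4, 0.3, 0.15, 0.25),
    stringsAsFactors = FALSE)
}
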