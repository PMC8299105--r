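#' Levins' niche breadth index
#'
#' B = 1 / sum(P^2) for a proportion profile P over samples: 1 for an OTU
#' confined to one sample, N for an OTU spread evenly over N samples. The
#' profile is the within-OTU normalisation across samples (see
#' [otu_profile()]), so B is bounded above by the OTU's occurrence count.
#'
#' @param profile non-negative numeric vector summing to one (within 1e-9).
#' @return The niche breadth, a scalar in `[1, length(profile)]`.
#' @examples
#' niche_breadth(c(0.25, 0.25, 0.25, 0.25))  # 4
#' niche_breadth(c(0.75, 0.25))              # 1.6
#' @export
niche_breadth <- function(profile) {
  stopifnot(is.numeric(profile))
  if (any(profile < 0)) stop("profile entries must be non-negative")
  s <- sum(profile)
  if (s == 0) stop("zero-sum profile")
  if (abs(s - 1) > 1e-9)
    stop("profile must sum to 1 (got ", format(s), ")")
  1 / sum(profile^2)
}

#' Tukey-fence outlier threshold for a B-value distribution
#'
#' The fixed generalist/specialist cuts used in practice sit at the outlier
#' fences of the observed niche-breadth distribution; this helper computes
#' the fence (Q3 + 1.5 IQR upper, Q1 - 1.5 IQR lower, quartiles by linear
#' interpolation) as a suggested data-driven threshold.
#'
#' @param b_values numeric vector (at least 4 values).
#' @param tail `"upper"` or `"lower"`.
#' @return The fence value.
#' @export
suggest_outlier_threshold <- function(b_values, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  b_values <- b_values[is.finite(b_values)]
  if (length(b_values) < 4L) stop("need at least 4 finite values")
  q <- stats::quantile(b_values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  if (tail == "upper") q[2L] + 1.5 * iqr else q[1L] - 1.5 * iqr
}

#' Classification thresholds and rules
#'
#' Defaults reproduce the published rule set: generalists need global
#' B > 17, occurrence above 50% of samples and mean within-sample relative
#' abundance at least 2e-5; habitat specialists need within-region
#' B below the region threshold (12 for subtropical, 17 for warm temperate
#' and temperate) and within-region occurrence above 4. All inequalities
#' are strict, as stated. `auto_threshold = TRUE` replaces the fixed cuts
#' with the outlier fences of the current dataset's B distributions.
#'
#' @param generalist_b_threshold global B cut (default 17).
#' @param generalist_occurrence_fraction occurrence fraction cut (default 0.5).
#' @param min_mean_relabund abundance filter (default 2e-5).
#' @param specialist_b_thresholds named vector region -> B cut.
#' @param specialist_min_occurrence within-region occurrence cut (default 4).
#' @param auto_threshold derive cuts from outlier fences instead.
#' @return A `classification_config` list.
#' @export
classification_config <- function(generalist_b_threshold = 17,
                                  generalist_occurrence_fraction = 0.5,
                                  min_mean_relabund = 2e-5,
                                  specialist_b_thresholds = c(
                                    subtropical = 12,
                                    warm_temperate = 17,
                                    temperate = 17),
                                  specialist_min_occurrence = 4,
                                  auto_threshold = FALSE) {
  stopifnot(generalist_b_threshold > 0,
            generalist_occurrence_fraction > 0,
            generalist_occurrence_fraction <= 1,
            min_mean_relabund >= 0,
            all(specialist_b_thresholds > 0),
            specialist_min_occurrence >= 0)
  structure(list(generalist_b_threshold = generalist_b_threshold,
                 generalist_occurrence_fraction = generalist_occurrence_fraction,
                 min_mean_relabund = min_mean_relabund,
                 specialist_b_thresholds = specialist_b_thresholds,
                 specialist_min_occurrence = specialist_min_occurrence,
                 auto_threshold = auto_threshold),
            class = "classification_config")
}

#' Classify OTUs as generalists, habitat specialists or medium
#'
#' Computes per-OTU niche breadth globally and within each region (profiles
#' renormalised over the region's samples), occurrence, and mean
#' within-sample relative abundance, then applies the rule set in `config`.
#' Generalist takes precedence when both rules fire; an OTU qualifying as a
#' specialist in several regions is assigned the region with the lowest B
#' and the tie is recorded. OTUs failing the abundance filter that meet no
#' specialist rule are labelled `"filtered"`.
#'
#' @param table an [otu_table()] (typically rarefied).
#' @param metadata data.frame with rownames = sample ids and a `region`
#'   column covering every sample of `table`.
#' @param config a [classification_config()].
#' @return An object of class `niche_class`: a list with `results` (per-OTU
#'   data.frame), `thresholds` (the cuts actually used), `config`, `regions`.
#' @export
niche_classify <- function(table, metadata,
                           config = classification_config()) {
  stopifnot(is_otu_table(table), inherits(config, "classification_config"))
  check_metadata(table, metadata)
  region <- as.character(metadata[colnames(table), "region"])
  regions <- unique(region)
  tab <- table(region)
  if (any(tab < 2L))
    stop("region '", names(tab)[tab < 2L][1L], "' has fewer than 2 samples")
  n <- ncol(table)
  counts <- unclass(table)
  tot <- rowSums(counts)
  occ <- rowSums(counts > 0)
  relab <- within_sample_relabund(table)
  mean_relab <- rowMeans(relab)

  b_global <- ifelse(tot > 0, tot^2 / rowSums(counts^2), NA_real_)
  b_region <- matrix(NA_real_, nrow(counts), length(regions),
                     dimnames = list(rownames(counts), regions))
  occ_region <- b_region
  for (r in regions) {
    sub <- counts[, region == r, drop = FALSE]
    rt <- rowSums(sub)
    b_region[, r] <- ifelse(rt > 0, rt^2 / rowSums(sub^2), NA_real_)
    occ_region[, r] <- rowSums(sub > 0)
  }

  thr_gen <- config$generalist_b_threshold
  thr_spec <- config$specialist_b_thresholds
  if (config$auto_threshold) {
    pass <- mean_relab >= config$min_mean_relabund & is.finite(b_global)
    thr_gen <- suggest_outlier_threshold(b_global[pass], "upper")
    thr_spec <- vapply(regions, function(r)
      suggest_outlier_threshold(b_region[is.finite(b_region[, r]), r],
                                "lower"), numeric(1L))
  } else {
    missing_thr <- setdiff(regions, names(thr_spec))
    if (length(missing_thr))
      stop("no specialist B threshold for region(s): ",
           paste(missing_thr, collapse = ", "),
           "; supply specialist_b_thresholds or use auto_threshold")
    thr_spec <- thr_spec[regions]
  }

  pass_ab <- mean_relab >= config$min_mean_relabund
  is_gen <- pass_ab & is.finite(b_global) & b_global > thr_gen &
    (occ / n) > config$generalist_occurrence_fraction

  qual <- sapply(regions, function(r)
    is.finite(b_region[, r]) & b_region[, r] < thr_spec[[r]] &
      occ_region[, r] > config$specialist_min_occurrence)
  if (is.null(dim(qual))) qual <- matrix(qual, nrow = 1L,
                                         dimnames = list(rownames(counts), regions))
  n_qual <- rowSums(qual)
  spec_region <- rep(NA_character_, nrow(counts))
  for (i in which(n_qual > 0)) {
    cand <- regions[qual[i, ]]
    spec_region[i] <- cand[which.min(b_region[i, cand])]
  }
  tie <- vapply(seq_len(nrow(counts)), function(i)
    if (n_qual[i] > 1L) paste(regions[qual[i, ]], collapse = ",") else "",
    character(1L))

  label <- rep("medium", nrow(counts))
  label[!pass_ab] <- "filtered"
  label[!is_gen & n_qual > 0] <- paste0("specialist:",
                                        spec_region[!is_gen & n_qual > 0])
  label[is_gen] <- "generalist"

  res <- data.frame(otu_id = rownames(counts),
                    b_global = b_global,
                    occurrence_count = occ,
                    occurrence_fraction = occ / n,
                    mean_relabund = mean_relab,
                    label = label,
                    specialist_region_ties = tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (r in regions) {
    res[[paste0("b_", r)]] <- b_region[, r]
    res[[paste0("occurrence_", r)]] <- occ_region[, r]
  }
  structure(list(results = res,
                 thresholds = list(generalist_b = thr_gen,
                                   specialist_b = thr_spec,
                                   generalist_occurrence_fraction =
                                     config$generalist_occurrence_fraction,
                                   specialist_min_occurrence =
                                     config$specialist_min_occurrence,
                                   min_mean_relabund = config$min_mean_relabund),
                 config = config, regions = regions,
                 n_samples = n),
            class = "niche_class")
}

#' @export
print.niche_class <- function(x, ...) {
  cat("Niche-breadth classification over", nrow(x$results), "OTUs and",
      x$n_samples, "samples\n")
  cat("  generalist B >", format(x$thresholds$generalist_b),
      "| occurrence >",
      paste0(100 * x$thresholds$generalist_occurrence_fraction, "%"),
      "| mean relabund >=", format(x$thresholds$min_mean_relabund), "\n")
  cat("  specialist B <",
      paste(names(x$thresholds$specialist_b), "=",
            format(x$thresholds$specialist_b), collapse = ", "),
      "| region occurrence >", x$thresholds$specialist_min_occurrence, "\n")
  print(table(x$results$label))
  invisible(x)
}

#' @export
summary.niche_class <- function(object, ...) {
  res <- object$results
  lab <- table(res$label)
  gen <- res[res$label == "generalist", , drop = FALSE]
  out <- list(labels = lab,
              n_generalists = sum(res$label == "generalist"),
              generalist_cumulative_relabund = sum(gen$mean_relabund),
              b_range = range(res$b_global, na.rm = TRUE),
              thresholds = object$thresholds)
  class(out) <- "summary.niche_class"
  out
}

#' @export
print.summary.niche_class <- function(x, ...) {
  print(x$labels)
  cat("generalists hold ",
      format(100 * x$generalist_cumulative_relabund, digits = 3),
      "% of reads (mean relative abundance summed)\n", sep = "")
  invisible(x)
}

#' @export
plot.niche_class <- function(x, ...) {
  b <- x$results$b_global
  graphics::hist(b[is.finite(b)], breaks = 40,
                 main = "Niche breadth distribution",
                 xlab = "Levins' B (global)", ...)
  graphics::abline(v = x$thresholds$generalist_b, lty = 2)
  invisible(x)
}

#' Write a classification result to TSV
#' @param x a `niche_class` object.
#' @param path output path.
#' @export
write_classification <- function(x, path) {
  stopifnot(inherits(x, "niche_class"))
  utils::write.table(x$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
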