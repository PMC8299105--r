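#' Construct an OTU count table
#'
#' An `otu_table` is a non-negative integer matrix with one row per OTU and
#' one column per sample, the container every downstream stage consumes.
#'
#' @param counts numeric matrix of non-negative integers (rows = OTUs,
#'   columns = samples), or something coercible to one.
#' @param otu_ids,sample_ids character vectors of unique identifiers; default
#'   to the dimnames of `counts`.
#' @return An object of class `otu_table`: the integer matrix with
#'   `rownames` = OTU ids and `colnames` = sample ids.
#' @examples
#' tab <- otu_table(matrix(c(1, 3, 2, 4), 2), c("o1", "o2"), c("s1", "s2"))
#' @export
otu_table <- function(counts, otu_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(otu_ids)) otu_ids <- paste0("OTU_", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(counts)))
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (length(otu_ids) != nrow(counts))
    stop("length of otu_ids (", length(otu_ids), ") != number of rows (",
         nrow(counts), ")")
  if (length(sample_ids) != ncol(counts))
    stop("length of sample_ids (", length(sample_ids), ") != number of columns (",
         ncol(counts), ")")
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id: ", otu_ids[duplicated(otu_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (any(!is.finite(counts)))
    stop("counts contain non-finite values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at OTU '", otu_ids[bad[1L]], "', sample '",
         sample_ids[bad[2L]], "'")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop("non-integer count at OTU '", otu_ids[bad[1L]], "', sample '",
         sample_ids[bad[2L]], "'")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(otu_ids, sample_ids)
  class(counts) <- c("otu_table", "matrix", "array")
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table: ", nrow(x), " OTUs x ", ncol(x), " samples, ",
      sum(x), " reads\n", sep = "")
  invisible(x)
}

#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("otu_table", "matrix", "array")
  out
}

is_otu_table <- function(x) inherits(x, "otu_table")

#' Read an OTU table from disk
#'
#' Supports the tab-separated convention (first header cell `#OTU ID`, one
#' row per OTU) and BIOM v1.0 JSON (via the biomformat package).
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom_json"`; by default guessed from the file
#'   extension (`.biom`/`.json` vs everything else).
#' @return An [otu_table()] with row/column order as stored in the file.
#' @export
read_otu_table <- function(path, format = c("auto", "tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE))
      "biom_json" else "tsv"
  }
  if (format == "biom_json") {
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(otu_table(m))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty OTU table file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("malformed header in ", path, ": expected '#OTU ID' plus sample ids")
  sample_ids <- header[-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  otu_ids <- vapply(body, `[[`, character(1L), 1L)
  n <- length(sample_ids)
  counts <- matrix(0L, length(body), n)
  for (r in seq_along(body)) {
    cells <- body[[r]][-1L]
    if (length(cells) != n)
      stop("row '", otu_ids[r], "' has ", length(cells),
           " cells; expected ", n)
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v)) {
      stop("non-numeric cell '", cells[which(is.na(v))[1L]], "' at OTU '",
           otu_ids[r], "', sample '", sample_ids[which(is.na(v))[1L]], "'")
    }
    bad <- which(v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad))
      stop("invalid (negative or non-integer) count '", cells[bad[1L]],
           "' at OTU '", otu_ids[r], "', sample '", sample_ids[bad[1L]], "'")
    counts[r, ] <- as.integer(round(v))
  }
  otu_table(counts, otu_ids, sample_ids)
}

#' Write an OTU table to disk
#'
#' @param table an [otu_table()].
#' @param path output file path.
#' @param format `"tsv"` or `"biom_json"`.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  stopifnot(is_otu_table(table))
  if (format == "biom_json") {
    b <- biomformat::make_biom(unclass(table))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#OTU ID", colnames(table)), collapse = "\t"), con)
  body <- apply(table, 1L, function(r) paste(r, collapse = "\t"))
  writeLines(paste(rownames(table), body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `region`, then any number of
#' numeric covariate columns.
#'
#' @param path file path.
#' @return A `data.frame` with rownames = sample ids, a `region` factor and
#'   numeric covariates.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "region") %in% names(df)))
    stop("metadata must contain 'sample_id' and 'region' columns")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  rownames(df) <- df$sample_id
  cov <- setdiff(names(df), c("sample_id", "region"))
  for (cn in cov) {
    df[[cn]] <- as.numeric(df[[cn]])
    if (any(!is.finite(df[[cn]])))
      stop("non-finite covariate values in column '", cn, "'")
  }
  df
}

#' Write sample metadata
#' @param metadata data.frame as returned by [read_sample_metadata()].
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

check_metadata <- function(table, metadata) {
  missing <- setdiff(colnames(table), rownames(metadata))
  if (length(missing))
    stop("samples missing from metadata: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  invisible(TRUE)
}

#' Rarefy an OTU table to fixed depth
#'
#' Random subsampling without replacement of each sample to exactly `depth`
#' reads (the normalisation the study pipeline applies before any analysis).
#' Samples with fewer than `depth` reads are dropped; their ids are recorded
#' in the `"dropped_samples"` attribute and reported via a message.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample (positive integer).
#' @param seed integer seed; identical seed gives identical output.
#' @return A rarefied [otu_table()]; every retained column sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(is_otu_table(table), depth >= 1)
  tot <- colSums(table)
  keep <- tot >= depth
  if (!any(keep))
    stop("all ", ncol(table), " samples have fewer than ", depth, " reads")
  dropped <- colnames(table)[!keep]
  if (length(dropped))
    message("rarefy: dropping ", length(dropped),
            " sample(s) below depth: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  sub <- table[, keep, drop = FALSE]
  set.seed(as.integer(seed))
  # vegan expects samples in rows; its count-sanity warnings are redundant
  # with the validation above
  rar <- t(suppressWarnings(vegan::rrarefy(t(unclass(sub)), sample = depth)))
  out <- otu_table(rar, rownames(sub), colnames(sub))
  attr(out, "dropped_samples") <- dropped
  out
}

#' Within-sample relative abundance
#'
#' Each column is divided by its total, so columns sum to one. This is the
#' normalisation behind the mean-relative-abundance filter (2e-5) of the
#' generalist rule, not the profile entering the niche-breadth index.
#'
#' @param table an [otu_table()].
#' @return A numeric matrix of proportions with the same dimnames.
#' @export
within_sample_relabund <- function(table) {
  stopifnot(is_otu_table(table))
  tot <- colSums(table)
  if (any(tot == 0))
    stop("zero-total sample: ", colnames(table)[which(tot == 0)[1L]])
  sweep(unclass(table), 2L, tot, "/")
}

#' Within-OTU profile across samples
#'
#' Returns P_ij = n_ij / sum_i n_ij for one OTU: the fraction of the OTU's
#' reads found in each sample. This is the profile whose inverse
#' Simpson concentration is Levins' niche breadth (so B ranges from 1 to the
#' number of samples).
#'
#' @param table an [otu_table()].
#' @param otu_id row identifier.
#' @return Named numeric vector over samples summing to one.
#' @export
otu_profile <- function(table, otu_id) {
  stopifnot(is_otu_table(table))
  if (!otu_id %in% rownames(table)) stop("unknown OTU id: ", otu_id)
  x <- as.numeric(table[otu_id, ])
  s <- sum(x)
  if (s == 0) stop("OTU '", otu_id, "' has zero total count")
  stats::setNames(x / s, colnames(table))
}

#' Prevalence filter
#'
#' Retains OTUs observed in at least `min_occurrence` samples and holding at
#' least `min_total_reads` reads in total; the sample axis is unchanged.
#' Defaults follow the rule that OTUs with fewer than four occurrences and
#' 10 reads are excluded before network construction.
#'
#' @param table an [otu_table()].
#' @param min_occurrence minimum number of samples with a non-zero count.
#' @param min_total_reads minimum total reads.
#' @return Filtered [otu_table()] (possibly with zero rows).
#' @export
prevalence_filter <- function(table, min_occurrence = 4L,
                              min_total_reads = 10L) {
  stopifnot(is_otu_table(table), min_occurrence >= 0, min_total_reads >= 0)
  occ <- rowSums(table > 0)
  tot <- rowSums(table)
  table[occ >= min_occurrence & tot >= min_total_reads, , drop = FALSE]
}
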