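#' Declare a path-model skeleton
#'
#' A directed acyclic diagram over observed variables, optionally with
#' composite variables defined as the first principal-component score of a
#' set of indicator columns (the reduction used for blocks like "carbon" =
#' SOC + DOC).
#'
#' @param edges data.frame with columns `from`, `to` (and optionally
#'   `coef`, used by [generate_sem_dataset()]).
#' @param composites named list: composite name -> character vector of
#'   indicator columns.
#' @return A `path_skeleton` list with `edges`, `variables`, `composites`.
#' @export
path_model_skeleton <- function(edges, composites = list()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$coef)) edges$coef <- rep(NA_real_, nrow(edges))
  if (any(edges$from == edges$to)) stop("self-loop in DAG")
  if (anyDuplicated(edges[c("from", "to")]))
    stop("duplicate edge in DAG")
  sk <- structure(list(edges = edges,
                       variables = unique(c(edges$from, edges$to)),
                       composites = composites),
                  class = "path_skeleton")
  topo_sort_dag(sk)  # errors if cyclic
  sk
}

as_path_skeleton <- function(x) {
  if (inherits(x, "path_skeleton")) return(x)
  if (is.data.frame(x)) return(path_model_skeleton(x))
  if (inherits(x, "path_model")) return(x$skeleton)
  stop("cannot interpret DAG of class ", paste(class(x), collapse = "/"))
}

# Kahn's algorithm; errors on cycles
topo_sort_dag <- function(sk) {
  vars <- sk$variables
  indeg <- stats::setNames(integer(length(vars)), vars)
  for (v in sk$edges$to) indeg[v] <- indeg[v] + 1L
  out <- character(0L)
  avail <- names(indeg)[indeg == 0L]
  edges <- sk$edges
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    out <- c(out, v)
    ch <- edges$to[edges$from == v]
    for (u in ch) {
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0L) avail <- c(avail, u)
    }
    edges <- edges[edges$from != v, , drop = FALSE]
  }
  if (length(out) != length(vars))
    stop("DAG contains a cycle involving: ",
         paste(setdiff(vars, out), collapse = ", "))
  out
}

#' Parse a flat path-model declaration
#'
#' One directed edge per line as `parent -> child`; composites as
#' `name = var1 + var2`; blank lines and `#` comments ignored.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return A [path_model_skeleton()].
#' @export
parse_path_model <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  comp <- list(); from <- character(0L); to <- character(0L)
  for (ln in lines) {
    if (grepl("->", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "->", fixed = TRUE)[[1L]])
      if (length(parts) != 2L || !all(nzchar(parts)))
        stop("malformed edge line: '", ln, "'")
      from <- c(from, parts[1L]); to <- c(to, parts[2L])
    } else if (grepl("=", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "=", fixed = TRUE)[[1L]])
      inds <- trimws(strsplit(parts[2L], "+", fixed = TRUE)[[1L]])
      if (length(parts) != 2L || !all(nzchar(c(parts[1L], inds))))
        stop("malformed composite line: '", ln, "'")
      comp[[parts[1L]]] <- inds
    } else stop("unparseable line: '", ln, "'")
  }
  path_model_skeleton(data.frame(from = from, to = to,
                                 stringsAsFactors = FALSE), comp)
}

# first principal-component score of z-scored indicators, sign-aligned so
# the first indicator loads positively, then z-scored
composite_score <- function(data, indicators) {
  missing <- setdiff(indicators, names(data))
  if (length(missing))
    stop("composite indicators missing from data: ",
         paste(missing, collapse = ", "))
  M <- scale(as.matrix(data[indicators]))
  pc <- stats::prcomp(M, center = FALSE, scale. = FALSE)
  sc <- pc$x[, 1L]
  if (pc$rotation[1L, 1L] < 0) sc <- -sc
  as.numeric(scale(sc))
}

#' Fit a standardized path model
#'
#' All columns are z-scored (composites are computed first); each
#' endogenous node is regressed by ordinary least squares on its parents.
#' The fitted coefficients are standardized path coefficients, and total
#' effects are accumulated over all directed paths in topological order.
#'
#' @param data sample x variable data.frame.
#' @param dag a [path_model_skeleton()], data.frame of edges, or a file
#'   path/text handled by [parse_path_model()].
#' @return An object of class `path_model`: list with `skeleton`, `edges`
#'   (with fitted `coef`), `r_squared` per endogenous node, `total_effects`
#'   matrix (sources x targets, diagonal 1), `data` (the standardized
#'   model frame), `n`.
#' @export
fit_paths <- function(data, dag) {
  sk <- as_path_skeleton(dag)
  data <- as.data.frame(data)
  for (cn in names(sk$composites))
    data[[cn]] <- composite_score(data, sk$composites[[cn]])
  missing <- setdiff(sk$variables, names(data))
  if (length(missing))
    stop("DAG variables missing from data: ", paste(missing, collapse = ", "))
  X <- as.data.frame(scale(as.matrix(data[sk$variables])))
  if (any(!is.finite(as.matrix(X))))
    stop("non-finite values after standardization (constant column?)")
  n <- nrow(X)
  edges <- sk$edges
  endo <- unique(edges$to)
  r2 <- stats::setNames(numeric(0L), character(0L))
  for (v in endo) {
    pa <- edges$from[edges$to == v]
    if (n <= length(pa) + 1L)
      stop("too few observations (", n, ") to fit node '", v, "'")
    Xp <- as.matrix(X[pa])
    if (length(pa) > 1L) {
      kap <- kappa(crossprod(Xp) / (n - 1), exact = TRUE)
      if (kap > 1e8) {
        cors <- stats::cor(Xp)
        diag(cors) <- 0
        worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1L, ]
        stop("collinear parents of '", v, "': ", pa[worst[1L]], " and ",
             pa[worst[2L]])
      }
    }
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xp), X[[v]])
    edges$coef[edges$to == v] <- fit$coefficients[-1L]
    r2[v] <- 1 - sum(fit$residuals^2) / sum((X[[v]] - mean(X[[v]]))^2)
  }
  model <- structure(list(skeleton = sk, edges = edges, r_squared = r2,
                          data = X, n = n),
                     class = "path_model")
  model$total_effects <- total_effects(model)
  model
}

#' Standardized total effects
#'
#' Sum over all directed paths of the product of edge coefficients along
#' each path, computed in topological order as (I - A)^-1 where A holds the
#' direct coefficients; the diagonal (effect of a node on itself) is 1 by
#' convention and unrelated pairs are 0.
#'
#' @param model a fitted `path_model` (or skeleton with coefficients).
#' @return Square matrix, rows = sources, columns = targets.
#' @export
total_effects <- function(model) {
  sk <- as_path_skeleton(model)
  edges <- if (inherits(model, "path_model")) model$edges else sk$edges
  if (any(is.na(edges$coef)) && nrow(edges))
    stop("model has unfitted coefficients; run fit_paths() first")
  vars <- sk$variables
  if (!length(vars))
    return(matrix(numeric(0), 0, 0))
  A <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  for (e in seq_len(nrow(edges)))
    A[edges$from[e], edges$to[e]] <- edges$coef[e]
  # DAG: series terminates; (I - A)^-1 = I + A + A^2 + ...
  solve(diag(length(vars)) - A)
}

#' @export
print.path_model <- function(x, ...) {
  cat("Standardized path model:", length(x$skeleton$variables),
      "variables,", nrow(x$edges), "paths, n =", x$n, "\n")
  df <- x$edges
  df$coef <- round(df$coef, 3)
  print(df, row.names = FALSE)
  cat("r-squared:",
      paste(names(x$r_squared), "=", round(x$r_squared, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.path_model <- function(object, ...) {
  if (!nrow(object$edges)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(object$edges$coef,
                  paste(object$edges$from, "->", object$edges$to))
}

#' @export
summary.path_model <- function(object, ...) {
  exo <- setdiff(object$skeleton$variables, unique(object$edges$to))
  endo <- unique(object$edges$to)
  out <- list(coefficients = coef(object), r_squared = object$r_squared,
              total_effects = object$total_effects[exo, endo, drop = FALSE],
              n = object$n)
  class(out) <- "summary.path_model"
  out
}

#' @export
print.summary.path_model <- function(x, ...) {
  cat("paths:\n"); print(round(x$coefficients, 3))
  cat("total effects (exogenous on endogenous):\n")
  print(round(x$total_effects, 3))
  invisible(x)
}

#' Bootstrap significance of path and total effects
#'
#' Resamples rows with replacement, refits, and reports for every direct
#' edge and every (source, target) total effect a two-sided bootstrap
#' p-value: twice the (add-one smoothed) fraction of bootstrap replicates
#' on the opposite side of zero. Deterministic under `seed`.
#'
#' @param model a fitted `path_model`.
#' @param data the original data (composites are recomputed per resample).
#' @param n_bootstrap replicates (>= 200).
#' @param seed integer seed.
#' @return list with `edge_p` (named by "from -> to") and `total_p`
#'   (matrix, sources x targets).
#' @export
effect_significance <- function(model, data, n_bootstrap = 1000L, seed = 1L) {
  stopifnot(inherits(model, "path_model"), n_bootstrap >= 200L)
  data <- as.data.frame(data)
  set.seed(as.integer(seed))
  vars <- model$skeleton$variables
  n <- nrow(data)
  ne <- nrow(model$edges)
  boot_coef <- matrix(NA_real_, n_bootstrap, ne)
  boot_tot <- array(NA_real_, c(n_bootstrap, length(vars), length(vars)))
  failed <- 0L
  for (b in seq_len(n_bootstrap)) {
    ix <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(fit_paths(data[ix, , drop = FALSE], model$skeleton),
                    error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    boot_coef[b, ] <- fit$edges$coef
    boot_tot[b, , ] <- fit$total_effects
  }
  if (failed > 0.1 * n_bootstrap)
    stop("bootstrap refit failed in ", failed, " of ", n_bootstrap,
         " replicates")
  two_sided <- function(v) {
    v <- v[is.finite(v)]
    R <- length(v)
    min(1, 2 * min((1 + sum(v <= 0)) / (R + 1), (1 + sum(v >= 0)) / (R + 1)))
  }
  edge_p <- stats::setNames(apply(boot_coef, 2L, two_sided),
                            paste(model$edges$from, "->", model$edges$to))
  total_p <- matrix(NA_real_, length(vars), length(vars),
                    dimnames = list(vars, vars))
  for (a in seq_along(vars)) for (bb in seq_along(vars))
    total_p[a, bb] <- two_sided(boot_tot[, a, bb])
  diag(total_p) <- NA_real_
  list(edge_p = edge_p, total_p = total_p, n_failed = failed)
}

#' Write fitted path-model results as TSV
#' @param model a fitted `path_model`.
#' @param path output path for the edge table; total effects are written
#'   alongside with suffix `_total_effects.tsv`.
#' @export
write_path_model <- function(model, path) {
  utils::write.table(model$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  te <- model$total_effects
  df <- data.frame(source = rownames(te)[row(te)],
                   target = colnames(te)[col(te)],
                   total_effect = as.vector(te), stringsAsFactors = FALSE)
  df <- df[df$source != df$target & df$total_effect != 0, , drop = FALSE]
  utils::write.table(df, sub("\\.tsv$", "_total_effects.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
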