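as_graph <- function(x) {
  if (inherits(x, "igraph")) {
    if (is.null(igraph::V(x)$name))
      igraph::V(x)$name <- as.character(seq_len(igraph::vcount(x)))
    return(x)
  }
  if (inherits(x, "cooccur_net")) return(as_igraph(x))
  stop("expected a cooccur_net or igraph object")
}

check_simple <- function(g) {
  if (any(igraph::which_loop(g))) stop("graph contains a self-loop")
  if (any(igraph::which_multiple(g))) stop("graph contains multi-edges")
  invisible(g)
}

#' Node degree
#'
#' Incident edge count of every node of a simple undirected graph.
#' @param graph a `cooccur_net` or igraph object.
#' @return Named integer vector.
#' @export
degree_centrality <- function(graph) {
  g <- check_simple(as_graph(graph))
  igraph::degree(g)
}

#' Component-scaled closeness centrality
#'
#' Within each connected component of size k a node's closeness is
#' (k-1)/sum(shortest-path distances), multiplied by (k-1)/(n-1) so values
#' from different components are comparable; isolated nodes get 0. This is
#' the standard convention for disconnected graphs, which co-occurrence
#' networks usually are.
#'
#' @param graph a `cooccur_net` or igraph object.
#' @return Named numeric vector in `[0, 1]`.
#' @export
closeness_centrality <- function(graph) {
  g <- check_simple(as_graph(graph))
  n <- igraph::vcount(g)
  out <- stats::setNames(rep(0, n), igraph::V(g)$name)
  if (n <= 1L || igraph::ecount(g) == 0L) return(out)
  D <- igraph::distances(g)
  for (v in seq_len(n)) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    k <- length(reach) + 1L
    if (k > 1L)
      out[v] <- ((k - 1) / sum(D[v, reach])) * ((k - 1) / (n - 1))
  }
  out
}

#' Normalized betweenness centrality
#'
#' Fraction of shortest paths passing through each node, normalized by
#' (n-1)(n-2)/2 for an undirected graph.
#' @param graph a `cooccur_net` or igraph object.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(graph) {
  g <- check_simple(as_graph(graph))
  igraph::betweenness(g, directed = FALSE, normalized = TRUE)
}

#' Eigenvector centrality
#'
#' Dominant eigenvector of the adjacency matrix, max-normalized to 1. On a
#' disconnected graph the mass concentrates on the component(s) with the
#' largest spectral radius; an edgeless graph returns all zeros.
#' @param graph a `cooccur_net` or igraph object.
#' @param components if `TRUE`, compute per connected component instead of
#'   on the full graph.
#' @return Named numeric vector in `[0, 1]`.
#' @export
eigen_centrality_scores <- function(graph, components = FALSE) {
  g <- check_simple(as_graph(graph))
  n <- igraph::vcount(g)
  out <- stats::setNames(rep(0, n), igraph::V(g)$name)
  if (igraph::ecount(g) == 0L) return(out)
  if (!components) {
    ec <- igraph::eigen_centrality(g)$vector
    out[names(ec)] <- ec
    return(out)
  }
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    vs <- which(comp$membership == cid)
    sg <- igraph::induced_subgraph(g, vs)
    if (igraph::ecount(sg) == 0L) next
    ec <- igraph::eigen_centrality(sg)$vector
    out[names(ec)] <- ec
  }
  out
}

#' Detect modules by modularity maximisation
#'
#' Louvain-style local moving + aggregation (resolution 1), deterministic
#' under `seed`. The reported Q is the standard modularity of the returned
#' partition and can be recomputed independently from its definition.
#'
#' @param graph a `cooccur_net` or igraph object with at least one edge.
#' @param seed integer seed.
#' @return list with `membership` (named integer vector) and `modularity`.
#' @export
detect_modules <- function(graph, seed = 1L) {
  g <- check_simple(as_graph(graph))
  if (igraph::ecount(g) == 0L) stop("graph has no edges")
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, resolution = 1)
  mem <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(mem), names(mem)),
       modularity = igraph::modularity(g, mem))
}

#' Within-module degree z-score and participation coefficient
#'
#' Zi = (within-module degree - module mean)/module sd (0 when the sd is 0);
#' Pi = 1 - sum over modules of (k_im/k_i)^2 (0 for isolated nodes). Roles
#' follow the standard cutoffs: module hub (Zi >= 2.5, Pi <= 0.62),
#' connector (Zi < 2.5, Pi > 0.62), kinless (both exceeded), else
#' peripheral.
#'
#' @param graph a `cooccur_net` or igraph object.
#' @param modules named membership vector as from [detect_modules()].
#' @return data.frame with columns `node`, `zi`, `pi`, `role`.
#' @export
zi_pi <- function(graph, modules) {
  g <- check_simple(as_graph(graph))
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(modules)))
    stop("modules must cover every node of the graph")
  mem <- modules[nodes]
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(A)
  mods <- sort(unique(mem))
  # within-module degree of every node to every module
  kim <- sapply(mods, function(m) rowSums(A[, mem == m, drop = FALSE]))
  if (is.null(dim(kim))) kim <- matrix(kim, nrow = length(nodes))
  own <- match(mem, mods)
  k_in <- kim[cbind(seq_along(nodes), own)]
  zi <- numeric(length(nodes))
  for (m in seq_along(mods)) {
    in_m <- own == m
    mu <- mean(k_in[in_m]); sdv <- stats::sd(k_in[in_m])
    zi[in_m] <- if (is.na(sdv) || sdv == 0) 0 else (k_in[in_m] - mu) / sdv
  }
  pi <- ifelse(k > 0, 1 - rowSums((kim / pmax(k, 1))^2), 0)
  role <- ifelse(zi >= 2.5,
                 ifelse(pi <= 0.62, "module_hub", "kinless"),
                 ifelse(pi > 0.62, "connector", "peripheral"))
  data.frame(node = nodes, zi = zi, pi = pi, role = role,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x` with slope, intercept, r-squared and
#' the slope's t-test p-value (used for the niche-breadth versus centrality
#' relationships).
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 finite observations")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate input
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L],
       n = length(x))
}

#' One-way ANOVA on node degree by niche group
#'
#' F-test across groups plus Tukey HSD post-hoc comparisons summarised as a
#' compact letter display (groups sharing a letter are not significantly
#' different at 0.05). Singleton groups are excluded with a warning.
#'
#' @param values per-node numeric values (e.g. degree).
#' @param labels per-node group labels.
#' @return list with `F`, `p`, `letters` (named by group), `group_means`,
#'   `n_per_group`.
#' @export
compare_degree_groups <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    warning("excluding singleton group(s): ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
    keep <- labels %in% names(sizes)[sizes >= 2L]
    values <- values[keep]; labels <- labels[keep]
  }
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least 2 groups with >= 2 members")
  df <- data.frame(y = values, g = g)
  means <- tapply(values, g, mean)
  ssb <- sum(tapply(values, g, length) * (means - mean(values))^2)
  if (ssb == 0) {
    return(list(F = 0, p = 1,
                letters = stats::setNames(rep("a", nlevels(g)), levels(g)),
                group_means = means, n_per_group = table(g)))
  }
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1L]]
  letters <- tryCatch({
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
    multcomp::cld(glht, level = 0.05)$mcletters$Letters
  }, error = function(e)
    stats::setNames(rep("a", nlevels(g)), levels(g)))
  list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
       letters = letters[levels(g)], group_means = means,
       n_per_group = table(g))
}

#' Topological characterisation of a co-occurrence network
#'
#' Computes every node-level property (degree, closeness, betweenness,
#' eigenvector centrality, module membership, Zi, Pi, role) and, when a
#' [niche_classify()] result is supplied, carries the niche label and B
#' value along so niche-topology relationships can be examined.
#'
#' @param net a `cooccur_net` or igraph object.
#' @param classification optional `niche_class` object.
#' @param seed seed for module detection.
#' @param ec_components compute eigenvector centrality per component
#'   instead of on the full graph.
#' @return An object of class `topology_report`: list with `nodes`
#'   (per-node data.frame), `modularity`, `graph`.
#' @export
network_topology <- function(net, classification = NULL, seed = 1L,
                             ec_components = FALSE) {
  g <- check_simple(as_graph(net))
  nodes <- igraph::V(g)$name
  deg <- degree_centrality(g)
  clo <- closeness_centrality(g)
  bet <- betweenness_centrality(g)
  eig <- eigen_centrality_scores(g, components = ec_components)
  if (igraph::ecount(g) > 0L) {
    mod <- detect_modules(g, seed = seed)
    zp <- zi_pi(g, mod$membership)
    module_id <- mod$membership[nodes]
    Q <- mod$modularity
  } else {
    zp <- data.frame(node = nodes, zi = 0, pi = 0, role = "peripheral",
                     stringsAsFactors = FALSE)
    module_id <- stats::setNames(seq_along(nodes), nodes)
    Q <- NA_real_
  }
  df <- data.frame(node = nodes, degree = as.integer(deg[nodes]),
                   closeness = clo[nodes], betweenness = bet[nodes],
                   eigenvector = eig[nodes],
                   module_id = as.integer(module_id[nodes]),
                   zi = zp$zi[match(nodes, zp$node)],
                   pi = zp$pi[match(nodes, zp$node)],
                   role = zp$role[match(nodes, zp$node)],
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(classification)) {
    stopifnot(inherits(classification, "niche_class"))
    res <- classification$results
    ix <- match(df$node, res$otu_id)
    df$niche_label <- res$label[ix]
    df$b_global <- res$b_global[ix]
  }
  structure(list(nodes = df, modularity = Q, graph = g),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Topology report over", nrow(x$nodes), "nodes;",
      igraph::ecount(x$graph), "edges; modularity Q =",
      format(x$modularity, digits = 4), "\n")
  print(table(x$nodes$role))
  invisible(x)
}

#' @export
summary.topology_report <- function(object, ...) {
  df <- object$nodes
  out <- list(n_nodes = nrow(df), modularity = object$modularity,
              roles = table(df$role),
              degree_summary = summary(df$degree))
  if (!is.null(df$niche_label))
    out$mean_degree_by_label <- tapply(df$degree, df$niche_label, mean)
  class(out) <- "summary.topology_report"
  out
}

#' @export
print.summary.topology_report <- function(x, ...) {
  cat("nodes:", x$n_nodes, " modularity:", format(x$modularity, digits = 4),
      "\n")
  print(x$roles)
  if (!is.null(x$mean_degree_by_label)) {
    cat("mean degree by niche label:\n")
    print(round(x$mean_degree_by_label, 2))
  }
  invisible(x)
}

#' Niche breadth ~ centrality regressions
#'
#' The linear models relating each node's global B value to its closeness
#' and betweenness centrality.
#' @param topology a `topology_report` containing niche labels/B values.
#' @return list of [regress()] summaries, one per centrality.
#' @export
b_centrality_regressions <- function(topology) {
  stopifnot(inherits(topology, "topology_report"))
  df <- topology$nodes
  if (is.null(df$b_global))
    stop("topology report carries no B values; pass a classification to ",
         "network_topology()")
  safe <- function(x, y) tryCatch(regress(x, y), error = function(e) {
    warning("regression skipped: ", conditionMessage(e))
    NULL
  })
  out <- list(closeness = safe(df$closeness, df$b_global),
              betweenness = safe(df$betweenness, df$b_global))
  out[!vapply(out, is.null, logical(1))]
}

#' Write a topology report as TSV
#' @param topology a `topology_report`.
#' @param path output path.
#' @export
write_topology <- function(topology, path) {
  utils::write.table(topology$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
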