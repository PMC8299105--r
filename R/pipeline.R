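#' Derive a stage seed from the master seed
#'
#' Each pipeline stage draws its randomness from a seed derived
#' deterministically from the master seed and the stage name, so stages are
#' independently reproducible.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 101) %% 2147483629)
}

#' Pipeline configuration
#'
#' Exactly one input source must be given: either `otu_table` + `metadata`
#' file paths, or a [synthetic_spec()].
#'
#' @param otu_table,metadata input file paths (TSV / BIOM-JSON).
#' @param synthetic a [synthetic_spec()].
#' @param out_dir output directory (created if absent).
#' @param rarefy_depth reads per sample for rarefaction (`NULL` = skip).
#' @param classification a [classification_config()].
#' @param network a [network_config()].
#' @param dag path to a [parse_path_model()] declaration (`NULL` = the
#'   default synthetic driver DAG in synthetic mode).
#' @param sem_n samples drawn for the synthetic driver dataset.
#' @param seed master seed.
#' @param verbose emit timestamped progress lines.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(otu_table = NULL, metadata = NULL,
                            synthetic = NULL, out_dir = "fungalnet_out",
                            rarefy_depth = NULL,
                            classification = classification_config(),
                            network = network_config(),
                            dag = NULL, sem_n = 2000L, seed = 1L,
                            verbose = TRUE) {
  has_files <- !is.null(otu_table) || !is.null(metadata)
  has_syn <- !is.null(synthetic)
  if (has_files && has_syn)
    stop("give either input file paths or a synthetic spec, not both")
  if (!has_files && !has_syn)
    stop("no input: give otu_table+metadata paths or a synthetic spec")
  if (has_files && (is.null(otu_table) || is.null(metadata)))
    stop("file input needs both otu_table and metadata paths")
  if (has_syn) stopifnot(inherits(synthetic, "synthetic_spec"))
  structure(list(otu_table = otu_table, metadata = metadata,
                 synthetic = synthetic, out_dir = out_dir,
                 rarefy_depth = rarefy_depth,
                 classification = classification, network = network,
                 dag = dag, sem_n = as.integer(sem_n),
                 seed = as.integer(seed), verbose = verbose),
            class = "pipeline_config")
}

plog <- function(verbose, stage, ...) {
  if (verbose)
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: input (read or simulate), rarefaction,
#' niche-breadth classification, ensemble network inference, topology, and
#' path effects; writes every stage's table plus a JSON run manifest
#' recording all parameters, derived seeds, stage timings and input
#' checksums. Identical configuration and seed give byte-identical numeric
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fitted stage objects and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("fungalnet")),
                   master_seed = config$seed, stages = list())
  timings <- list()
  results <- list(paths = character(0L))
  stage <- "input"
  run_stage <- function(name, fun) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(fun(), error = function(e) {
      writeLines(c(paste("FAILED at stage:", name), conditionMessage(e)),
                 out("FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  # --- input -------------------------------------------------------------
  truth <- NULL
  input <- run_stage("input", function() {
    if (!is.null(config$synthetic)) {
      spec <- config$synthetic
      spec$seed <- derive_seed(config$seed, "simulate")
      plog(config$verbose, "input", "simulating community (seed ", spec$seed, ")")
      sim <- generate_community(spec)
      write_otu_table(sim$table, out("00_input_table.tsv"))
      write_sample_metadata(sim$metadata, out("00_metadata.tsv"))
      utils::write.table(sim$truth$labels, out("00_truth_labels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(sim$truth$true_edges, out("00_truth_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$input <<- list(mode = "synthetic",
                                     spec = unclass(spec)[
                                       setdiff(names(spec), "block_spec")],
                                     block_spec = lapply(spec$block_spec,
                                                         as.numeric))
      sim
    } else {
      plog(config$verbose, "input", "reading ", config$otu_table)
      tab <- read_otu_table(config$otu_table)
      md <- read_sample_metadata(config$metadata)
      check_metadata(tab, md)
      manifest$stages$input <<- list(
        mode = "files", otu_table = config$otu_table,
        metadata = config$metadata,
        checksums = as.list(tools::md5sum(c(config$otu_table,
                                            config$metadata))))
      list(table = tab, metadata = md, truth = NULL)
    }
  })
  truth <- input$truth

  # --- rarefaction -------------------------------------------------------
  table <- run_stage("rarefy", function() {
    if (is.null(config$rarefy_depth)) {
      plog(config$verbose, "rarefy", "skipped (no depth configured)")
      tab <- input$table
    } else {
      sd <- derive_seed(config$seed, "rarefy")
      plog(config$verbose, "rarefy", "depth ", config$rarefy_depth,
           " (seed ", sd, ")")
      tab <- rarefy(input$table, config$rarefy_depth, seed = sd)
      manifest$stages$rarefy <<- list(depth = config$rarefy_depth, seed = sd,
                                      dropped = attr(tab, "dropped_samples"))
    }
    write_otu_table(tab, out("01_rarefied_table.tsv"))
    tab
  })
  metadata <- input$metadata[colnames(table), , drop = FALSE]

  # --- classification ----------------------------------------------------
  classification <- run_stage("classify", function() {
    plog(config$verbose, "classify", "niche-breadth classification")
    cl <- niche_classify(table, metadata, config$classification)
    write_classification(cl, out("02_classification.tsv"))
    manifest$stages$classify <<- list(thresholds = cl$thresholds)
    cl
  })

  # --- network -----------------------------------------------------------
  net <- run_stage("network", function() {
    ncfg <- config$network
    ncfg$seed <- derive_seed(config$seed, "network")
    plog(config$verbose, "network", "ensemble inference (seed ", ncfg$seed,
         ", ", ncfg$n_permutations, " permutations)")
    nw <- infer_network(table, ncfg)
    write_edges(nw, out("03_edges.tsv"))
    write_network_graphml(nw, out("03_network.graphml"))
    manifest$stages$network <<- list(
      seed = ncfg$seed, n_permutations = ncfg$n_permutations,
      n_bootstraps = ncfg$n_bootstraps, alpha = ncfg$alpha,
      min_support = ncfg$min_support, measures = ncfg$measures,
      n_nodes = length(nw$nodes), n_edges = nrow(nw$edges))
    nw
  })

  # --- topology ----------------------------------------------------------
  topo <- run_stage("topology", function() {
    sd <- derive_seed(config$seed, "topology")
    plog(config$verbose, "topology", "centralities and modules (seed ", sd, ")")
    tp <- network_topology(net, classification, seed = sd)
    write_topology(tp, out("04_topology.tsv"))
    lines <- c(sprintf("modularity_Q\t%s", format(tp$modularity, digits = 10)))
    if (nrow(net$edges) > 0 && !is.null(tp$nodes$b_global)) {
      reg <- b_centrality_regressions(tp)
      for (nm in names(reg))
        lines <- c(lines, sprintf("regression_B_vs_%s\tslope=%.6g r2=%.6g p=%.6g n=%d",
                                  nm, reg[[nm]]$slope, reg[[nm]]$r_squared,
                                  reg[[nm]]$p_value, reg[[nm]]$n))
      grp <- sub(":.*$", "", tp$nodes$niche_label)
      an <- tryCatch(compare_degree_groups(tp$nodes$degree, grp),
                     error = function(e) NULL)
      if (!is.null(an))
        lines <- c(lines,
                   sprintf("anova_degree_by_group\tF=%.6g p=%.6g", an$F, an$p),
                   sprintf("anova_letters\t%s",
                           paste(names(an$letters), an$letters, sep = "=",
                                 collapse = " ")))
    }
    writeLines(lines, out("05_topology_summaries.tsv"))
    manifest$stages$topology <<- list(seed = sd, modularity = tp$modularity)
    tp
  })

  # --- path effects ------------------------------------------------------
  paths <- run_stage("effects", function() {
    sd <- derive_seed(config$seed, "effects")
    if (!is.null(config$dag) || is.null(config$synthetic)) {
      if (is.null(config$dag)) {
        plog(config$verbose, "effects", "skipped (no DAG declared)")
        return(NULL)
      }
      sk <- parse_path_model(config$dag)
      df <- driver_data_frame(table, metadata, classification, net)
      pm <- fit_paths(df, sk)
    } else {
      plog(config$verbose, "effects", "driver path model on synthetic data (seed ",
           sd, ")")
      dag <- default_path_dag()
      dat <- generate_sem_dataset(dag, n = config$sem_n, seed = sd)
      pm <- fit_paths(dat, dag[c("from", "to")])
    }
    write_path_model(pm, out("06_path_effects.tsv"))
    manifest$stages$effects <<- list(seed = sd, r_squared = as.list(pm$r_squared))
    pm
  })

  manifest$timings_sec <- timings
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  plog(config$verbose, "done", "outputs in ", config$out_dir)
  invisible(list(table = table, classification = classification,
                 network = net, topology = topo, paths = paths,
                 truth = truth, out_dir = config$out_dir))
}

# per-sample driver variables for file-based path analysis: covariates from
# the metadata plus generalist/specialist relative abundance and an
# edge-co-presence coexistence score
driver_data_frame <- function(table, metadata, classification, net) {
  relab <- within_sample_relabund(table)
  lab <- classification$results$label[match(rownames(table),
                                            classification$results$otu_id)]
  gen <- colSums(relab[lab == "generalist", , drop = FALSE])
  spe <- colSums(relab[startsWith(lab, "specialist"), , drop = FALSE])
  co <- rep(0, ncol(table))
  if (nrow(net$edges)) {
    pres <- unclass(table) > 0
    ia <- match(net$edges$otu_a, rownames(table))
    ib <- match(net$edges$otu_b, rownames(table))
    co <- colMeans(pres[ia, , drop = FALSE] & pres[ib, , drop = FALSE])
  }
  cov <- metadata[colnames(table),
                  setdiff(names(metadata), c("sample_id", "region")),
                  drop = FALSE]
  cbind(cov, generalist = gen, specialist = spe, coexistence = co)
}

#' Read a flat key = value pipeline configuration file
#'
#' Recognised keys: `mode` (`synthetic` or `files`), `otu_table`,
#' `metadata`, `dag`, `out_dir`, `seed`, `rarefy_depth`, `sem_n`,
#' `n_permutations`, `n_bootstraps`, `alpha`, `min_support`,
#' `auto_threshold`, and the [synthetic_spec()] fields (`n_regions`,
#' `samples_per_region`, `n_generalists`, `n_specialists_per_region`,
#' `n_medium`, `depth`). Lines starting with `#` are ignored.
#'
#' @param path config file path.
#' @param overrides named list applied on top of the file values.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    lines <- trimws(sub("#.*$", "", readLines(path)))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- trimws(strsplit(ln, "=", fixed = TRUE)[[1L]])
      if (length(parts) != 2L) stop("malformed config line: '", ln, "'")
      kv[[parts[1L]]] <- parts[2L]
    }
  }
  kv[names(overrides)] <- overrides
  num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  mode <- kv[["mode"]] %||% if (!is.null(kv[["otu_table"]])) "files" else "synthetic"
  syn <- NULL
  if (mode == "synthetic")
    syn <- synthetic_spec(
      n_regions = num("n_regions", 3L),
      samples_per_region = num("samples_per_region", 60L),
      n_generalists = num("n_generalists", 20L),
      n_specialists_per_region = num("n_specialists_per_region", 30L),
      n_medium = num("n_medium", 320L),
      depth = num("depth", 10000L))
  ncfg <- network_config(
    n_permutations = num("n_permutations", 1000L),
    n_bootstraps = num("n_bootstraps", 1000L),
    alpha = num("alpha", 0.001),
    min_support = num("min_support", 2L))
  ccfg <- classification_config(
    auto_threshold = isTRUE(as.logical(kv[["auto_threshold"]] %||% "FALSE")))
  pipeline_config(
    otu_table = kv[["otu_table"]], metadata = kv[["metadata"]],
    synthetic = syn, out_dir = kv[["out_dir"]] %||% "fungalnet_out",
    rarefy_depth = if (is.null(kv[["rarefy_depth"]])) NULL else
      num("rarefy_depth", NULL),
    classification = ccfg, network = ncfg, dag = kv[["dag"]],
    sem_n = num("sem_n", 2000L), seed = num("seed", 1L),
    verbose = !isTRUE(as.logical(kv[["quiet"]] %||% "FALSE")))
}
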