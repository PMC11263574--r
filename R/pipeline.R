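#' Default pipeline configuration
#'
#' A nested list mirroring the per-stage parameters, serializable to
#' YAML.  `stages` switches individual stages on or off; the global
#' `seed` is propagated deterministically to every stage.
#'
#' @param seed Global integer seed.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 0L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, qc = TRUE, classify = TRUE,
                  compose = TRUE, de = TRUE, gradient = TRUE,
                  spatial = TRUE),
    simulate = list(n_cells_per_sample = 560, doublet_rate = 0.05),
    qc = list(n_doublet_runs = 20, target_sum = 10000),
    classify = list(broad_resolution = 0.2, broad_n_pcs = 30,
                    subclass_resolution = 1.0, subclass_n_pcs = 20,
                    n_hvg = 1500, r_threshold = 0.49),
    compose = list(pseudocount = 0.5),
    de = list(class = "PTHLH", min_cells = 10, shrink_weight = 0.5),
    gradient = list(subclass = "PTHLH", region = "CN", n_hvg = 1200),
    spatial = list(n_perm = 1000, k = 6,
                   colocal = list(a = "PTHLH", b = "TAC3", strength = 4))
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Values present in the file override [default_pipeline_config()].
#'
#' @param path Path to a YAML config file.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = user$seed %||% 0L)
  modifyList(cfg, user)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline end to end
#'
#' Executes simulate -> qc -> classify -> compose -> de -> gradient ->
#' spatial in order, honouring the stage switches, writing per-stage
#' TSV outputs and a machine-readable `manifest.json` (seeds,
#' parameters, per-stage cell funnel) to `out_dir`.  A stage failure
#' halts the run with an error naming the stage; outputs of completed
#' stages are preserved.
#'
#' @param config A configuration list ([default_pipeline_config()]) or
#'   path to a YAML file.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("striatax")),
                   seed = config$seed, parameters = config, stages = list())
  res <- list()
  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) {
      manifest$stages[[name]] <<- list(skipped = TRUE)
      return(invisible(NULL))
    }
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    gc(verbose = FALSE)
    manifest$stages[[name]] <<- c(list(skipped = FALSE), out$manifest)
    res[[name]] <<- out$value
  }

  run_stage("simulate", function() {
    gc_cfg <- default_taxonomy_config(
      seed = config$seed,
      n_cells_per_sample = config$simulate$n_cells_per_sample,
      doublet_rate = config$simulate$doublet_rate)
    ds <- generate_dataset(gc_cfg)
    write_dataset(ds, file.path(out_dir, "simulate"))
    list(value = ds, manifest = list(n_cells = nrow(ds$counts$counts),
                                     n_genes = ncol(ds$counts$counts)))
  })

  run_stage("qc", function() {
    cm <- res$simulate$counts
    t <- qc_thresholds(n_doublet_runs = config$qc$n_doublet_runs)
    qc <- qc_cascade(cm, t, seed = config$seed + 11L,
                     target_sum = config$qc$target_sum)
    utils::write.table(qc$funnel, file.path(out_dir, "qc_funnel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = qc,
         manifest = list(funnel = qc$funnel,
                         cells_in = nrow(cm$counts),
                         cells_out = length(qc$kept)))
  })

  run_stage("classify", function() {
    cm <- res$simulate$counts
    kept <- if (isTRUE(config$stages$qc)) res$qc$kept else cm$cell_ids
    sub <- subset_cells(cm, kept)
    norm <- normalize_log(sub, target_sum = config$qc$target_sum)
    hv <- select_hvg(norm, n = config$classify$n_hvg)
    broad <- embed_cluster(norm, hv, n_pcs = config$classify$broad_n_pcs,
                           resolution = config$classify$broad_resolution,
                           seed = config$seed + 21L)
    types <- label_clusters_by_markers(norm, broad)
    neuron_cells <- names(broad)[types[as.character(broad)] == "neurons"]
    neuron_cells <- neuron_quality_refilter(sub, neuron_cells)
    norm_n <- subset_norm(norm, neuron_cells)
    broad_n <- broad[neuron_cells]
    inter <- select_interneurons(norm_n, broad_n)
    norm_i <- subset_norm(norm, inter)
    sc <- subclass_clustering(norm_i,
                              n_hvg = config$classify$n_hvg,
                              n_pcs = config$classify$subclass_n_pcs,
                              resolution = config$classify$subclass_resolution,
                              seed = config$seed + 31L)
    norm_f <- subset_norm(norm, names(sc$labels))
    mg <- merge_subclasses(norm_f, sc$labels,
                           r_threshold = config$classify$r_threshold)
    markers <- rank_marker_genes(norm_f, sc$labels)
    labs <- data.frame(cell_id = names(sc$labels),
                       subclass = as.integer(sc$labels),
                       class = as.integer(mg$classes),
                       stringsAsFactors = FALSE)
    utils::write.table(labs, file.path(out_dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(utils::head(markers[markers$p_adj < 0.05, ], 5000),
                       file.path(out_dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(mg$newick, file.path(out_dir, "dendrogram.nwk"))
    list(value = list(norm = norm, labels = sc$labels, merged = mg,
                      interneurons = inter, markers = markers),
         manifest = list(n_interneurons = length(inter),
                         n_kept = length(sc$labels),
                         n_subclasses = length(unique(sc$labels)),
                         n_classes = length(unique(mg$class_of))))
  })

  run_stage("compose", function() {
    cls <- res$classify
    meta <- res$simulate$counts$cell_meta
    tab <- class_fractions(cls$merged$classes, meta)
    tab <- compute_clr(tab, pseudocount = config$compose$pseudocount)
    test <- region_composition_test(tab)
    utils::write.table(tab, file.path(out_dir, "composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(test, file.path(out_dir, "composition_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = list(table = tab, test = test),
         manifest = list(n_classes = length(unique(tab$class))))
  })

  truth_subclass <- function() {
    tr <- res$simulate$truth
    stats::setNames(tr$population, tr$cell_id)
  }

  run_stage("de", function() {
    cls <- res$classify
    truth <- truth_subclass()
    # analyse the configured subclass (by planted population name)
    target_cells <- names(cls$labels)[
      truth[names(cls$labels)] == config$de$class]
    lab <- stats::setNames(rep(config$de$class, length(target_cells)),
                           target_cells)
    pb <- aggregate_pseudobulk(res$simulate$counts, lab,
                               min_cells = config$de$min_cells)
    det <- nb_glm_lrt(pb, shrink_weight = config$de$shrink_weight)
    degs <- select_degs(det)
    utils::write.table(det, file.path(out_dir, "de_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = list(results = det, degs = degs),
         manifest = list(n_up = length(degs$up), n_down = length(degs$down)))
  })

  run_stage("gradient", function() {
    cls <- res$classify
    truth <- truth_subclass()
    meta <- res$simulate$counts$cell_meta
    cells <- names(cls$labels)[
      truth[names(cls$labels)] == config$gradient$subclass &
        meta[names(cls$labels), "region"] == config$gradient$region]
    fa <- factor_analysis_single(subset_norm(cls$norm, cells),
                                 n_hvg = config$gradient$n_hvg)
    utils::write.table(
      data.frame(cell_id = names(fa$scores), value = fa$scores),
      file.path(out_dir, "factor.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(gene = names(fa$weights), weight = fa$weights),
      file.path(out_dir, "weights.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(value = fa, manifest = list(n_cells = length(fa$scores),
                                     n_genes = length(fa$weights)))
  })

  run_stage("spatial", function() {
    truth <- truth_subclass()
    cls <- res$classify
    labs <- truth[names(cls$labels)]
    co <- config$spatial$colocal
    sp <- generate_spatial(unname(labs),
                           colocal_pairs = list(co),
                           seed = config$seed + 41L)
    g <- build_neighbor_graph(sp[, c("x", "y")], k = config$spatial$k)
    ne <- neighborhood_enrichment(g, sp$label,
                                  n_perm = config$spatial$n_perm,
                                  seed = config$seed + 43L)
    utils::write.table(as.data.frame(ne$z),
                       file.path(out_dir, "neighborhood_z.tsv"),
                       sep = "\t", quote = FALSE)
    list(value = list(spatial = sp, enrichment = ne),
         manifest = list(n_cells = nrow(sp),
                         method = igraph::graph_attr(g, "method")))
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = res, manifest = manifest))
}
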