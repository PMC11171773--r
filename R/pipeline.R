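#' Run configuration with the model's default thresholds
#'
#' Collects every tunable threshold of the pipeline in one serializable
#' list. Defaults follow the model's stated operating point: IF reliability
#' threshold 0.86, DEG criteria FDR 0.1 / fold change 1.5, 10,000 null
#' draws, driver and TF significance 0.05, callback window 5 segments,
#' top-10% frequency cut, clustering boost 2.
#'
#' @param if_threshold,fdr,fc,null_draws,driver_alpha,tf_alpha,window
#'   see description.
#' @param top_frac,z_alpha,boost,resolution see description.
#' @param driver_mechanisms mechanism view for the dysregulation stage.
#' @param include_low_confidence traverse low-IF edges during path search.
#' @param bw_adjust KDE bandwidth multiplier.
#' @param seed root seed; per-stage seeds are derived from it.
#' @return Named list of class `tcs_config`.
#' @export
tcs_config <- function(if_threshold = 0.86, fdr = 0.1, fc = 1.5,
                       null_draws = 10000, driver_alpha = 0.05,
                       tf_alpha = 0.05, window = 5, top_frac = 0.10,
                       z_alpha = 0.05, boost = 2, resolution = 1,
                       driver_mechanisms = c("correlation",
                                             "transcriptional_regulation"),
                       include_low_confidence = FALSE, bw_adjust = 1,
                       seed = 1) {
  structure(list(if_threshold = if_threshold, fdr = fdr, fc = fc,
                 null_draws = null_draws, driver_alpha = driver_alpha,
                 tf_alpha = tf_alpha, window = window, top_frac = top_frac,
                 z_alpha = z_alpha, boost = boost, resolution = resolution,
                 driver_mechanisms = driver_mechanisms,
                 include_low_confidence = include_low_confidence,
                 bw_adjust = bw_adjust, seed = seed),
            class = "tcs_config")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  out <- df
  for (j in which(num)) out[[j]] <- sprintf("%.10g", df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full temporal causal signaling pipeline
#'
#' For every adjacent timepoint pair: DEG calling, primary-driver
#' dysregulation analysis, upstream-regulator enrichment and driver-to-TF
#' shortest-path collection; then cross-segment frequency/callback pruning,
#' hypernode clustering, and (when an annotation is supplied) the GO
#' information-flow network. All stage outputs are written as fixed-name
#' TSV/GraphML files plus a `manifest.json` recording the configuration,
#' derived seeds and per-stage row counts; re-running with the same inputs
#' and config reproduces the outputs byte-identically.
#'
#' @param series an [expression_series()].
#' @param net a [knowledge_network()] (virtual expansion and IF flagging are
#'   applied here).
#' @param outdir output directory (created if needed).
#' @param config a [tcs_config()].
#' @param regulons,complexes optional cluster-weighting side information.
#' @param annotation optional `term_annotation` for the GO flow view.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_all <- function(series, net, outdir, config = tcs_config(),
                    regulons = list(), complexes = list(),
                    annotation = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  info <- function(fmt, ...) {
    message(sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(fmt, ...)))
  }
  net <- filter_by_if(net, config$if_threshold)
  net <- expand_virtual(net)
  segs <- segments_of(series)
  counts <- list()
  degs_all <- list()
  drivers_all <- list()
  tfs_all <- list()
  pathsets <- list()
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    lab <- segment_label(seg)
    flab <- gsub(":", "_", lab, fixed = TRUE)
    info("segment %s: DEGs", lab)
    degs <- call_degs(series, seg, fdr_threshold = config$fdr,
                      fc_threshold = config$fc)
    write_tsv(degs$stats, file.path(outdir, sprintf("degs_%s.tsv", flab)))
    info("segment %s: drivers", lab)
    drv <- run_driver_analysis(series, seg, net,
                               mechanisms = config$driver_mechanisms,
                               null_draws = config$null_draws,
                               driver_alpha = config$driver_alpha,
                               seed = derive_seed(config$seed,
                                                  paste0("drivers_", lab)),
                               bw_adjust = config$bw_adjust)
    write_tsv(drv$genes, file.path(outdir, sprintf("drivers_%s.tsv", flab)))
    info("segment %s: TF enrichment", lab)
    tfs <- run_enrichment(degs, net, tf_alpha = config$tf_alpha)
    write_tsv(as.data.frame(tfs),
              file.path(outdir, sprintf("tfs_%s.tsv", flab)))
    info("segment %s: paths", lab)
    ps <- suppressWarnings(
      collect_segment_paths(drv, tfs, net, segment = seg,
                            include_low_confidence =
                              config$include_low_confidence))
    write_tsv(paths_as_table(ps),
              file.path(outdir, sprintf("paths_%s.tsv", flab)))
    degs_all[[lab]] <- degs
    drivers_all[[lab]] <- drv
    tfs_all[[lab]] <- tfs
    pathsets[[lab]] <- ps
    counts[[lab]] <- list(degs_up = length(degs$up),
                          degs_down = length(degs$down),
                          drivers = sum(drv$genes$is_driver),
                          tf_calls = sum(tfs$significant),
                          paths = length(ps$paths))
  }
  any_paths <- any(vapply(pathsets, function(p) length(p$paths) > 0L,
                          logical(1L)))
  pruned <- NULL
  hyper <- NULL
  if (any_paths) {
    info("temporal pruning")
    stats <- node_frequencies(pathsets)
    pruned <- prune_network(stats, pathsets, net = net,
                            top_frac = config$top_frac,
                            window = config$window,
                            z_alpha = config$z_alpha)
    write_tsv(pruned$node_stats, file.path(outdir, "temporal_stats.tsv"))
    gpr <- igraph::graph_from_data_frame(
      pruned$kept_edges, directed = TRUE,
      vertices = sort(unique(c(pruned$kept_nodes, pruned$kept_edges$source,
                               pruned$kept_edges$target))))
    igraph::write_graph(gpr, file.path(outdir, "pruned.graphml"),
                        format = "graphml")
    info("hypernode clustering")
    wg <- weight_for_clustering(pruned, regulons = regulons,
                                complexes = complexes, boost = config$boost)
    if (igraph::vcount(wg) > 0L) {
      hn <- louvain_hypernodes(wg, seed = derive_seed(config$seed, "louvain"),
                               resolution = config$resolution)
      hyper <- aggregate_hyperedges(pruned, hn)
      memb <- do.call(rbind, lapply(hn, function(h) {
        data.frame(node = h$members, hypernode = h$id, label = h$label,
                   stringsAsFactors = FALSE)
      }))
      write_tsv(memb, file.path(outdir, "hypernodes.tsv"))
      write_tsv(hyper$hyperedges, file.path(outdir, "hyperedges.tsv"))
    }
  } else {
    info("no collected paths; skipping temporal pruning and hypergraph")
  }
  goflow <- NULL
  if (!is.null(annotation) && length(segs) >= 2L) {
    info("GO information flow")
    degsets <- lapply(degs_all, function(d) union(d$up, d$down))
    selections <- lapply(degsets, function(dg) {
      if (length(dg) == 0L) character() else
        suppressWarnings(greedy_select_terms(dg, annotation))
    })
    goflow <- build_flow_network(selections, annotation, degsets)
    write_tsv(goflow$nodes, file.path(outdir, "goflow_nodes.tsv"))
    write_tsv(goflow$edges, file.path(outdir, "goflow_edges.tsv"))
  }
  manifest <- list(
    package = "tcsnet",
    version = as.character(utils::packageVersion("tcsnet")),
    config = unclass(config),
    derived_seeds = c(
      stats::setNames(
        lapply(names(pathsets), function(lab)
          derive_seed(config$seed, paste0("drivers_", lab))),
        paste0("drivers_", names(pathsets))),
      list(louvain = derive_seed(config$seed, "louvain"))),
    n_genes = length(series$genes),
    n_samples = ncol(series$values),
    n_network_nodes = nrow(net$nodes),
    n_network_edges = nrow(net$edges),
    segments = counts,
    kept_nodes = if (is.null(pruned)) 0L else length(pruned$kept_nodes),
    hypernodes = if (is.null(hyper)) 0L else length(hyper$hypernodes))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  info("done")
  invisible(list(degs = degs_all, drivers = drivers_all, tfs = tfs_all,
                 pathsets = pathsets, pruned = pruned, hypergraph = hyper,
                 goflow = goflow, manifest = manifest))
}
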