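PATH_MECHANISMS <- c("transcriptional_regulation", "ppi", "metabolic",
                     "virtual")

#' Directed signaling view of a network for path search
#'
#' Builds the igraph used for shortest-path collection: transcriptional,
#' metabolic and virtual edges forward only, PPI edges in both directions,
#' correlation edges excluded (they feed the dysregulation statistic, not
#' causal routing). Low-confidence edges are dropped by default; duplicate
#' edges between the same ordered pair collapse to the max-IF representative.
#'
#' @param net a [knowledge_network()].
#' @param include_low_confidence traverse flagged edges too (default FALSE).
#' @return An igraph directed graph with edge attributes `sign`, `mechanism`,
#'   `if_score`.
#' @export
path_view <- function(net, include_low_confidence = FALSE) {
  e <- net$edges[net$edges$mechanism %in% PATH_MECHANISMS, , drop = FALSE]
  if (!include_low_confidence) {
    e <- e[!e$low_confidence, , drop = FALSE]
  }
  if (nrow(e) > 0L) {
    und <- e[!e$directed, , drop = FALSE]
    if (nrow(und) > 0L) {
      rev <- und
      rev$source <- und$target
      rev$target <- und$source
      e <- rbind(e, rev)
    }
    # max-IF representative per ordered pair
    key <- paste(e$source, e$target, sep = "\r")
    e <- e[order(key, -e$if_score), , drop = FALSE]
    e <- e[!duplicated(paste(e$source, e$target, sep = "\r")), , drop = FALSE]
  }
  igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target, sign = e$sign,
               mechanism = e$mechanism, if_score = e$if_score,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = sort(unique(c(e$source, e$target))))
}

#' All shortest signaling paths between driver and TF sets
#'
#' Breadth-first search with unit edge cost from every source to every
#' target on the directed signaling view; for each reachable pair, all
#' minimum-length directed paths are retained (downstream frequency
#' statistics depend on path multiplicity). Unreachable or absent pairs are
#' recorded with a reason code. A pair with identical source and target
#' yields the trivial single-node path.
#'
#' @param net a [knowledge_network()] or a prebuilt igraph from
#'   [path_view()].
#' @param sources,targets character vectors of node ids.
#' @param segment optional timepoint pair label carried in the result.
#' @param include_low_confidence passed to [path_view()].
#' @return Object of class `path_set`: `segment`, `paths` (list of node-id
#'   vectors, lexicographically ordered), `pairs` (data frame source, target,
#'   length, n_paths) and `unreachable` (data frame source, target, reason).
#' @export
find_signal_paths <- function(net, sources, targets, segment = NULL,
                              include_low_confidence = FALSE) {
  stopifnot(length(sources) > 0L, length(targets) > 0L)
  g <- if (inherits(net, "igraph")) net else {
    path_view(net, include_low_confidence)
  }
  vnames <- igraph::V(g)$name
  sources <- unique(sources)
  targets <- unique(targets)
  paths <- list()
  pairs <- list()
  unreach <- list()
  for (s in sort(sources)) {
    if (!(s %in% vnames)) {
      unreach[[length(unreach) + 1L]] <-
        data.frame(source = s, target = sort(targets),
                   reason = "source_absent_from_view",
                   stringsAsFactors = FALSE)
      next
    }
    for (t in sort(targets)) {
      if (s == t) {
        paths[[length(paths) + 1L]] <- s
        pairs[[length(pairs) + 1L]] <-
          data.frame(source = s, target = t, length = 0L, n_paths = 1L,
                     stringsAsFactors = FALSE)
        next
      }
      if (!(t %in% vnames)) {
        unreach[[length(unreach) + 1L]] <-
          data.frame(source = s, target = t,
                     reason = "target_absent_from_view",
                     stringsAsFactors = FALSE)
        next
      }
      sp <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t, mode = "out"))
      if (length(sp$vpaths) == 0L) {
        unreach[[length(unreach) + 1L]] <-
          data.frame(source = s, target = t, reason = "no_path",
                     stringsAsFactors = FALSE)
        next
      }
      np <- lapply(sp$vpaths, function(v) vnames[as.integer(v)])
      np <- np[order(vapply(np, paste, character(1L), collapse = ">"))]
      paths <- c(paths, np)
      pairs[[length(pairs) + 1L]] <-
        data.frame(source = s, target = t, length = length(np[[1L]]) - 1L,
                   n_paths = length(np), stringsAsFactors = FALSE)
    }
  }
  bind <- function(x, proto) if (length(x) > 0L) do.call(rbind, x) else proto
  structure(list(
    segment = segment,
    paths = paths,
    pairs = bind(pairs, data.frame(source = character(), target = character(),
                                   length = integer(), n_paths = integer())),
    unreachable = bind(unreach,
                       data.frame(source = character(), target = character(),
                                  reason = character()))),
    class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("path_set%s: %d paths over %d reachable pairs (%d unreachable)\n",
              if (is.null(x$segment)) "" else paste0(" ",
                                                     segment_label(x$segment)),
              length(x$paths), nrow(x$pairs), nrow(x$unreachable)))
  invisible(x)
}

#' Collect driver-to-TF shortest paths for one segment
#'
#' Binds the outputs of the driver analysis and the regulator enrichment:
#' sources are genes flagged as primary regulatory drivers, targets the
#' significant TF calls (deduplicated over pseudo states), connected by
#' [find_signal_paths()]. A driver that is itself a significant TF
#' contributes its trivial single-node path.
#'
#' @param drivers a `driver_analysis` (or its `genes` data frame).
#' @param tfs a `regulator_calls` data frame.
#' @param net a [knowledge_network()].
#' @param segment timepoint pair label.
#' @param include_low_confidence passed to [path_view()].
#' @return A `path_set` (empty, with a warning, if either side is empty).
#' @export
collect_segment_paths <- function(drivers, tfs, net, segment = NULL,
                                  include_low_confidence = FALSE) {
  gd <- if (inherits(drivers, "driver_analysis")) drivers$genes else drivers
  src <- gd$gene[gd$is_driver]
  tgt <- unique(tfs$regulator[tfs$significant])
  if (length(src) == 0L || length(tgt) == 0L) {
    warning("segment ", if (is.null(segment)) "" else segment_label(segment),
            ": no significant ",
            if (length(src) == 0L) "drivers" else "TFs",
            "; empty path set")
    return(structure(list(segment = segment, paths = list(),
                          pairs = data.frame(source = character(),
                                             target = character(),
                                             length = integer(),
                                             n_paths = integer()),
                          unreachable = data.frame(source = character(),
                                                   target = character(),
                                                   reason = character())),
                     class = "path_set"))
  }
  find_signal_paths(net, src, tgt, segment = segment,
                    include_low_confidence = include_low_confidence)
}

#' Flatten a path set to a data frame
#'
#' @param ps a `path_set`.
#' @return Data frame with columns segment, source, target, length, path
#'   (node ids joined by `>`).
#' @export
paths_as_table <- function(ps) {
  if (length(ps$paths) == 0L) {
    return(data.frame(segment = character(), source = character(),
                      target = character(), length = integer(),
                      path = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    segment = if (is.null(ps$segment)) "" else segment_label(ps$segment),
    source = vapply(ps$paths, `[`, character(1L), 1L),
    target = vapply(ps$paths, function(p) p[length(p)], character(1L)),
    length = vapply(ps$paths, length, integer(1L)) - 1L,
    path = vapply(ps$paths, paste, character(1L), collapse = ">"),
    stringsAsFactors = FALSE)
}
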