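#' Propagate gene annotations up the GO parent graph
#'
#' Closes a raw term-to-gene annotation under the is-a parent relation: each
#' term's gene set becomes the union over itself and all of its descendants,
#' so a gene annotated to a term is annotated to every ancestor. The parent
#' graph must be acyclic.
#'
#' @param term_genes named list: term id -> character vector of gene ids.
#' @param parents named list: term id -> character vector of parent term ids.
#' @return Object of class `term_annotation` with the closed `term_genes`
#'   and the `parents` map.
#' @export
propagate_ancestors <- function(term_genes, parents) {
  terms <- unique(c(names(term_genes), names(parents),
                    unlist(parents, use.names = FALSE)))
  edges <- do.call(rbind, lapply(names(parents), function(tm) {
    if (length(parents[[tm]]) == 0L) return(NULL)
    cbind(tm, parents[[tm]])
  }))
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1L], to = edges[, 2L],
                 stringsAsFactors = FALSE),
      directed = TRUE, vertices = terms)
    if (!igraph::is_dag(g)) {
      cyc <- igraph::feedback_arc_set(g)
      ends <- igraph::ends(g, cyc[1L])
      stop(sprintf("parent graph has a cycle through edge %s -> %s",
                   ends[1L], ends[2L]))
    }
    order <- igraph::topo_sort(g, mode = "out")$name
  } else {
    order <- terms
  }
  closed <- stats::setNames(vector("list", length(terms)), terms)
  for (tm in terms) closed[[tm]] <- unique(term_genes[[tm]])
  # child-to-parent edges: visiting children before parents pushes genes up
  for (tm in order) {
    for (pa in parents[[tm]]) {
      closed[[pa]] <- union(closed[[pa]], closed[[tm]])
    }
  }
  closed <- lapply(closed, function(g) if (is.null(g)) character() else
    sort(g))
  structure(list(term_genes = closed, parents = parents),
            class = "term_annotation")
}

#' Read term-to-gene and term-to-parent annotation TSVs
#'
#' Both files are two-column TSVs with headers (`term_id`, `gene_id` and
#' `term_id`, `parent_id`); the annotation is returned already propagated.
#'
#' @param annotation_path term-to-gene TSV.
#' @param parent_path optional term-to-parent TSV.
#' @return A `term_annotation` (see [propagate_ancestors()]).
#' @export
read_annotation <- function(annotation_path, parent_path = NULL) {
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  term_genes <- lapply(split(as.character(ann[[2L]]),
                             as.character(ann[[1L]])), unique)
  parents <- list()
  if (!is.null(parent_path)) {
    pp <- utils::read.delim(parent_path, stringsAsFactors = FALSE)
    parents <- lapply(split(as.character(pp[[2L]]),
                            as.character(pp[[1L]])), unique)
  }
  propagate_ancestors(term_genes, parents)
}

#' Greedy GO term selection covering a DEG set
#'
#' Restricts candidates to terms covering at most `coverage_ceiling` of the
#' DEG set (excluding overly general terms), then iteratively picks the term
#' adding the most not-yet-covered DEGs. Selection stops when the best
#' candidate adds fewer than `min_new` genes or when more than `max_overlap`
#' of its DEG hits are already covered. Ties are broken by smaller total
#' term size, then lexicographic term id.
#'
#' @param degs character vector of DEG ids.
#' @param ann a `term_annotation`.
#' @param coverage_ceiling maximum admissible coverage fraction (default
#'   0.5).
#' @param min_new minimum number of newly covered genes per accepted term
#'   (default 3).
#' @param max_overlap maximum tolerated overlap fraction of a candidate's
#'   DEG hits with already covered genes (default 0.5).
#' @return Character vector of selected term ids in selection order (empty,
#'   with a warning, when no term is admissible).
#' @export
greedy_select_terms <- function(degs, ann, coverage_ceiling = 0.5,
                                min_new = 3, max_overlap = 0.5) {
  stopifnot(length(degs) > 0L, inherits(ann, "term_annotation"))
  degs <- unique(degs)
  hits <- lapply(ann$term_genes, function(g) intersect(g, degs))
  sizes <- vapply(ann$term_genes, length, integer(1L))
  admissible <- vapply(hits, length, integer(1L)) / length(degs) <=
    coverage_ceiling
  cand <- names(hits)[admissible & vapply(hits, length, integer(1L)) > 0L]
  if (length(cand) == 0L) {
    warning("no admissible GO terms for this DEG set")
    return(character())
  }
  covered <- character()
  selected <- character()
  repeat {
    new_n <- vapply(cand, function(tm) length(setdiff(hits[[tm]], covered)),
                    integer(1L))
    best_n <- max(new_n)
    if (best_n < min_new) break
    tied <- cand[new_n == best_n]
    tied <- tied[order(sizes[tied], tied)]
    best <- tied[1L]
    ov <- length(intersect(hits[[best]], covered)) /
      max(length(hits[[best]]), 1L)
    if (ov > max_overlap) break
    selected <- c(selected, best)
    covered <- union(covered, hits[[best]])
    cand <- setdiff(cand, best)
    if (length(cand) == 0L) break
  }
  selected
}

#' Build the GO information-flow network across segments
#'
#' One node per (selected term, segment) with the term's covered DEGs; an
#' edge connects nodes of adjacent segments whose covered-gene sets share
#' at least one gene, weighted by the intersection size.
#'
#' @param selections list (one element per segment, temporal order) of
#'   selected term id vectors.
#' @param ann a `term_annotation`.
#' @param degs_per_segment list of DEG id vectors parallel to `selections`.
#' @return Object of class `goflow_network`: `nodes` (data frame term,
#'   segment, n_covered), `edges` (data frame term1, segment1, term2,
#'   segment2, weight) and `covered` (list of per-node covered gene sets).
#' @export
build_flow_network <- function(selections, ann, degs_per_segment) {
  stopifnot(length(selections) >= 2L,
            length(selections) == length(degs_per_segment))
  covered <- list()
  nodes <- list()
  for (s in seq_along(selections)) {
    for (tm in selections[[s]]) {
      key <- paste(tm, s, sep = "@")
      covered[[key]] <- sort(intersect(ann$term_genes[[tm]],
                                       degs_per_segment[[s]]))
      nodes[[key]] <- data.frame(term = tm, segment = s,
                                 n_covered = length(covered[[key]]),
                                 stringsAsFactors = FALSE)
    }
  }
  edges <- list()
  for (s in seq_len(length(selections) - 1L)) {
    for (t1 in selections[[s]]) {
      for (t2 in selections[[s + 1L]]) {
        w <- length(intersect(covered[[paste(t1, s, sep = "@")]],
                              covered[[paste(t2, s + 1L, sep = "@")]]))
        if (w >= 1L) {
          edges[[length(edges) + 1L]] <-
            data.frame(term1 = t1, segment1 = s, term2 = t2,
                       segment2 = s + 1L, weight = w,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  bind <- function(x, proto) if (length(x) > 0L) do.call(rbind, x) else proto
  structure(list(
    nodes = bind(unname(nodes),
                 data.frame(term = character(), segment = integer(),
                            n_covered = integer())),
    edges = bind(edges, data.frame(term1 = character(), segment1 = integer(),
                                   term2 = character(), segment2 = integer(),
                                   weight = integer())),
    covered = covered),
    class = "goflow_network")
}

#' @export
print.goflow_network <- function(x, ...) {
  cat(sprintf("goflow_network: %d term nodes, %d cross-segment edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
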