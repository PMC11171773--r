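#' Weighted undirected graph for hypernode clustering
#'
#' Drops edge direction on the pruned network and assigns each edge base
#' weight 1, multiplied once by `boost` when both endpoints belong to a
#' common regulon (regulator plus its targets) or a common complex — regulons
#' and complexes tend to operate collectively, so clustering should prefer
#' to keep them together. Parallel kept edges between the same unordered
#' pair accumulate their weights.
#'
#' @param pruned a `pruned_network` (see [prune_network()]).
#' @param regulons named list: regulator id -> character vector of targets.
#' @param complexes list of character vectors of member ids.
#' @param boost multiplicative up-weighting factor, >= 1 (default 2).
#' @return An igraph undirected graph with edge attribute `weight`.
#' @export
weight_for_clustering <- function(pruned, regulons = list(),
                                  complexes = list(), boost = 2) {
  stopifnot(boost >= 1)
  ke <- pruned$kept_edges
  if (nrow(ke) == 0L) {
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(pruned$kept_nodes))
  }
  lo <- pmin(ke$source, ke$target)
  hi <- pmax(ke$source, ke$target)
  w <- stats::aggregate(list(weight = rep(1, length(lo))),
                        by = list(a = lo, b = hi), FUN = sum)
  groups <- c(lapply(names(regulons), function(r) {
    unique(c(r, regulons[[r]]))
  }), complexes)
  shared <- mapply(function(a, b) {
    any(vapply(groups, function(g) a %in% g && b %in% g, logical(1L)))
  }, w$a, w$b)
  w$weight <- w$weight * ifelse(shared, boost, 1)
  g <- igraph::graph_from_data_frame(
    data.frame(from = w$a, to = w$b, weight = w$weight,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = sort(unique(c(pruned$kept_nodes, w$a, w$b))))
  g
}

#' Louvain hypernode clustering
#'
#' Modularity-optimizing Louvain communities on the weighted undirected
#' graph; each community becomes a hypernode. Isolated nodes form singleton
#' hypernodes. The hypernode label is the most frequent member annotation
#' (ties broken lexicographically), or the lexicographically first member id
#' when no annotations are supplied.
#'
#' @param graph weighted undirected igraph from [weight_for_clustering()].
#' @param seed integer seed; Louvain refinement is stochastic and the seed
#'   makes the partition reproducible.
#' @param resolution Louvain resolution parameter (default 1).
#' @param annotations optional named character vector node id -> annotation.
#' @return List of hypernodes, each `list(id, members, label)`; members are
#'   sorted, hypernodes ordered by their smallest member.
#' @export
louvain_hypernodes <- function(graph, seed = 1, resolution = 1,
                               annotations = NULL) {
  stopifnot(igraph::vcount(graph) > 0L)
  comm <- with_seed(seed,
                    igraph::cluster_louvain(graph, resolution = resolution))
  memb <- igraph::membership(comm)
  groups <- split(names(memb), memb)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1L), 1L))]
  lapply(seq_along(groups), function(i) {
    members <- groups[[i]]
    label <- if (!is.null(annotations) &&
                 any(members %in% names(annotations))) {
      ann <- annotations[intersect(members, names(annotations))]
      tab <- sort(table(ann), decreasing = TRUE)
      best <- names(tab)[tab == tab[1L]]
      sort(best)[1L]
    } else {
      members[1L]
    }
    list(id = i, members = members, label = label)
  })
}

#' Aggregate kept edges into hyperedges
#'
#' For every ordered pair of distinct hypernodes with at least one
#' underlying kept edge, emits a hyperedge whose weight is the underlying
#' edge count and whose sign summary is `activation` or `repression` when
#' the signed underlying edges are unanimous, else `mixed` (also `mixed`
#' when only unsigned edges connect the pair). Intra-hypernode edges are
#' omitted.
#'
#' @param pruned a `pruned_network`.
#' @param hypernodes list from [louvain_hypernodes()].
#' @return Object of class `hypernode_network`: `hypernodes` and
#'   `hyperedges` (data frame source, target, sign, weight).
#' @export
aggregate_hyperedges <- function(pruned, hypernodes) {
  memb <- integer(0)
  for (h in hypernodes) {
    memb[h$members] <- h$id
  }
  stopifnot(all(pruned$kept_nodes %in% names(memb)))
  ke <- pruned$kept_edges
  he <- data.frame(source = integer(), target = integer(),
                   sign = character(), weight = integer(),
                   stringsAsFactors = FALSE)
  if (nrow(ke) > 0L) {
    hs <- memb[ke$source]
    ht <- memb[ke$target]
    inter <- hs != ht
    if (any(inter)) {
      df <- data.frame(source = hs[inter], target = ht[inter],
                       sign = ke$sign[inter], stringsAsFactors = FALSE)
      key <- paste(df$source, df$target)
      he <- do.call(rbind, lapply(split(df, key), function(d) {
        signed <- setdiff(unique(d$sign), "unknown")
        summary_sign <- if (length(signed) == 1L) signed else "mixed"
        data.frame(source = d$source[1L], target = d$target[1L],
                   sign = summary_sign, weight = nrow(d),
                   stringsAsFactors = FALSE)
      }))
      he <- he[order(he$source, he$target), , drop = FALSE]
      rownames(he) <- NULL
    }
  }
  structure(list(hypernodes = hypernodes, hyperedges = he),
            class = "hypernode_network")
}

#' @export
print.hypernode_network <- function(x, ...) {
  cat(sprintf("hypernode_network: %d hypernodes, %d hyperedges\n",
              length(x$hypernodes), nrow(x$hyperedges)))
  invisible(x)
}
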