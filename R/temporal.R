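#' Cross-segment node path frequencies
#'
#' The frequency of a node in a segment is its number of path memberships
#' among that segment's collected shortest paths (a node on three paths
#' counts three). Mean and standard deviation (population form) are taken
#' across all segments, counting zero where the node is absent.
#'
#' @param pathsets list of `path_set` objects, one per segment, in temporal
#'   order.
#' @return Object of class `node_temporal_stats`: `freq` (node x segment
#'   integer matrix), `mean_freq`, `sd_freq`, `segments`.
#' @export
node_frequencies <- function(pathsets) {
  stopifnot(length(pathsets) >= 1L)
  seg_labels <- vapply(seq_along(pathsets), function(i) {
    s <- pathsets[[i]]$segment
    if (is.null(s)) sprintf("seg%d", i) else segment_label(s)
  }, character(1L))
  nodes <- sort(unique(unlist(lapply(pathsets, function(ps) {
    unlist(ps$paths, use.names = FALSE)
  }))))
  freq <- matrix(0L, nrow = length(nodes), ncol = length(pathsets),
                 dimnames = list(nodes, seg_labels))
  for (i in seq_along(pathsets)) {
    counts <- table(unlist(lapply(pathsets[[i]]$paths, unique),
                           use.names = FALSE))
    if (length(counts) > 0L) {
      freq[names(counts), i] <- as.integer(counts)
    }
  }
  mean_freq <- rowMeans(freq)
  sd_freq <- sqrt(rowMeans((freq - mean_freq)^2))
  structure(list(freq = freq, mean_freq = mean_freq, sd_freq = sd_freq,
                 segments = seg_labels),
            class = "node_temporal_stats")
}

#' Detect callback regulators
#'
#' A callback regulator is a node that terminates a collected path in one
#' segment (a downstream effect) and originates a path in a strictly later
#' segment within `window` segments (it has become an upstream influencer).
#'
#' @param pathsets list of `path_set` objects in temporal order.
#' @param window maximum forward gap in segment units (default 5).
#' @return Data frame with columns `node`, `end_segment`, `reuse_segment`
#'   (1-based segment indices), one row per (end, reuse) pair.
#' @export
detect_callbacks <- function(pathsets, window = 5) {
  stopifnot(window >= 1)
  ends <- lapply(pathsets, function(ps) {
    unique(vapply(ps$paths, function(p) p[length(p)], character(1L),
                  USE.NAMES = FALSE))
  })
  starts <- lapply(pathsets, function(ps) {
    unique(vapply(ps$paths, `[`, character(1L), 1L, USE.NAMES = FALSE))
  })
  out <- list()
  for (e in seq_along(pathsets)) {
    for (r in seq_along(pathsets)) {
      gap <- r - e
      if (gap <= 0 || gap > window) next
      shared <- intersect(ends[[e]], starts[[r]])
      # a trivial single-node path makes a node both terminus and source;
      # that is reuse only across distinct segments, which r > e ensures
      if (length(shared) > 0L) {
        out[[length(out) + 1L]] <- data.frame(node = sort(shared),
                                              end_segment = e,
                                              reuse_segment = r,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(node = character(), end_segment = integer(),
                      reuse_segment = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$node, res$end_segment, res$reuse_segment), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Z-test of a node's segment frequency against its temporal mean
#'
#' `z = (observed - mean) / sd` with the node's cross-segment mean and
#' population sd; the p-value is the one-sided upper-tail standard normal
#' survival probability (significant upregulation of usage). A node with
#' zero frequency variance gets `z = 0`, `p = 1`.
#'
#' @param stats a `node_temporal_stats` (see [node_frequencies()]).
#' @param node node id.
#' @param segment segment index (column of the frequency matrix) or label.
#' @return List with `z` and `p`.
#' @export
zscore_test <- function(stats, node, segment) {
  stopifnot(inherits(stats, "node_temporal_stats"))
  obs <- unname(stats$freq[node, segment])
  s <- unname(stats$sd_freq[[node]])
  if (s == 0) return(list(z = 0, p = 1))
  z <- (obs - unname(stats$mean_freq[[node]])) / s
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Prune the cross-time network to its key regulatory nodes
#'
#' Keeps a node iff it ranks in the top `top_frac` by total path frequency
#' across all segments (ceiling count, boundary ties included) or it is a
#' detected callback regulator whose frequency Z-test in some reuse segment
#' has `p < z_alpha`. Kept edges are the path-view edges that lie on at
#' least one collected path and have both endpoints kept.
#'
#' @param stats a `node_temporal_stats`.
#' @param pathsets the list of `path_set` objects the stats came from.
#' @param net optional [knowledge_network()] used to annotate kept edges
#'   with signs.
#' @param top_frac frequency quantile kept (default 0.10).
#' @param window callback window in segments (default 5).
#' @param z_alpha callback significance level (default 0.05).
#' @return Object of class `pruned_network`: `kept_nodes`, `kept_edges`
#'   (data frame source, target, sign), `keep_reason` (named list),
#'   `node_stats` (per-node summary data frame) and `callbacks`.
#' @export
prune_network <- function(stats, pathsets, net = NULL, top_frac = 0.10,
                          window = 5, z_alpha = 0.05) {
  stopifnot(inherits(stats, "node_temporal_stats"))
  nodes <- rownames(stats$freq)
  stopifnot(length(nodes) >= 1L)
  total <- rowSums(stats$freq)
  n_keep <- ceiling(top_frac * length(nodes))
  cutoff <- sort(total, decreasing = TRUE)[n_keep]
  top_decile <- total >= cutoff
  cb <- detect_callbacks(pathsets, window = window)
  cb$z <- rep(NA_real_, nrow(cb))
  cb$p <- rep(NA_real_, nrow(cb))
  for (i in seq_len(nrow(cb))) {
    zt <- zscore_test(stats, cb$node[i], cb$reuse_segment[i])
    cb$z[i] <- zt$z
    cb$p[i] <- zt$p
  }
  cb$significant <- !is.na(cb$p) & cb$p < z_alpha
  cb_sig <- unique(cb$node[cb$significant])
  keep <- nodes[top_decile[nodes] | nodes %in% cb_sig]
  keep_reason <- lapply(stats::setNames(keep, keep), function(nd) {
    c(if (top_decile[[nd]]) "top_decile",
      if (nd %in% cb_sig) "callback_significant")
  })
  # edges on collected paths with both endpoints kept
  eseen <- unique(do.call(rbind, lapply(pathsets, function(ps) {
    segs <- lapply(ps$paths, function(p) {
      if (length(p) < 2L) return(NULL)
      cbind(p[-length(p)], p[-1L])
    })
    do.call(rbind, segs)
  })))
  if (is.null(eseen)) eseen <- matrix(character(), ncol = 2L)
  kept <- eseen[eseen[, 1L] %in% keep & eseen[, 2L] %in% keep, ,
                drop = FALSE]
  kept_edges <- data.frame(source = as.character(kept[, 1L]),
                           target = as.character(kept[, 2L]),
                           stringsAsFactors = FALSE)
  kept_edges$sign <- rep("unknown", nrow(kept_edges))
  if (!is.null(net) && nrow(kept_edges) > 0L) {
    e <- net$edges[net$edges$mechanism %in% PATH_MECHANISMS, , drop = FALSE]
    und <- e[!e$directed, , drop = FALSE]
    if (nrow(und) > 0L) {
      rev <- und; rev$source <- und$target; rev$target <- und$source
      e <- rbind(e, rev)
    }
    key <- paste(e$source, e$target, sep = "\r")
    sgn <- tapply(e$sign, key, function(s) {
      s <- unique(setdiff(s, "unknown"))
      if (length(s) == 1L) s else "unknown"
    })
    hit <- sgn[paste(kept_edges$source, kept_edges$target, sep = "\r")]
    kept_edges$sign[!is.na(hit)] <- hit[!is.na(hit)]
  }
  kept_edges <- kept_edges[order(kept_edges$source, kept_edges$target), ,
                           drop = FALSE]
  rownames(kept_edges) <- NULL
  node_stats <- data.frame(node = nodes, total_freq = unname(total),
                           mean_freq = unname(stats$mean_freq),
                           sd_freq = unname(stats$sd_freq),
                           top_decile = unname(top_decile),
                           callback_significant = nodes %in% cb_sig,
                           kept = nodes %in% keep,
                           stringsAsFactors = FALSE)
  structure(list(kept_nodes = sort(keep), kept_edges = kept_edges,
                 keep_reason = keep_reason, node_stats = node_stats,
                 callbacks = cb),
            class = "pruned_network")
}

#' @export
print.pruned_network <- function(x, ...) {
  cat(sprintf("pruned_network: %d kept nodes, %d kept edges (%d callback-significant)\n",
              length(x$kept_nodes), nrow(x$kept_edges),
              sum(vapply(x$keep_reason, function(r)
                "callback_significant" %in% r, logical(1L)))))
  invisible(x)
}
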