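#' Expected DEG direction under a pseudo activation state
#'
#' Sign algebra of upstream-regulator analysis: an activated regulator pushes
#' activation targets up and repression targets down; a repressed regulator
#' does the opposite; an unsigned edge predicts either direction.
#'
#' @param pseudo_state `"activated"` or `"repressed"` (vectorized).
#' @param edge_sign `"activation"`, `"repression"` or `"unknown"`
#'   (vectorized).
#' @return Character vector over `{"up", "down", "either"}`.
#' @export
predicted_direction <- function(pseudo_state, edge_sign) {
  n <- max(length(pseudo_state), length(edge_sign))
  pseudo_state <- rep_len(pseudo_state, n)
  edge_sign <- rep_len(edge_sign, n)
  stopifnot(all(pseudo_state %in% c("activated", "repressed")),
            all(edge_sign %in% PKN_SIGNS))
  out <- rep("either", n)
  act <- pseudo_state == "activated"
  out[edge_sign == "activation"] <- ifelse(act[edge_sign == "activation"],
                                           "up", "down")
  out[edge_sign == "repression"] <- ifelse(act[edge_sign == "repression"],
                                           "down", "up")
  out
}

# DEG direction lookup: named vector "up"/"down" over DEG ids in the PKN.
deg_direction_in <- function(degs, universe) {
  up <- intersect(degs$up, universe)
  down <- intersect(degs$down, universe)
  stats::setNames(c(rep("up", length(up)), rep("down", length(down))),
                  c(up, down))
}

#' Contingency table for one regulator under a pseudo activation state
#'
#' Over the PKN node universe of size `n`:
#' `a` counts the regulator's transcriptional targets whose DEG status
#' matches the direction predicted by the pseudo state and the edge sign;
#' `b` the remaining pattern-matching DEGs in the PKN; `c` the remaining
#' targets; `d` everything else. DEGs outside the PKN are discarded first.
#'
#' @param regulator node id with at least one outgoing transcriptional edge.
#' @param pseudo_state `"activated"` or `"repressed"`.
#' @param degs a `deg_set` (see [call_degs()]).
#' @param net a [knowledge_network()].
#' @param universe optional character vector overriding the node universe
#'   (default: nodes of the transcriptional + virtual mechanism view).
#' @param unknown_sign `"either"` counts unsigned-edge targets as matching if
#'   they are DEG in any direction; `"strict"` never matches them.
#' @return List of class `contingency_table` with `a`, `b`, `c`, `d`, `n`.
#' @export
build_table <- function(regulator, pseudo_state, degs, net, universe = NULL,
                        unknown_sign = c("either", "strict")) {
  unknown_sign <- match.arg(unknown_sign)
  if (is.null(universe)) {
    uv <- mechanism_view(net, c("transcriptional_regulation", "virtual"))
    universe <- uv$nodes$id
  }
  te <- net$edges[net$edges$mechanism == "transcriptional_regulation" &
                    net$edges$source == regulator, , drop = FALSE]
  if (nrow(te) == 0L) {
    stop("regulator '", regulator,
         "' has no outgoing transcriptional_regulation edge")
  }
  # collapse duplicate regulator->target edges; unknown sign wins only if no
  # signed duplicate exists
  sgn <- tapply(te$sign, te$target, function(s) {
    s <- unique(s)
    if (length(s) > 1L) s <- setdiff(s, "unknown")
    if (length(s) > 1L) "unknown" else s
  })
  targets <- names(sgn)
  dirs <- deg_direction_in(degs, universe)
  pred <- predicted_direction(pseudo_state, unname(sgn))
  tgt_dir <- dirs[targets]
  match_a <- !is.na(tgt_dir) &
    (pred == tgt_dir | (pred == "either" & unknown_sign == "either"))
  a <- sum(match_a)
  # global margin: DEGs matching any direction this regulator's edge signs
  # predict under the pseudo state
  pred_dirs <- unique(pred)
  if ("either" %in% pred_dirs && unknown_sign == "either") {
    pred_dirs <- c("up", "down")
  }
  pred_dirs <- setdiff(pred_dirs, "either")
  matched_global <- sum(dirs %in% pred_dirs)
  b <- matched_global - a
  cc <- length(targets) - a
  n <- length(universe)
  d <- n - a - b - cc
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(cc),
                 d = as.integer(d), n = as.integer(n)),
            class = "contingency_table")
}

#' Modified Fisher's exact test p-value (upper tail)
#'
#' Computes `p = sum_k (a+b)! (a+c)! (c+d)! (b+d)! /
#' [(a+k)! (b-k)! (c-k)! (d+k)! n!]` in log-factorial space, summing k from 0
#' while all factorial arguments stay non-negative (k up to `min(b, c)`).
#' This is the one-sided hypergeometric upper-tail probability of observing
#' `a` or more pattern-matching targets with all margins fixed; smaller
#' values indicate stronger regulator-target enrichment.
#'
#' @param a,b,c,d non-negative table cells (vectorized; recycled to a common
#'   length). A `contingency_table` may be given as `a`.
#' @return p-value(s) in (0, 1].
#' @export
fet_pvalue <- function(a, b = NULL, c = NULL, d = NULL) {
  if (inherits(a, "contingency_table")) {
    t <- a; a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  n <- a + b + c + d
  base <- lgamma(a + b + 1) + lgamma(a + c + 1) + lgamma(c + d + 1) +
    lgamma(b + d + 1) - lgamma(n + 1)
  kmax <- pmin(b, c)
  acc <- rep(-Inf, len)
  for (k in 0:max(kmax)) {
    live <- k <= kmax
    if (!any(live)) break
    term <- base[live] - lgamma(a[live] + k + 1) - lgamma(b[live] - k + 1) -
      lgamma(c[live] - k + 1) - lgamma(d[live] + k + 1)
    m <- pmax(acc[live], term)
    acc[live] <- m + log(exp(acc[live] - m) + exp(term - m))
  }
  pmin(exp(acc), 1)
}

#' Upstream-regulator enrichment for one segment's DEGs
#'
#' Every node with outgoing transcriptional edges is evaluated twice — once
#' under an activated and once under a repressed pseudo state — with the
#' modified FET of [fet_pvalue()]. Benjamini-Hochberg FDR is computed over
#' the doubled family; calls with `fdr <= tf_alpha` are flagged significant.
#'
#' @param degs a `deg_set` (see [call_degs()]).
#' @param net a [knowledge_network()].
#' @param tf_alpha FDR significance level (default 0.05).
#' @param universe,unknown_sign passed to [build_table()].
#' @return Data frame of class `regulator_calls`: regulator, state, a, b, c,
#'   d, p, fdr, significant; sorted ascending by p.
#' @export
run_enrichment <- function(degs, net, tf_alpha = 0.05, universe = NULL,
                           unknown_sign = "either") {
  if (is.null(universe)) {
    uv <- mechanism_view(net, c("transcriptional_regulation", "virtual"))
    universe <- uv$nodes$id
  }
  empty <- data.frame(regulator = character(), state = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), p = numeric(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  deg_in_pkn <- intersect(c(degs$up, degs$down), universe)
  if (length(deg_in_pkn) == 0L) {
    warning("no DEGs inside the PKN for segment ",
            segment_label(degs$segment))
    return(structure(empty, class = c("regulator_calls", "data.frame")))
  }
  regulators <- sort(unique(
    net$edges$source[net$edges$mechanism == "transcriptional_regulation"]))
  if (length(regulators) == 0L) {
    return(structure(empty, class = c("regulator_calls", "data.frame")))
  }
  calls <- lapply(regulators, function(r) {
    do.call(rbind, lapply(c("activated", "repressed"), function(st) {
      t <- build_table(r, st, degs, net, universe = universe,
                       unknown_sign = unknown_sign)
      data.frame(regulator = r, state = st, a = t$a, b = t$b, c = t$c,
                 d = t$d, p = fet_pvalue(t), stringsAsFactors = FALSE)
    }))
  })
  calls <- do.call(rbind, calls)
  calls$fdr <- stats::p.adjust(calls$p, method = "BH")
  calls$significant <- calls$fdr <= tf_alpha
  calls <- calls[order(calls$p, calls$regulator, calls$state), , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("regulator_calls", "data.frame"))
}
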