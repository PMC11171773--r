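#' Generate a synthetic signed scale-free prior knowledge network
#'
#' Preferential-attachment directed regulatory core: new genes attach as
#' targets of existing regulators chosen proportionally to out-degree, then
#' extra edges are added the same way, producing the heavy-tailed out-degree
#' distribution typical of transcriptional networks. Signs are drawn
#' activation/repression 0.7/0.3, IF scores Uniform(0.5, 1). A gene-gene
#' correlation layer connects a fraction of co-regulated target pairs
#' (mimicking co-expression resources at toy scale). Regulons are the
#' out-neighborhoods of the highest out-degree regulators; complexes are
#' small random member sets ready for virtual expansion.
#'
#' @param n_genes number of genes (default 200).
#' @param n_edges number of directed regulatory edges, at least
#'   `n_genes - 1` (default 600).
#' @param regulon_count number of regulons to report (default 10).
#' @param complex_count number of complex nodes to add (default 5).
#' @param p_correlation probability of a correlation edge between two
#'   targets sharing a regulator (default 0.1).
#' @param seed integer seed.
#' @return List with `net` (a [knowledge_network()]), `regulons` (named
#'   list) and `complexes` (named list of member vectors).
#' @export
generate_network <- function(n_genes = 200, n_edges = 600,
                             regulon_count = 10, complex_count = 5,
                             p_correlation = 0.1, seed = 1) {
  stopifnot(n_genes >= 2, n_edges >= n_genes - 1)
  if (n_edges > n_genes * (n_genes - 1)) {
    stop("more edges requested than ordered gene pairs")
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  with_seed(seed, {
    src <- integer(n_edges)
    tgt <- integer(n_edges)
    outdeg <- rep(0, n_genes)
    src[1L] <- 1L; tgt[1L] <- 2L; outdeg[1L] <- 1
    ekeys <- new.env(hash = TRUE)
    assign("1-2", TRUE, envir = ekeys)
    m <- 1L
    # growth phase: each new gene becomes the target of a preferential source
    for (v in 3:n_genes) {
      s <- sample.int(v - 1L, 1L, prob = outdeg[seq_len(v - 1L)] + 1)
      m <- m + 1L
      src[m] <- s; tgt[m] <- v
      outdeg[s] <- outdeg[s] + 1
      assign(paste(s, v, sep = "-"), TRUE, envir = ekeys)
    }
    # densification phase: remaining edges, preferential sources
    while (m < n_edges) {
      s <- sample.int(n_genes, 1L, prob = outdeg + 1)
      t <- sample.int(n_genes, 1L)
      if (s == t) next
      key <- paste(s, t, sep = "-")
      if (exists(key, envir = ekeys, inherits = FALSE)) next
      m <- m + 1L
      src[m] <- s; tgt[m] <- t
      outdeg[s] <- outdeg[s] + 1
      assign(key, TRUE, envir = ekeys)
    }
    reg_edges <- data.frame(
      source = genes[src], target = genes[tgt],
      sign = sample(c("activation", "repression"), n_edges, replace = TRUE,
                    prob = c(0.7, 0.3)),
      mechanism = "transcriptional_regulation",
      if_score = stats::runif(n_edges, 0.5, 1),
      reference = "synthetic", stringsAsFactors = FALSE)

    # correlation layer over co-regulated pairs
    cor_rows <- list()
    seen <- new.env(hash = TRUE)
    for (s in unique(src)) {
      ts <- tgt[src == s]
      if (length(ts) < 2L) next
      prs <- utils::combn(sort(ts), 2L)
      pick <- stats::runif(ncol(prs)) < p_correlation
      for (i in which(pick)) {
        key <- paste(prs[1L, i], prs[2L, i], sep = "-")
        if (exists(key, envir = seen, inherits = FALSE)) next
        assign(key, TRUE, envir = seen)
        cor_rows[[length(cor_rows) + 1L]] <-
          data.frame(source = genes[prs[1L, i]], target = genes[prs[2L, i]],
                     sign = "unknown", mechanism = "correlation",
                     if_score = stats::runif(1L, 0.5, 1),
                     reference = "synthetic", stringsAsFactors = FALSE)
      }
    }
    edges <- rbind(reg_edges, do.call(rbind, cor_rows))

    hubs <- order(outdeg, decreasing = TRUE)[seq_len(min(regulon_count,
                                                         n_genes))]
    regulons <- stats::setNames(
      lapply(hubs, function(h) sort(genes[tgt[src == h]])), genes[hubs])
    regulons <- regulons[vapply(regulons, length, integer(1L)) > 0L]

    members <- list()
    if (complex_count > 0L) {
      for (i in seq_len(complex_count)) {
        mem <- sort(sample(genes, sample(2:3, 1L)))
        members[[sprintf("cplx%02d", i)]] <- mem
        prs <- utils::combn(mem, 2L)
        edges <- rbind(edges, data.frame(
          source = prs[1L, ], target = prs[2L, ], sign = "unknown",
          mechanism = "ppi", if_score = stats::runif(ncol(prs), 0.5, 1),
          reference = "synthetic", stringsAsFactors = FALSE))
      }
    }
    net <- knowledge_network(edges, members = members)
    list(net = net, regulons = regulons, complexes = members)
  })
}

#' Simulate a time series with planted driver cascades
#'
#' Baseline log2 expression is Normal(10, 1) per gene (the mean-10 array
#' convention). Each planted driver receives a `+delta` shift from its onset
#' segment onward; the shift propagates one edge per segment (the `lag`)
#' along its planted regulatory path, flipping sign across repression edges,
#' so cascade member expression responds in later segments. The terminal
#' TF's direct transcriptional targets respond already in the onset segment
#' (regulator activity travels through the cascade faster than the sampling
#' interval; expression of the intermediates lags), which is what lets the
#' upstream-regulator test call the TF in the same segment in which the
#' driver fires. Replicate noise is i.i.d. Normal(0, `noise_sd`). When
#' feasible, one later driver is chosen to be the terminus of an earlier
#' planted path, planting a callback event.
#'
#' @param network list from [generate_network()] (or a bare
#'   [knowledge_network()]).
#' @param n_timepoints number of timepoints, at least 3 (default 8).
#' @param replicates replicates per timepoint (default 3).
#' @param delta planted log2 shift (default 2).
#' @param noise_sd replicate noise sd (default 0.25).
#' @param n_drivers number of planted drivers (default 5).
#' @param lag segments per propagation step (default 1).
#' @param path_length maximum planted cascade length in edges (default 3;
#'   0 plants bare driver shifts with no cascade).
#' @param onsets optional integer vector of onset segments (recycled to
#'   `n_drivers`); default spreads onsets over the early segments.
#' @param tf_response shift the terminal TF's regulon at onset (default
#'   TRUE); FALSE perturbs only the cascade itself, the design used for
#'   scoring pure driver recovery.
#' @param plant_callback re-use one cascade terminus as a later driver to
#'   plant a callback event when feasible (default TRUE).
#' @param seed integer seed.
#' @return List with `series` (an [expression_series()]) and `truth`
#'   (`planted_drivers`: data frame gene, onset_segment; `planted_paths`:
#'   list of node-id vectors; `planted_callbacks`: data frame node,
#'   end_segment, reuse_segment; plus `effect_size`, `noise_sd`, `seed`).
#' @export
simulate_series <- function(network, n_timepoints = 8, replicates = 3,
                            delta = 2, noise_sd = 0.25, n_drivers = 5,
                            lag = 1, path_length = 3, onsets = NULL,
                            tf_response = TRUE, plant_callback = TRUE,
                            seed = 1) {
  net <- if (inherits(network, "knowledge_network")) network else network$net
  stopifnot(n_timepoints >= 3, replicates >= 1)
  reg <- net$edges[net$edges$mechanism == "transcriptional_regulation", ,
                   drop = FALSE]
  genes <- sort(net$nodes$id[net$nodes$kind == "gene"])
  n_seg <- n_timepoints - 1L
  g <- igraph::graph_from_data_frame(
    data.frame(from = reg$source, to = reg$target,
               sign = reg$sign, stringsAsFactors = FALSE),
    directed = TRUE, vertices = genes)
  outdeg <- igraph::degree(g, mode = "out")
  with_seed(seed, {
    # drivers are planted among regulator-like genes: at least two
    # transcriptional targets and at least four interactions overall, the
    # neighborhood size the dysregulation statistic is designed around
    alldeg <- table(factor(c(net$edges$source, net$edges$target),
                           levels = genes))
    cand <- names(outdeg)[outdeg >= 2 & alldeg[names(outdeg)] >= 4]
    if (length(cand) < n_drivers) cand <- names(outdeg)[outdeg >= 2]
    if (length(cand) < n_drivers) {
      stop("network too sparse to plant ", n_drivers, " drivers")
    }
    drivers <- sample(cand, n_drivers)
    onsets <- if (is.null(onsets)) {
      sort(rep_len(seq_len(max(n_seg - path_length, 1L)), n_drivers))
    } else {
      stopifnot(all(onsets >= 1), all(onsets <= n_seg))
      rep_len(as.integer(onsets), n_drivers)
    }
    # random forward walk of up to path_length regulatory edges, preferring
    # continuations that keep out-degree > 0 so the terminus has targets
    walk_from <- function(start) {
      path <- start
      cur <- start
      for (step in seq_len(path_length)) {
        nxt <- setdiff(names(igraph::neighbors(g, cur, mode = "out")), path)
        if (length(nxt) == 0L) break
        fertile <- nxt[outdeg[nxt] > 0]
        pool <- if (length(fertile) > 0L) fertile else nxt
        cur <- if (length(pool) == 1L) pool else
          sample(pool, 1L, prob = (outdeg[pool] + 1)^2)
        path <- c(path, cur)
      }
      path
    }
    paths <- lapply(drivers, walk_from)
    # plant one callback: a later driver re-uses an earlier path terminus
    callbacks <- data.frame(node = character(), end_segment = integer(),
                            reuse_segment = integer(),
                            stringsAsFactors = FALSE)
    if (plant_callback) for (k in seq_len(n_drivers)) {
      term <- paths[[k]][length(paths[[k]])]
      reuse_seg <- onsets[k] + length(paths[[k]]) - 1L
      if (term %in% drivers || outdeg[term] < 1 || reuse_seg > n_seg ||
          reuse_seg <= onsets[k]) next
      j <- which(onsets > onsets[k])[1L]
      if (is.na(j)) next
      drivers[j] <- term
      onsets[j] <- reuse_seg
      paths[[j]] <- walk_from(term)
      callbacks <- data.frame(node = term, end_segment = onsets[k],
                              reuse_segment = reuse_seg,
                              stringsAsFactors = FALSE)
      break
    }

    baseline <- stats::rnorm(length(genes), mean = 10, sd = 1)
    names(baseline) <- genes
    shift <- matrix(0, nrow = length(genes), ncol = n_timepoints,
                    dimnames = list(genes, NULL))
    esign <- function(a, b) {
      s <- reg$sign[reg$source == a & reg$target == b][1L]
      if (identical(s, "repression")) -1 else 1
    }
    for (k in seq_len(n_drivers)) {
      path <- paths[[k]]
      eff <- delta
      for (pos in seq_along(path)) {
        if (pos > 1L) eff <- eff * esign(path[pos - 1L], path[pos])
        # onset timepoint of this cascade position: change happens between
        # the two timepoints of segment onset + (pos-1)*lag
        t_on <- onsets[k] + (pos - 1L) * lag + 1L
        if (t_on > n_timepoints) break
        shift[path[pos], t_on:n_timepoints] <-
          shift[path[pos], t_on:n_timepoints] + eff
      }
      # the terminal TF's regulon responds in the onset segment: activity
      # reaches it through the cascade within one sampling interval even
      # though intermediate expression lags
      if (!tf_response) next
      term <- path[length(path)]
      t_on <- onsets[k] + 1L
      tf_eff <- delta * prod(vapply(seq_len(length(path) - 1L), function(i) {
        esign(path[i], path[i + 1L])
      }, numeric(1L)))
      tgts <- setdiff(reg$target[reg$source == term], path)
      for (tg in tgts) {
        if (!(tg %in% genes)) next
        shift[tg, t_on:n_timepoints] <- shift[tg, t_on:n_timepoints] +
          tf_eff * esign(term, tg)
      }
    }
    samples <- as.vector(t(outer(seq_len(n_timepoints), seq_len(replicates),
                                 function(t, r) sprintf("T%d_r%d", t, r))))
    vals <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
    groups <- character(length(samples))
    names(groups) <- samples
    col <- 0L
    for (t in seq_len(n_timepoints)) {
      for (r in seq_len(replicates)) {
        col <- col + 1L
        vals[, col] <- baseline + shift[, t] +
          stats::rnorm(length(genes), sd = noise_sd)
        groups[col] <- sprintf("T%d", t)
      }
    }
    series <- expression_series(vals, groups)
    truth <- list(
      planted_drivers = data.frame(gene = drivers, onset_segment = onsets,
                                   stringsAsFactors = FALSE),
      planted_paths = paths,
      planted_callbacks = callbacks,
      effect_size = delta, noise_sd = noise_sd, seed = seed)
    list(series = series, truth = truth)
  })
}
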