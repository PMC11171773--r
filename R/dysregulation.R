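#' Augment a segment's replicate groups with a mean pseudo-sample
#'
#' Kernel density estimation over an edge needs at least three points per
#' timepoint. Each timepoint's replicate group is therefore appended with one
#' pseudo-sample equal to the per-gene replicate mean; for unreplicated
#' timepoints the per-gene midpoint of the two timepoints is appended as well,
#' bringing every group to at least three points.
#'
#' @param series an [expression_series()].
#' @param segment length-2 character vector of adjacent timepoint labels.
#' @return List with matrices `g1` and `g2` (genes x augmented samples).
#' @export
augment_with_mean_group <- function(series, segment) {
  stopifnot(inherits(series, "expression_series"), length(segment) == 2L)
  s1 <- timepoint_samples(series, segment[1L])
  s2 <- timepoint_samples(series, segment[2L])
  x1 <- series$values[, s1, drop = FALSE]
  x2 <- series$values[, s2, drop = FALSE]
  g1 <- cbind(x1, mean = rowMeans(x1))
  g2 <- cbind(x2, mean = rowMeans(x2))
  if (length(s1) < 2L || length(s2) < 2L) {
    mid <- (rowMeans(x1) + rowMeans(x2)) / 2
    if (length(s1) < 2L) g1 <- cbind(g1, mid = mid)
    if (length(s2) < 2L) g2 <- cbind(g2, mid = mid)
  }
  list(g1 = g1, g2 = g2)
}

#' Build the 2D sample cloud of an edge
#'
#' For genes *i* and *j*, each sample becomes a 2D point
#' (expression of *i*, expression of *j*); the two timepoint groups form two
#' clouds. The kernel densities are evaluated on the lattice spanned by the
#' Cartesian product of all observed values of gene *i* and gene *j* across
#' both groups (the sample-pair grid).
#'
#' @param g1,g2 augmented expression matrices from
#'   [augment_with_mean_group()].
#' @param gene_i,gene_j gene ids (edge endpoints).
#' @return Object of class `sample_cloud`: `edge`, `points1`, `points2`
#'   (n x 2 matrices) and `grid` (list with lattice coordinates `x`, `y`).
#' @export
sample_cloud <- function(g1, g2, gene_i, gene_j) {
  p1 <- cbind(g1[gene_i, ], g1[gene_j, ])
  p2 <- cbind(g2[gene_i, ], g2[gene_j, ])
  cl <- structure(list(edge = c(gene_i, gene_j), points1 = p1, points2 = p2,
                       grid = NULL),
                  class = "sample_cloud")
  cl$grid <- cloud_lattice(cl)
  cl
}

cloud_lattice <- function(cloud) {
  list(x = c(cloud$points1[, 1L], cloud$points2[, 1L]),
       y = c(cloud$points1[, 2L], cloud$points2[, 2L]))
}

#' Regularize a degenerate sample cloud
#'
#' Gaussian kernel placement assumes the pooled 2x2 covariance is
#' well-conditioned. If its condition number exceeds `cond_tol` or its rank
#' is below 2, all points are rotated to the principal axes and the
#' degenerate axis receives seeded jitter of magnitude `eps` times the
#' dominant standard deviation; identical point sets are jittered on both
#' axes. Well-conditioned clouds are returned unchanged. The evaluation
#' lattice is rebuilt from the transformed points.
#'
#' @param cloud a [sample_cloud()].
#' @param cond_tol condition-number tolerance (default 1e8).
#' @param eps jitter scale relative to the dominant axis sd (default 1e-3).
#' @param seed optional integer for reproducible jitter.
#' @return The (possibly transformed) cloud.
#' @export
regularize_cloud <- function(cloud, cond_tol = 1e8, eps = 1e-3, seed = NULL) {
  pooled <- rbind(cloud$points1, cloud$points2)
  cc <- stats::cov(pooled)
  eg <- eigen(cc, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  n1 <- nrow(cloud$points1)
  if (ev[1L] <= 0) {
    # every point identical in both coordinates
    jit <- with_seed(seed, matrix(stats::rnorm(2L * nrow(pooled), sd = eps),
                                  ncol = 2L))
    pooled <- pooled + jit
  } else if (ev[2L] <= 0 || ev[1L] / ev[2L] > cond_tol) {
    rot <- pooled %*% eg$vectors
    jit <- with_seed(seed,
                     stats::rnorm(nrow(pooled), sd = eps * sqrt(ev[1L])))
    rot[, 2L] <- rot[, 2L] + jit
    pooled <- rot
  } else {
    return(cloud)
  }
  cloud$points1 <- pooled[seq_len(n1), , drop = FALSE]
  cloud$points2 <- pooled[-seq_len(n1), , drop = FALSE]
  cloud$grid <- cloud_lattice(cloud)
  cloud
}

# Gaussian-mixture density (one isotropic kernel per sample point, per-axis
# bandwidths) evaluated on the Cartesian lattice xs x ys, floored and
# normalized to a discrete probability mass over the lattice.
lattice_density <- function(points, xs, ys, hx, hy, floor_p = 1e-12) {
  a <- stats::dnorm(outer(xs, points[, 1L], "-"), sd = hx)
  b <- stats::dnorm(outer(ys, points[, 2L], "-"), sd = hy)
  d <- (a %*% t(b)) / nrow(points)
  d <- pmax(d, floor_p)
  d / sum(d)
}

# Silverman's rule per axis with the dispersion taken within the two groups
# (root mean group variance, mean group IQR): the bandwidth must track each
# group's own spread, not the between-group separation under test —
# otherwise a large shift widens the kernels and caps its own divergence.
silverman_bw_groups <- function(x1, x2) {
  n <- length(x1) + length(x2)
  s_w <- sqrt((stats::var(x1) + stats::var(x2)) / 2)
  iqr_w <- (stats::IQR(x1) + stats::IQR(x2)) / 2 / 1.349
  spread <- min(s_w, if (iqr_w > 0) iqr_w else s_w)
  if (!is.finite(spread) || spread <= 0) {
    spread <- max(s_w, stats::sd(c(x1, x2)), 1e-6, na.rm = TRUE)
  }
  0.9 * spread * n^(-0.2)
}

#' Symmetrized Kullback-Leibler edge dysregulation score
#'
#' The two timepoint clouds are turned into Gaussian-mixture densities (one
#' kernel per sample point, per-axis Silverman bandwidths computed from the
#' within-group dispersion of the points), evaluated on the cloud's
#' sample-pair lattice, floored at `floor_p` and renormalized; the score is
#' the average of the two directed discrete KL divergences. Zero iff the two
#' normalized densities coincide on the lattice; invariant under swapping
#' the groups.
#'
#' @param cloud a [sample_cloud()] (regularize first for degenerate clouds).
#' @param bw_adjust scalar multiplier on the Silverman bandwidths.
#' @param floor_p density floor applied before normalization (default 1e-12).
#' @param grid optional evaluation lattice (list with numeric `x`, `y`)
#'   overriding the cloud's sample-pair lattice, e.g. a dense regular grid.
#' @param bw_floor optional absolute lower bound on the per-axis bandwidth.
#'   With very few replicates the local dispersion estimate is unstable, and
#'   a coincidentally tight replicate group shrinks the kernels enough to
#'   make ordinary noise look divergent; flooring the bandwidth at the
#'   cohort's typical within-group noise scale moderates this (see
#'   [run_driver_analysis()], which sets it from the data).
#' @return Non-negative scalar.
#' @export
edge_kld <- function(cloud, bw_adjust = 1, floor_p = 1e-12, grid = NULL,
                     bw_floor = 0) {
  if (is.null(grid)) grid <- cloud$grid
  xs <- grid$x
  ys <- grid$y
  hx <- max(silverman_bw_groups(cloud$points1[, 1L], cloud$points2[, 1L]),
            bw_floor) * bw_adjust
  hy <- max(silverman_bw_groups(cloud$points1[, 2L], cloud$points2[, 2L]),
            bw_floor) * bw_adjust
  p1 <- lattice_density(cloud$points1, xs, ys, hx, hy, floor_p)
  p2 <- lattice_density(cloud$points2, xs, ys, hx, hy, floor_p)
  lr <- log(p1) - log(p2)
  (sum(p1 * lr) - sum(p2 * lr)) / 2
}

#' Permutation null distribution of edge KLD scores
#'
#' Draws random unordered gene pairs that do not share an edge in the given
#' network view and scores each exactly like a real edge (augmentation,
#' regularization, symmetrized KLD). The resulting values form the null
#' against which observed edge scores are ranked.
#'
#' @param series an [expression_series()].
#' @param segment adjacent timepoint pair.
#' @param net a [knowledge_network()] view; pairs sharing *any* edge in it
#'   are excluded from the null.
#' @param n_draws number of null pairs (default 10000).
#' @param seed optional integer seed.
#' @param bw_adjust,floor_p,cond_tol passed to the KLD machinery.
#' @param bw_floor absolute bandwidth floor; `NULL` (default) derives the
#'   cohort floor from the augmented segment matrices (see [edge_kld()]).
#' @return Numeric vector of length `n_draws`.
#' @export
null_kld_distribution <- function(series, segment, net, n_draws = 10000,
                                  seed = NULL, bw_adjust = 1,
                                  floor_p = 1e-12, cond_tol = 1e8,
                                  bw_floor = NULL) {
  stopifnot(n_draws >= 1)
  genes <- intersect(net$nodes$id, series$genes)
  m <- length(genes)
  if (m < 2L) stop("need at least two expressed network genes")
  idx <- stats::setNames(seq_len(m), genes)
  in_view <- net$edges$source %in% genes & net$edges$target %in% genes
  ekey <- unique(edge_pair_key(idx[net$edges$source[in_view]],
                               idx[net$edges$target[in_view]], m))
  n_pairs <- m * (m - 1) / 2
  admissible <- n_pairs - length(ekey)
  if (admissible <= 0) stop("no null pairs: every gene pair shares an edge")
  if (admissible < n_draws) {
    warning(sprintf("only %d admissible null pairs for %d draws; sampling with replacement",
                    admissible, n_draws))
  }
  aug <- augment_with_mean_group(series, segment)
  g1 <- aug$g1[genes, , drop = FALSE]
  g2 <- aug$g2[genes, , drop = FALSE]
  if (is.null(bw_floor)) bw_floor <- cohort_bw_floor(g1, g2)
  with_seed(seed, {
    pairs <- matrix(0L, nrow = n_draws, ncol = 2L)
    filled <- 0L
    while (filled < n_draws) {
      k <- (n_draws - filled) * 2L
      i <- sample.int(m, k, replace = TRUE)
      j <- sample.int(m, k, replace = TRUE)
      ok <- i != j & !(edge_pair_key(i, j, m) %in% ekey)
      take <- min(sum(ok), n_draws - filled)
      if (take > 0L) {
        sel <- which(ok)[seq_len(take)]
        pairs[filled + seq_len(take), ] <- cbind(i[sel], j[sel])
        filled <- filled + take
      }
    }
    vapply(seq_len(n_draws), function(r) {
      cl <- sample_cloud(g1, g2, genes[pairs[r, 1L]], genes[pairs[r, 2L]])
      cl <- regularize_cloud(cl, cond_tol = cond_tol)
      edge_kld(cl, bw_adjust = bw_adjust, floor_p = floor_p,
               bw_floor = bw_floor)
    }, numeric(1L))
  })
}

# Cohort-level bandwidth floor: Silverman's constant applied to the median
# per-gene within-group dispersion of the augmented segment matrices.
cohort_bw_floor <- function(g1, g2) {
  v1 <- apply(g1, 1L, stats::var)
  v2 <- apply(g2, 1L, stats::var)
  s_w <- sqrt((v1 + v2) / 2)
  med <- stats::median(s_w, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) return(0)
  0.9 * med * (ncol(g1) + ncol(g2))^(-0.2)
}

# canonical integer key of an unordered index pair
edge_pair_key <- function(i, j, m) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * m + hi
}

#' Empirical p-value against a permutation null
#'
#' Add-one smoothed upper-tail rank: `(1 + #\{null >= observed\}) /
#' (1 + |null|)`. The smoothing keeps p strictly positive so the downstream
#' Fisher log-combination is always defined.
#'
#' @param observed observed statistic (scalar or vector).
#' @param null numeric vector of null statistics.
#' @return p-value(s) in (0, 1].
#' @export
empirical_pvalue <- function(observed, null) {
  stopifnot(length(null) > 0L)
  vapply(observed, function(o) (1 + sum(null >= o)) / (1 + length(null)),
         numeric(1L))
}

# Kost-McDermott polynomial approximation of cov(-2 ln p_i, -2 ln p_j)
# from the Pearson correlation of the underlying statistics.
kost_cov <- function(rho) {
  pmin(pmax(3.263 * rho + 0.710 * rho^2 + 0.027 * rho^3, -4), 4)
}

#' Combine a gene's edge p-values (Fisher with Brown's correction)
#'
#' Fisher's statistic `chi2 = sum(-2 log p)` over the gene's incident edges.
#' Because edges sharing the gene are dependent through correlated partner
#' profiles, Brown's correction rescales the reference distribution to
#' `c * chisq(df')` with the pairwise covariances of the `-2 log p` terms
#' estimated by the Kost-McDermott polynomial from the Pearson correlations
#' of the partner-gene expression profiles. With a single edge, or all
#' correlations zero, the result reduces to plain Fisher with `df = 2k`.
#'
#' @param edge_p vector of per-edge p-values in (0, 1].
#' @param correlations optional k x k matrix of pairwise Pearson correlations
#'   between the edges' partner-gene profiles.
#' @return List with `chi2`, `df`, `p`, `n_edges`.
#' @export
aggregate_gene <- function(edge_p, correlations = NULL) {
  k <- length(edge_p)
  stopifnot(k >= 1L)
  if (any(edge_p <= 0)) stop("edge p-values must be strictly positive")
  chi2 <- -2 * sum(log(edge_p))
  e_chi <- 2 * k
  if (k == 1L || is.null(correlations)) {
    var_chi <- 4 * k
  } else {
    stopifnot(nrow(correlations) == k, ncol(correlations) == k)
    cov_off <- kost_cov(correlations[upper.tri(correlations)])
    var_chi <- max(4 * k + 2 * sum(cov_off), 1e-8)
  }
  scale_c <- var_chi / (2 * e_chi)
  df <- 2 * e_chi^2 / var_chi
  p <- stats::pchisq(chi2 / scale_c, df = df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = max(p, .Machine$double.xmin),
       n_edges = k)
}

#' Primary regulatory driver analysis for one time segment
#'
#' Runs the full per-edge dysregulation pipeline on the selected mechanism
#' view of the network: replicate augmentation, cloud regularization,
#' symmetrized KLD per edge, empirical p-values against a shared random-pair
#' null, and Fisher/Brown aggregation to gene level. Genes are returned
#' sorted by aggregated p; those at or below `driver_alpha` are flagged as
#' primary regulatory drivers.
#'
#' @param series an [expression_series()].
#' @param segment adjacent timepoint pair.
#' @param net a [knowledge_network()] (full network; the view is selected
#'   here).
#' @param mechanisms mechanism view for Algorithm 1 (default correlation +
#'   transcriptional regulation).
#' @param null_draws size of the permutation null (default 10000).
#' @param driver_alpha significance level for the driver flag (default 0.05).
#' @param seed optional integer seed (null sampling and jitter).
#' @param bw_adjust,floor_p,cond_tol numerical knobs of the KLD machinery.
#' @param null optional precomputed null vector (skips resampling).
#' @return Object of class `driver_analysis`: data frame `genes` (gene,
#'   chi2, df, p, n_edges, is_driver), data frame `edges` (gene_i, gene_j,
#'   kld, p) and the `null` vector.
#' @export
run_driver_analysis <- function(series, segment, net,
                                mechanisms = c("correlation",
                                               "transcriptional_regulation"),
                                null_draws = 10000, driver_alpha = 0.05,
                                seed = NULL, bw_adjust = 1, floor_p = 1e-12,
                                cond_tol = 1e8, null = NULL) {
  view <- mechanism_view(net, mechanisms)
  genes <- intersect(view$nodes$id, series$genes)
  e <- view$edges
  keep <- e$source %in% genes & e$target %in% genes & e$source != e$target
  e <- e[keep, , drop = FALSE]
  empty <- data.frame(gene = character(), chi2 = numeric(), df = numeric(),
                      p = numeric(), n_edges = integer(),
                      is_driver = logical(), stringsAsFactors = FALSE)
  if (nrow(e) == 0L) {
    warning("no expressed edge endpoints in segment ", segment_label(segment))
    return(structure(list(genes = empty,
                          edges = data.frame(), null = numeric(),
                          segment = segment),
                     class = "driver_analysis"))
  }
  # collapse the multiset to unique unordered expressed pairs
  lo <- pmin(e$source, e$target)
  hi <- pmax(e$source, e$target)
  pairs <- unique(data.frame(gene_i = lo, gene_j = hi,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$gene_i, pairs$gene_j), , drop = FALSE]
  rownames(pairs) <- NULL

  aug <- augment_with_mean_group(series, segment)
  g1 <- aug$g1[genes, , drop = FALSE]
  g2 <- aug$g2[genes, , drop = FALSE]
  bw_floor <- cohort_bw_floor(g1, g2)
  jitter_seed <- derive_seed(seed, "regularize")
  pairs$kld <- vapply(seq_len(nrow(pairs)), function(r) {
    cl <- sample_cloud(g1, g2, pairs$gene_i[r], pairs$gene_j[r])
    cl <- regularize_cloud(cl, cond_tol = cond_tol, seed = jitter_seed)
    edge_kld(cl, bw_adjust = bw_adjust, floor_p = floor_p,
             bw_floor = bw_floor)
  }, numeric(1L))

  if (is.null(null)) {
    null <- null_kld_distribution(series, segment, view, n_draws = null_draws,
                                  seed = derive_seed(seed, "null"),
                                  bw_adjust = bw_adjust, floor_p = floor_p,
                                  cond_tol = cond_tol, bw_floor = bw_floor)
  }
  pairs$p <- empirical_pvalue(pairs$kld, null)

  # Brown's correction needs the dependence between edges sharing the gene;
  # partner correlations are estimated on the full time-series profiles,
  # where the estimate is stable, not on the one segment under test
  expr_seg <- series$values
  touched <- sort(unique(c(pairs$gene_i, pairs$gene_j)))
  res <- lapply(touched, function(g) {
    rows <- which(pairs$gene_i == g | pairs$gene_j == g)
    partners <- ifelse(pairs$gene_i[rows] == g, pairs$gene_j[rows],
                       pairs$gene_i[rows])
    corr <- NULL
    if (length(rows) > 1L) {
      prof <- t(expr_seg[partners, , drop = FALSE])
      corr <- suppressWarnings(stats::cor(prof))
      corr[!is.finite(corr)] <- 0
    }
    agg <- aggregate_gene(pairs$p[rows], corr)
    data.frame(gene = g, chi2 = agg$chi2, df = agg$df, p = agg$p,
               n_edges = agg$n_edges, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[order(res$p, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res$is_driver <- res$p <= driver_alpha
  structure(list(genes = res, edges = pairs, null = null, segment = segment),
            class = "driver_analysis")
}

#' @export
print.driver_analysis <- function(x, ...) {
  cat(sprintf("driver_analysis %s: %d genes over %d edges, %d drivers (null size %d)\n",
              segment_label(x$segment), nrow(x$genes), nrow(x$edges),
              sum(x$genes$is_driver), length(x$null)))
  invisible(x)
}
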