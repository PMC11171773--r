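# Small builders shared across test files.

# Edge-table shorthand: each row "source target sign mechanism if_score"
edge_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(source = r[[1]], target = r[[2]],
               sign = if (length(r) >= 3) r[[3]] else "activation",
               mechanism = if (length(r) >= 4) r[[4]] else
                 "transcriptional_regulation",
               if_score = if (length(r) >= 5) as.numeric(r[[5]]) else 1,
               reference = "test", stringsAsFactors = FALSE)
  }))
}

toy_net <- function(...) knowledge_network(edge_df(...))

# Expression series with explicit per-timepoint replicate matrices.
# values: named list timepoint -> genes x replicates matrix (same rownames).
toy_series <- function(values) {
  mats <- lapply(names(values), function(tp) {
    m <- values[[tp]]
    colnames(m) <- sprintf("%s_r%d", tp, seq_len(ncol(m)))
    m
  })
  all <- do.call(cbind, mats)
  groups <- unlist(lapply(names(values), function(tp) {
    stats::setNames(rep(tp, ncol(values[[tp]])),
                    sprintf("%s_r%d", tp, seq_len(ncol(values[[tp]]))))
  }))
  expression_series(all, groups)
}

# Two-timepoint series of pure noise around per-gene baselines, with an
# optional shift applied to selected genes at the second timepoint.
noise_series <- function(genes, reps = 3, shift = c(), delta = 0,
                         noise_sd = 0.25, seed = 1) {
  withr::with_seed(seed, {
    base <- stats::rnorm(length(genes), 10, 1)
    names(base) <- genes
    m1 <- matrix(stats::rnorm(length(genes) * reps, base, noise_sd),
                 nrow = length(genes), dimnames = list(genes, NULL))
    b2 <- base
    b2[shift] <- b2[shift] + delta
    m2 <- matrix(stats::rnorm(length(genes) * reps, b2, noise_sd),
                 nrow = length(genes), dimnames = list(genes, NULL))
    toy_series(list(T1 = m1, T2 = m2))
  })
}

# A minimal path_set built from bare node-id vectors.
fake_pathset <- function(paths, segment = NULL) {
  structure(list(
    segment = segment,
    paths = paths,
    pairs = data.frame(source = vapply(paths, `[`, character(1L), 1L),
                       target = vapply(paths, function(p) p[length(p)],
                                       character(1L)),
                       length = lengths(paths) - 1L,
                       n_paths = 1L, stringsAsFactors = FALSE),
    unreachable = data.frame(source = character(), target = character(),
                             reason = character())),
    class = "path_set")
}
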