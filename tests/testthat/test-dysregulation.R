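two_gene_series <- function(p1, p2) {
  # p1/p2: n x 2 matrices of (gene i, gene j) sample points per timepoint
  m1 <- t(p1); m2 <- t(p2)
  rownames(m1) <- rownames(m2) <- c("gi", "gj")
  toy_series(list(T1 = m1, T2 = m2))
}

cloud_from_points <- function(p1, p2) {
  g1 <- rbind(gi = p1[, 1L], gj = p1[, 2L])
  g2 <- rbind(gi = p2[, 1L], gj = p2[, 2L])
  sample_cloud(g1, g2, "gi", "gj")
}

test_that("mean-group augmentation reaches three samples per side", {
  genes <- c("a", "b")
  # two replicates per side -> third column is the replicate mean
  s2 <- toy_series(list(T1 = matrix(c(1, 2, 3, 6), 2,
                                    dimnames = list(genes, NULL)),
                        T2 = matrix(c(5, 6, 7, 10), 2,
                                    dimnames = list(genes, NULL))))
  aug <- augment_with_mean_group(s2, c("T1", "T2"))
  expect_equal(ncol(aug$g1), 3L)
  expect_equal(unname(aug$g1[, 3L]), c(2, 4))
  expect_equal(unname(aug$g2[, 3L]), c(6, 8))

  # single replicate -> mean plus cross-timepoint midpoint
  s1 <- toy_series(list(T1 = matrix(c(1, 2), 2, dimnames = list(genes, NULL)),
                        T2 = matrix(c(5, 6), 2,
                                    dimnames = list(genes, NULL))))
  aug1 <- augment_with_mean_group(s1, c("T1", "T2"))
  expect_equal(ncol(aug1$g1), 3L)
  expect_equal(ncol(aug1$g2), 3L)
  expect_equal(unname(aug1$g1[, 3L]), c(3, 4))
  expect_equal(unname(aug1$g2[, 3L]), c(3, 4))

  # five replicates -> sixth equals the mean of the first five
  m5 <- matrix(seq_len(10), 2, dimnames = list(genes, NULL))
  s5 <- toy_series(list(T1 = m5, T2 = m5 + 1))
  aug5 <- augment_with_mean_group(s5, c("T1", "T2"))
  expect_equal(ncol(aug5$g1), 6L)
  expect_equal(unname(aug5$g1[, 6L]), unname(rowMeans(m5)))
})

test_that("cloud regularization repairs degenerate geometry", {
  # perfectly collinear: x_j = 2 x_i
  x <- c(1, 2, 3, 4)
  cl <- cloud_from_points(cbind(x, 2 * x), cbind(x + 0.5, 2 * (x + 0.5)))
  reg <- regularize_cloud(cl, seed = 1)
  cc <- stats::cov(rbind(reg$points1, reg$points2))
  expect_equal(qr(cc)$rank, 2L)

  # well-conditioned cloud returned unchanged
  set.seed(2)
  p1 <- matrix(rnorm(8), 4, 2)
  p2 <- matrix(rnorm(8), 4, 2)
  ok <- cloud_from_points(p1, p2)
  expect_identical(regularize_cloud(ok, seed = 1), ok)

  # all points identical: non-degenerate, deterministic under seed
  same <- cloud_from_points(matrix(1, 4, 2), matrix(1, 4, 2))
  r1 <- regularize_cloud(same, seed = 9)
  r2 <- regularize_cloud(same, seed = 9)
  expect_identical(r1, r2)
  expect_equal(qr(stats::cov(rbind(r1$points1, r1$points2)))$rank, 2L)
})

test_that("edge KLD is zero for identical groups and symmetric under swap", {
  set.seed(3)
  p <- matrix(rnorm(12, 10, 0.5), 6, 2)
  expect_identical(edge_kld(cloud_from_points(p, p)), 0)

  q <- matrix(rnorm(12, 11, 0.5), 6, 2)
  a <- cloud_from_points(p, q)
  b <- cloud_from_points(q, p)
  expect_identical(edge_kld(a), edge_kld(b))
  expect_gte(edge_kld(a), 0)
})

test_that("separated clouds match the brute-force fine-grid oracle", {
  set.seed(5)
  n <- 30
  # clouds separated by 5 within-group (pooled) sd along the first axis
  p1 <- cbind(rnorm(n), rnorm(n))
  p2 <- cbind(rnorm(n) + 5, rnorm(n))
  cl <- cloud_from_points(p1, p2)
  hx <- oracle_bw(p1[, 1L], p2[, 1L])
  hy <- oracle_bw(p1[, 2L], p2[, 2L])
  gx <- seq(min(c(p1[, 1], p2[, 1])) - 4 * hx,
            max(c(p1[, 1], p2[, 1])) + 4 * hx, length.out = 81)
  gy <- seq(min(c(p1[, 2], p2[, 2])) - 4 * hy,
            max(c(p1[, 2], p2[, 2])) + 4 * hy, length.out = 81)
  impl <- edge_kld(cl, grid = list(x = gx, y = gy))
  oracle <- oracle_kld_grid(p1, p2, hx, hy, gx, gy)
  expect_lt(abs(impl - oracle) / oracle, 0.05)
})

test_that("empirical p-values follow the add-one smoothed tail rank", {
  null <- 1:1000
  expect_equal(empirical_pvalue(1001, null), 1 / 1001)
  expect_equal(empirical_pvalue(0.5, null), 1)
  # observed equal to the median of an odd-length null: brute-force count
  null3 <- c(5, 1, 9, 2, 7)
  obs <- 5
  expect_equal(empirical_pvalue(obs, null3),
               (1 + sum(null3 >= obs)) / (1 + length(null3)))
  expect_equal(empirical_pvalue(obs, null3), 4 / 6)
})

test_that("gene aggregation reduces to Fisher and respects Brown scaling", {
  expect_equal(aggregate_gene(c(1, 1, 1))$chi2, 0)
  expect_equal(aggregate_gene(c(1, 1, 1))$p, 1)

  one <- aggregate_gene(0.05)
  expect_equal(one$chi2, -2 * log(0.05))
  expect_equal(one$chi2, 5.9915, tolerance = 1e-4)
  expect_equal(one$df, 2)
  expect_equal(one$p, 0.05)

  # zero correlation: plain Fisher with df = 2k
  r0 <- diag(3)
  f <- aggregate_gene(c(0.1, 0.2, 0.3), r0)
  expect_equal(f$df, 6)
  expect_equal(f$p, pchisq(f$chi2, 6, lower.tail = FALSE))

  # positive dependence widens the scale and lowers the df
  rp <- matrix(0.8, 3, 3); diag(rp) <- 1
  b <- aggregate_gene(c(0.1, 0.2, 0.3), rp)
  expect_lt(b$df, 6)
  expect_gt(b$p, f$p)

  expect_error(aggregate_gene(c(0.5, 0)), "positive")
})

test_that("the null generator is seeded, reproducible and guarded", {
  genes <- sprintf("g%02d", 1:12)
  net <- knowledge_network(edge_df(list("g01", "g02"), list("g03", "g04")),
                           nodes = data.frame(id = genes, kind = "gene"))
  series <- noise_series(genes, seed = 8)
  n1 <- null_kld_distribution(series, c("T1", "T2"), net, n_draws = 50,
                              seed = 4)
  n2 <- null_kld_distribution(series, c("T1", "T2"), net, n_draws = 50,
                              seed = 4)
  expect_identical(n1, n2)
  expect_length(n1, 50L)

  # tiny network: more draws than admissible pairs warns
  tiny <- noise_series(c("g01", "g02", "g03"), seed = 2)
  tiny_net <- knowledge_network(
    edge_df(list("g01", "g02")),
    nodes = data.frame(id = c("g01", "g02", "g03"), kind = "gene"))
  expect_warning(
    null_kld_distribution(tiny, c("T1", "T2"), tiny_net,
                          n_draws = 500, seed = 1),
    "with replacement")

  # complete graph: no admissible pair at all
  cg <- knowledge_network(edge_df(list("g01", "g02"), list("g01", "g03"),
                                  list("g02", "g03")))
  expect_error(null_kld_distribution(series, c("T1", "T2"), cg,
                                     n_draws = 10, seed = 1),
               "no null pairs")
})

test_that("driver analysis is deterministic and handles empty views", {
  genes <- sprintf("g%02d", 1:20)
  net <- generate_network(n_genes = 20, n_edges = 40, complex_count = 0,
                          seed = 5)$net
  series <- noise_series(sprintf("g%04d", 1:20), shift = "g0001", delta = 2,
                         seed = 6)
  a <- run_driver_analysis(series, c("T1", "T2"), net, null_draws = 100,
                           seed = 3)
  b <- run_driver_analysis(series, c("T1", "T2"), net, null_draws = 100,
                           seed = 3)
  expect_identical(a$genes, b$genes)
  expect_identical(a$null, b$null)

  # disjoint expression: empty result with a warning
  stranger <- noise_series(paste0("x", 1:5), seed = 1)
  expect_warning(e <- run_driver_analysis(stranger, c("T1", "T2"), net,
                                          null_draws = 10, seed = 1),
                 "no expressed edge endpoints")
  expect_equal(nrow(e$genes), 0L)
})
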