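pruned_of <- function(edges, nodes = NULL) {
  kept_edges <- data.frame(source = vapply(edges, `[`, "", 1L),
                           target = vapply(edges, `[`, "", 2L),
                           sign = vapply(edges, function(e) {
                             if (length(e) >= 3) e[3] else "unknown"
                           }, ""), stringsAsFactors = FALSE)
  kept <- unique(c(kept_edges$source, kept_edges$target, nodes))
  structure(list(kept_nodes = sort(kept), kept_edges = kept_edges,
                 keep_reason = setNames(rep(list("top_decile"),
                                            length(kept)), kept)),
            class = "pruned_network")
}

clique_edges <- function(members) {
  prs <- utils::combn(members, 2L)
  lapply(seq_len(ncol(prs)), function(i) c(prs[1L, i], prs[2L, i]))
}

test_that("clustering weights apply the boost once per qualifying edge", {
  pr <- pruned_of(list(c("a", "b"), c("b", "c"), c("c", "d")))
  g1 <- weight_for_clustering(pr, boost = 1)
  expect_true(all(igraph::E(g1)$weight == 1))

  # edge inside a complex doubles
  g2 <- weight_for_clustering(pr, complexes = list(c("a", "b")), boost = 2)
  w <- igraph::E(g2)$weight
  names(w) <- apply(igraph::ends(g2, igraph::E(g2)), 1, paste,
                    collapse = "-")
  expect_equal(unname(w[["a-b"]]), 2)
  expect_equal(unname(w[["b-c"]]), 1)

  # membership in both a regulon and a complex boosts once, not twice
  g3 <- weight_for_clustering(pr, regulons = list(a = c("b")),
                              complexes = list(c("a", "b")), boost = 2)
  w3 <- igraph::E(g3)$weight
  names(w3) <- apply(igraph::ends(g3, igraph::E(g3)), 1, paste,
                     collapse = "-")
  expect_equal(unname(w3[["a-b"]]), 2)

  # antiparallel kept edges accumulate weight on one undirected edge
  pr2 <- pruned_of(list(c("a", "b"), c("b", "a")))
  g4 <- weight_for_clustering(pr2, boost = 1)
  expect_equal(igraph::ecount(g4), 1L)
  expect_equal(igraph::E(g4)$weight, 2)
})

test_that("Louvain recovers planted structure deterministically", {
  # a single node forms a singleton hypernode
  lone <- pruned_of(list(), nodes = "solo")
  g0 <- weight_for_clustering(lone)
  hn0 <- louvain_hypernodes(g0, seed = 1)
  expect_length(hn0, 1L)
  expect_equal(hn0[[1L]]$members, "solo")

  # two 10-node cliques joined by one edge split exactly in two
  a <- sprintf("a%02d", 1:10)
  b <- sprintf("b%02d", 1:10)
  pr <- pruned_of(c(clique_edges(a), clique_edges(b), list(c("a01", "b01"))))
  g <- weight_for_clustering(pr)
  hn <- louvain_hypernodes(g, seed = 7)
  expect_length(hn, 2L)
  expect_setequal(hn[[1L]]$members, a)
  expect_setequal(hn[[2L]]$members, b)

  # determinism under a fixed seed
  hn2 <- louvain_hypernodes(g, seed = 7)
  expect_identical(hn, hn2)

  # labels follow the dominant member annotation, ties lexicographic
  ann <- setNames(c(rep("oxidative stress", 9), "flagellum",
                    rep("anaerobic shift", 10)), c(a, b))
  hn3 <- louvain_hypernodes(g, seed = 7, annotations = ann)
  expect_equal(hn3[[1L]]$label, "oxidative stress")
  expect_equal(hn3[[2L]]$label, "anaerobic shift")
})

test_that("regulon boosting flips a marginal co-clustering case", {
  # b1 sits in clique B but its regulator a1 (clique A) claims it; the
  # a1-b1 tie is too weak at boost 1 and wins at boost 4
  a <- sprintf("a%02d", 1:4)
  b <- sprintf("b%02d", 1:4)
  edges <- c(clique_edges(a), clique_edges(b), list(c("a01", "b01")))
  pr <- pruned_of(edges)
  reg <- list(a01 = "b01")

  base <- louvain_hypernodes(weight_for_clustering(pr, regulons = reg,
                                                   boost = 1), seed = 3)
  memb_of <- function(hn, node) {
    for (h in hn) if (node %in% h$members) return(h$id)
    NA_integer_
  }
  expect_false(memb_of(base, "b01") == memb_of(base, "a01"))

  boosted <- louvain_hypernodes(weight_for_clustering(pr, regulons = reg,
                                                      boost = 4), seed = 3)
  expect_true(memb_of(boosted, "b01") == memb_of(boosted, "a01"))
})

test_that("hyperedges aggregate counts and sign summaries", {
  a <- c("a1", "a2", "a3")
  b <- c("b1", "b2", "b3")
  edges <- c(clique_edges(a), clique_edges(b),
             list(c("a1", "b1", "activation"), c("a2", "b2", "activation"),
                  c("a3", "b3", "activation")))
  pr <- pruned_of(edges)
  hn <- louvain_hypernodes(weight_for_clustering(pr), seed = 5)
  hyper <- aggregate_hyperedges(pr, hn)
  expect_equal(nrow(hyper$hyperedges), 1L)
  expect_equal(hyper$hyperedges$weight, 3L)
  expect_equal(hyper$hyperedges$sign, "activation")

  # 2 activation + 1 repression -> mixed
  edges2 <- c(clique_edges(a), clique_edges(b),
              list(c("a1", "b1", "activation"), c("a2", "b2", "activation"),
                   c("a3", "b3", "repression")))
  pr2 <- pruned_of(edges2)
  hyper2 <- aggregate_hyperedges(pr2, louvain_hypernodes(
    weight_for_clustering(pr2), seed = 5))
  expect_equal(hyper2$hyperedges$sign, "mixed")

  # no inter-hypernode edges at all
  pr3 <- pruned_of(clique_edges(a))
  hyper3 <- aggregate_hyperedges(pr3, louvain_hypernodes(
    weight_for_clustering(pr3), seed = 5))
  expect_equal(nrow(hyper3$hyperedges), 0L)
})

test_that("hyperedge weights plus intra-community edges conserve the total", {
  set.seed(17)
  nodes <- sprintf("v%02d", 1:20)
  edges <- lapply(1:40, function(i) sample(nodes, 2))
  pr <- pruned_of(edges)
  hn <- louvain_hypernodes(weight_for_clustering(pr), seed = 2)
  hyper <- aggregate_hyperedges(pr, hn)
  memb <- integer(0)
  for (h in hn) memb[h$members] <- h$id
  intra <- sum(memb[pr$kept_edges$source] == memb[pr$kept_edges$target])
  expect_equal(sum(hyper$hyperedges$weight) + intra, nrow(pr$kept_edges))

  # modularity of the Louvain partition is at least the singleton partition
  g <- weight_for_clustering(pr)
  mod_l <- igraph::modularity(g, memb[igraph::V(g)$name],
                              weights = igraph::E(g)$weight)
  mod_s <- igraph::modularity(g, seq_len(igraph::vcount(g)),
                              weights = igraph::E(g)$weight)
  expect_gte(mod_l, mod_s)
})
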