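test_that("TSV networks read, write and round-trip losslessly", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tsign\tmechanism\tif_score\treference",
               "A\tB\tactivation\ttranscriptional_regulation\t0.9\tpmid:1",
               "B\tC\trepression\ttranscriptional_regulation\t0.83\tpmid:2"),
             tsv)
  net <- read_network(tsv)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(net$edges$directed))
  expect_equal(net$edges$low_confidence, c(FALSE, TRUE))

  out <- tempfile(fileext = ".tsv")
  write_network(net, out)
  net2 <- read_network(out)
  expect_identical(net$nodes, net2$nodes)
  expect_identical(net$edges, net2$edges)

  # an irrational score survives the round trip bit-exactly
  net$edges$if_score[1L] <- 1 / 3
  write_network(net, out)
  expect_identical(read_network(out)$edges$if_score[1L], 1 / 3)
})

test_that("degenerate and malformed network files are handled", {
  empty <- tempfile(); file.create(empty)
  net <- read_network(empty)
  expect_equal(nrow(net$nodes), 0L)
  expect_equal(nrow(net$edges), 0L)

  bad <- tempfile()
  writeLines(c("source\ttarget\tsign\tmechanism\tif_score\treference",
               "A\tB\tactivation\ttranscriptional_regulation\t0.9\tx",
               "B\tC\trepression"), bad)
  expect_error(read_network(bad), "line 3")

  unk <- tempfile()
  writeLines(c("source\ttarget\tsign\tmechanism\tif_score\treference",
               "A\tB\tact.\ttranscriptional_regulation\t0.9\tx"), unk)
  expect_warning(net <- read_network(unk), "unrecognized sign")
  expect_equal(net$edges$sign, "unknown")
})

test_that("SIF dialect parses multi-target rows", {
  sif <- tempfile(fileext = ".sif")
  writeLines(c("A activation B C", "B repression D"), sif)
  net <- read_network(sif, dialect = "sif")
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(net$nodes$id, c("A", "B", "C", "D"))
  expect_equal(net$edges$sign, c("activation", "activation", "repression"))
})

test_that("graphml dialect mirrors the TSV attributes", {
  net <- toy_net(list("A", "B", "activation", "ppi", 0.9),
                 list("B", "C", "repression",
                      "transcriptional_regulation", 0.7))
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$source, to = net$edges$target,
               sign = net$edges$sign, mechanism = net$edges$mechanism,
               if_score = net$edges$if_score,
               reference = net$edges$reference))
  gml <- tempfile(fileext = ".graphml")
  igraph::write_graph(g, gml, format = "graphml")
  net2 <- read_network(gml, dialect = "graphml")
  expect_setequal(net2$nodes$id, net$nodes$id)
  expect_equal(sort(net2$edges$mechanism), sort(net$edges$mechanism))
  expect_equal(sort(net2$edges$if_score), sort(net$edges$if_score))
})

test_that("IF filtering flags strictly-below-threshold edges and never deletes", {
  net <- toy_net(list("A", "B", "activation",
                      "transcriptional_regulation", 0.9),
                 list("B", "C", "repression",
                      "transcriptional_regulation", 0.85))
  f <- filter_by_if(net, 0.86)
  expect_equal(f$edges$low_confidence, c(FALSE, TRUE))
  expect_equal(nrow(f$edges), 2L)

  expect_false(any(filter_by_if(net, 0)$edges$low_confidence))
  # boundary: scores equal to the threshold are kept at full confidence
  eq <- toy_net(list("A", "B", "activation",
                     "transcriptional_regulation", 0.86),
                list("B", "C", "activation",
                     "transcriptional_regulation", 0.86))
  expect_false(any(filter_by_if(eq, 0.86)$edges$low_confidence))
  # idempotence
  expect_identical(filter_by_if(f, 0.86), f)
})

test_that("virtual expansion connects members to complexes", {
  edges <- edge_df(list("flhD", "x"), list("flhC", "x"))
  net <- knowledge_network(edges,
                           members = list(FlhDC = c("flhD", "flhC")))
  ex <- expand_virtual(net)
  virt <- ex$edges[ex$edges$mechanism == "virtual", ]
  expect_equal(nrow(virt), 2L)
  expect_setequal(virt$source, c("flhD", "flhC"))
  expect_true(all(virt$target == "FlhDC"))
  expect_true(all(virt$sign == "activation"))
  expect_true(all(virt$directed))
  # original edges untouched, no new nodes
  expect_equal(nrow(ex$edges), nrow(net$edges) + 2L)
  expect_identical(ex$nodes, net$nodes)

  # no complexes: identity
  plain <- toy_net(list("A", "B"))
  expect_identical(expand_virtual(plain), plain)

  # unknown member named in the error
  bad <- knowledge_network(edges, members = list(Cx = c("flhD", "ghost")))
  expect_error(expand_virtual(bad), "ghost")
})

test_that("expansion adds exactly sum(|members|) edges over many complexes", {
  edges <- edge_df(list("a", "b"), list("c", "d"), list("e", "f"))
  net <- knowledge_network(edges, members = list(C1 = c("a", "b", "c"),
                                                 C2 = c("d", "e")))
  ex <- expand_virtual(net)
  expect_equal(nrow(ex$edges) - nrow(net$edges), 5L)
  expect_equal(nrow(ex$nodes), nrow(net$nodes))
})

test_that("mechanism views filter edges and endpoint nodes", {
  net <- toy_net(list("A", "B", "unknown", "correlation", 0.9),
                 list("B", "C", "activation",
                      "transcriptional_regulation", 0.9),
                 list("D", "E", "unknown", "ppi", 0.9))
  v <- mechanism_view(net, "correlation")
  expect_equal(nrow(v$edges), 1L)
  expect_false(v$edges$directed)
  expect_setequal(v$nodes$id, c("A", "B"))

  all_v <- mechanism_view(net, c("correlation", "transcriptional_regulation",
                                 "ppi", "metabolic", "virtual"))
  expect_setequal(all_v$nodes$id, net$nodes$id)
  expect_equal(nrow(all_v$edges), nrow(net$edges))

  none <- mechanism_view(toy_net(list("A", "B", "unknown", "correlation")),
                         "transcriptional_regulation")
  expect_equal(nrow(none$edges), 0L)
  expect_equal(nrow(none$nodes), 0L)
})
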