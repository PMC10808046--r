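test_that("network reconstruction mirrors the interaction matrix", {
  K <- matrix(0, 3, 3)
  K[1, 2] <- -5
  K[2, 3] <- 0.4
  K[3, 1] <- 2
  net <- reconstruct_network(K, c("a", "b", "c"))
  expect_identical(nrow(net$edges), 3L)
  e <- net$edges[net$edges$from == "a", ]
  expect_identical(e$to, "b")
  expect_identical(e$sign, "-")
  expect_equal(e$weight, 5)

  empty <- reconstruct_network(matrix(0, 4, 4), paste0("g", 1:4))
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(nrow(empty$nodes), 4L)
})

test_that("MCC matches hand-worked fixtures", {
  tri <- structure(list(
    nodes = data.frame(gene = c("a", "b", "c"), category = NA),
    edges = data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                       sign = "+", weight = 1)), class = "signed_network")
  expect_equal(unname(mcc_scores(tri)), c(2, 2, 2))

  path <- structure(list(
    nodes = data.frame(gene = c("a", "b", "c"), category = NA),
    edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                       sign = "+", weight = 1)), class = "signed_network")
  expect_equal(mcc_scores(path), c(a = 1, b = 2, c = 1))

  iso <- structure(list(
    nodes = data.frame(gene = c("a", "b", "x"), category = NA),
    edges = data.frame(from = "a", to = "b", sign = "+", weight = 1)),
    class = "signed_network")
  expect_equal(unname(mcc_scores(iso)["x"]), 0)

  # triangle-free neighborhoods: MCC equals the degree (star fixture)
  star <- structure(list(
    nodes = data.frame(gene = c("h", "l1", "l2", "l3"), category = NA),
    edges = data.frame(from = "h", to = c("l1", "l2", "l3"),
                       sign = "+", weight = 1)), class = "signed_network")
  expect_equal(mcc_scores(star), c(h = 3, l1 = 1, l2 = 1, l3 = 1))
})

test_that("MCC equals brute-force enumeration on random graphs", {
  for (rep in 1:20) {
    net <- random_signed_network(n = sample(4:12, 1), p = 0.35, seed = rep)
    got <- mcc_scores(net)
    want <- mcc_bruteforce(support_adjacency(net))
    expect_equal(got[order(names(got))], want[order(names(want))])
  }
})

test_that("bidirectional fitted pairs count once toward cliques", {
  both <- structure(list(
    nodes = data.frame(gene = c("a", "b"), category = NA),
    edges = data.frame(from = c("a", "b"), to = c("b", "a"),
                       sign = "+", weight = 1)), class = "signed_network")
  expect_equal(mcc_scores(both), c(a = 1, b = 1))
})

test_that("the union simplification rule keeps the right node set", {
  net <- random_signed_network(10, 0.4, seed = 7)
  sc <- data.frame(gene = net$nodes$gene,
                   mcc = c(9, 7, 6, 0, 3, 8, 2, 1, 0, 5),
                   mrer = c(0, 0, 0.5, 2, 1.5, 0.2, 0, 3, 0.9, 1.01))
  simp <- simplify_network(net, sc, mcc_min = 7, mrer_min = 1)
  keep <- sc$gene[sc$mcc >= 7 | sc$mrer > 1]
  expect_setequal(simp$nodes$gene, keep)
  expect_true(all(simp$edges$from %in% keep & simp$edges$to %in% keep))
  # edges are exactly those induced by the kept nodes
  orig <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ]
  expect_identical(nrow(simp$edges), nrow(orig))

  # vacuous thresholds keep everything
  all_in <- simplify_network(net, sc, mcc_min = 0, mrer_min = -Inf)
  expect_identical(all_in$nodes, net$nodes)
  expect_identical(all_in$edges, net$edges)

  # monotone: raising a threshold never adds nodes
  tight <- simplify_network(net, sc, mcc_min = 9, mrer_min = 2)
  expect_true(all(tight$nodes$gene %in% simp$nodes$gene))
})

test_that("SIF output has one line per edge plus isolated nodes", {
  net <- reconstruct_network(matrix(c(0, 0, 0.5, 0), 2, 2), c("a", "b"))
  path <- withr::local_tempfile(fileext = ".sif")
  write_network(net, path, "SIF")
  expect_identical(readLines(path), "a\tactivates\tb")

  empty <- reconstruct_network(matrix(0, 2, 2), c("a", "b"))
  write_network(empty, path, "SIF")
  expect_setequal(readLines(path), c("a", "b"))

  back <- read_network(path, "SIF")
  expect_setequal(back$nodes$gene, c("a", "b"))
  expect_identical(nrow(back$edges), 0L)
})

test_that("GraphML round-trips attributes through an independent parser", {
  set.seed(55)
  n <- 20
  K <- matrix(0, n, n)
  idx <- sample(which(row(K) != col(K)), 30)
  K[idx] <- sample(c(-1, 1), 30, TRUE) * runif(30, 0.1, 90)
  ids <- paste0("gene", seq_len(n))
  net <- reconstruct_network(K, ids)
  rates <- setNames(runif(n, 0, 3), ids)
  sc <- node_scores(net, rates)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, "GraphML", scores = sc)

  g <- read_network(path, "GraphML")
  expect_setequal(igraph::V(g)$name, ids)
  expect_equal(as.numeric(igraph::ecount(g)), 30)
  expect_equal(sort(igraph::E(g)$weight), sort(net$edges$weight))
  expect_equal(igraph::V(g)$mrer[match(ids, igraph::V(g)$name)],
               unname(rates))

  # independent reader: raw XML
  doc <- xml2::read_xml(path)
  xml_edges <- xml2::xml_find_all(doc, ".//*[local-name()='edge']")
  expect_length(xml_edges, 30)
  keys <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//*[local-name()='key']"), "attr.name")
  expect_true(all(c("weight", "sign_num", "mcc", "mrer") %in% keys))
})

test_that("edges pointing outside the node set are refused", {
  bad <- structure(list(
    nodes = data.frame(gene = "a", category = NA),
    edges = data.frame(from = "a", to = "ghost", sign = "+", weight = 1)),
    class = "signed_network")
  path <- withr::local_tempfile(fileext = ".sif")
  expect_error(write_network(bad, path, "SIF"), "endpoints")
  expect_error(write_network(bad, path, "bogus"))
})
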