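#' Signed interaction network from a fitted interaction matrix
#'
#' Every nonzero `k_{i,j}^g` becomes a directed edge i -> j with sign
#' (positive = activation, negative = repression) and weight `|k|`. All
#' genes appear as nodes, including isolated ones.
#'
#' @param K fitted interaction matrix (rows = source RNA, columns = target
#'   regulator), satisfying the sparsity invariant (entries 0 or
#'   `0.1 <= |k| <= 100`).
#' @param gene_ids node identifiers, one per row/column of `K`.
#' @param categories optional named character vector of node annotations.
#' @return Object of class `signed_network`: list with `nodes` (data.frame:
#'   `gene`, `category`) and `edges` (data.frame: `from`, `to`, `sign`,
#'   `weight`).
#' @export
reconstruct_network <- function(K, gene_ids, categories = NULL) {
  K <- as.matrix(K)
  n <- length(gene_ids)
  stopifnot(all(dim(K) == n))
  nz <- which(K != 0, arr.ind = TRUE)
  edges <- data.frame(from = gene_ids[nz[, 1]], to = gene_ids[nz[, 2]],
                      sign = ifelse(K[nz] > 0, "+", "-"),
                      weight = abs(K[nz]), stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$from, gene_ids),
                       match(edges$to, gene_ids)), , drop = FALSE]
  rownames(edges) <- NULL
  cat_vec <- if (is.null(categories)) rep(NA_character_, n)
             else unname(categories[gene_ids])
  structure(list(nodes = data.frame(gene = gene_ids, category = cat_vec,
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("signed_network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " signed edges\n", sep = "")
  invisible(x)
}

# undirected simple igraph over the network's support (an undirected edge
# wherever either direction is present); used for clique finding
undirected_support <- function(net) {
  nodes <- if (inherits(net, "signed_network")) net$nodes$gene else net$nodes
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
}

#' Maximal clique centrality (MCC)
#'
#' `MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!`,
#' computed on the undirected support of the network (sign, weight, and
#' direction ignored; a bidirectional pair counts as one undirected edge).
#' Isolated nodes score 0; in a triangle-free neighborhood MCC reduces to
#' the degree.
#'
#' @param net a `signed_network` or `causal_network`.
#' @param max_nodes guard against exponential clique enumeration on
#'   unexpectedly large inputs (default 2000 nodes).
#' @return Named integer-valued numeric vector of MCC scores, one per node.
#' @export
mcc_scores <- function(net, max_nodes = 2000) {
  g <- undirected_support(net)
  if (igraph::vcount(g) > max_nodes)
    stop("network exceeds the ", max_nodes, "-node clique-enumeration guard")
  scores <- setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  cliques <- igraph::max_cliques(g, min = 2)
  for (cl in cliques) {
    members <- igraph::V(g)$name[as.integer(cl)]
    scores[members] <- scores[members] + factorial(length(cl) - 1)
  }
  scores
}

#' Node score table (MCC + MRER)
#'
#' @param net a `signed_network`.
#' @param mrer_overall named per-gene overall MRER (from [mrer()]).
#' @param mrer_per_stage optional stage-by-gene MRER matrix, appended as
#'   `mrer_<stage>` columns.
#' @return data.frame with `gene`, `mcc`, `mrer`, `degree`.
#' @export
node_scores <- function(net, mrer_overall, mrer_per_stage = NULL) {
  genes <- net$nodes$gene
  mcc <- mcc_scores(net)
  g <- undirected_support(net)
  deg <- igraph::degree(g)
  out <- data.frame(gene = genes, mcc = unname(mcc[genes]),
                    mrer = unname(mrer_overall[genes]),
                    degree = unname(deg[genes]), stringsAsFactors = FALSE)
  if (!is.null(mrer_per_stage))
    for (s in rownames(mrer_per_stage))
      out[[paste0("mrer_", s)]] <- unname(mrer_per_stage[s, genes])
  out
}

#' Simplify a network by the MCC/MRER union rule
#'
#' Retains the nodes satisfying `MCC >= mcc_min` OR `MRER > mrer_min` and
#' the edges whose both endpoints survive; the input network is not
#' modified.
#'
#' @param net a `signed_network`.
#' @param scores data.frame from [node_scores()] (columns `gene`, `mcc`,
#'   `mrer`).
#' @param mcc_min MCC threshold (default 7).
#' @param mrer_min MRER threshold, exceeded strictly (default 1).
#' @return The simplified `signed_network`.
#' @export
simplify_network <- function(net, scores, mcc_min = 7, mrer_min = 1) {
  if (!all(net$nodes$gene %in% scores$gene))
    stop("scores do not cover all nodes")
  sc <- scores[match(net$nodes$gene, scores$gene), ]
  keep <- sc$mcc >= mcc_min | sc$mrer > mrer_min
  kept <- net$nodes$gene[keep]
  edges <- net$edges[net$edges$from %in% kept & net$edges$to %in% kept, ,
                     drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = net$nodes[keep, , drop = FALSE], edges = edges),
            class = "signed_network")
}

# ---- network serialization --------------------------------------------------

net_nodes <- function(net) {
  if (inherits(net, "signed_network")) net$nodes$gene else net$nodes
}

#' Write a network to SIF or GraphML
#'
#' SIF uses one edge per line (`source relation target`) with relation
#' tokens `activates`/`represses` for signed networks and `tdmi` for TDMI
#' networks; isolated nodes are written as single-token lines. GraphML
#' (via igraph) carries numeric edge attributes (weight, sign, lag where
#' available) and node attributes (category, and any columns of `scores`).
#'
#' @param net a `signed_network` or `causal_network`.
#' @param path output file.
#' @param format `"SIF"` or `"GraphML"`.
#' @param scores optional [node_scores()] table stored as GraphML node
#'   attributes.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("SIF", "GraphML"),
                          scores = NULL) {
  format <- match.arg(format)
  nodes <- net_nodes(net)
  edges <- net$edges
  if (nrow(edges) &&
      !all(c(edges$from, edges$to) %in% nodes))
    stop("edge endpoints missing from the node set")
  relation <- if (inherits(net, "signed_network")) {
    ifelse(edges$sign == "+", "activates", "represses")
  } else rep("tdmi", nrow(edges))
  if (format == "SIF") {
    lines <- character(0)
    if (nrow(edges))
      lines <- paste(edges$from, relation, edges$to, sep = "\t")
    isolated <- setdiff(nodes, c(edges$from, edges$to))
    writeLines(c(lines, isolated), path)
    return(invisible(path))
  }
  vert <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (inherits(net, "signed_network") && !all(is.na(net$nodes$category)))
    vert$category <- net$nodes$category
  if (!is.null(scores)) {
    sc <- scores[match(nodes, scores$gene), setdiff(names(scores), "gene"),
                 drop = FALSE]
    vert <- cbind(vert, sc)
  }
  ed <- edges
  if (inherits(net, "signed_network")) {
    ed$sign_num <- ifelse(edges$sign == "+", 1, -1)
    ed$sign <- NULL
  }
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = vert)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path SIF or GraphML file.
#' @param format `"SIF"` or `"GraphML"`.
#' @return For SIF, a `signed_network` (relation `tdmi` edges get sign `+`
#'   and weight `NA`); for GraphML, the igraph object with all attributes.
#' @export
read_network <- function(path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  if (format == "GraphML")
    return(igraph::read_graph(path, format = "graphml"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  edges <- do.call(rbind, lapply(parts[nfield == 3], function(p)
    data.frame(from = p[1], relation = p[2], to = p[3],
               stringsAsFactors = FALSE)))
  isolated <- unlist(parts[nfield == 1])
  if (is.null(edges))
    edges <- data.frame(from = character(0), relation = character(0),
                        to = character(0), stringsAsFactors = FALSE)
  nodes <- unique(c(edges$from, edges$to, isolated))
  structure(list(nodes = data.frame(gene = nodes,
                                    category = NA_character_,
                                    stringsAsFactors = FALSE),
                 edges = data.frame(from = edges$from, to = edges$to,
                                    sign = ifelse(edges$relation == "represses",
                                                  "-", "+"),
                                    weight = rep(NA_real_, nrow(edges)),
                                    stringsAsFactors = FALSE)),
            class = "signed_network")
}
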