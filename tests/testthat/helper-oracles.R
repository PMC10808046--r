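# brute-force maximal-clique MCC oracle for small graphs (n <= 14):
# enumerate all vertex subsets, keep cliques with no extending vertex
mcc_bruteforce <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 14)
  scores <- setNames(numeric(n), rownames(adj))
  for (code in seq_len(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < 2) next
    sub <- adj[members, members, drop = FALSE]
    if (any(sub[upper.tri(sub)] == 0)) next
    outside <- setdiff(seq_len(n), members)
    extendable <- any(vapply(outside, function(v)
      all(adj[v, members] > 0), logical(1)))
    if (!extendable)
      scores[members] <- scores[members] + factorial(length(members) - 1)
  }
  scores
}

# adjacency of a signed_network's undirected support
support_adjacency <- function(net) {
  genes <- net$nodes$gene
  adj <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
  for (k in seq_len(nrow(net$edges))) {
    i <- match(net$edges$from[k], genes)
    j <- match(net$edges$to[k], genes)
    if (i != j) adj[i, j] <- adj[j, i] <- 1
  }
  adj
}

# random signed network on n nodes with edge probability p
random_signed_network <- function(n, p, seed) {
  set.seed(seed)
  genes <- paste0("n", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  on <- runif(nrow(pairs)) < p
  edges <- data.frame(from = genes[pairs[on, 1]], to = genes[pairs[on, 2]],
                      sign = sample(c("+", "-"), sum(on), TRUE),
                      weight = runif(sum(on), 0.1, 5),
                      stringsAsFactors = FALSE)
  structure(list(nodes = data.frame(gene = genes,
                                    category = NA_character_,
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "signed_network")
}

# small single-gene model with no interactions: closed-form fixed point
single_gene_fixture <- function(kr = 1.2, gamma = 0.4, alpha = 0.6,
                                beta = 0.3, span = 20) {
  params <- cim_parameters(kr = kr, gamma = gamma, g0 = alpha / beta,
                           alpha = alpha, beta = beta,
                           K = matrix(0, 1, 1), gene_ids = "g1")
  schedule <- stage_schedule(labels = "G1", times = span,
                             weights = matrix(1, 1, 1))
  g_star <- alpha / beta
  list(params = params, schedule = schedule, g_star = g_star,
       rna_star = kr * g_star / gamma)
}
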