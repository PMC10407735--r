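# Independent brute-force oracles used to cross-check the implementation.

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix
fwDistances <- function(adj) {
    n <- nrow(adj)
    D <- ifelse(adj > 0, 1, Inf)
    diag(D) <- 0
    for (k in seq_len(n))
        D <- pmin(D, outer(D[, k], D[k, ], `+`))
    D
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
fisherOracle <- function(tab) {
    m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
    x <- tab[1L, 1L]
    support <- max(0L, k - n):min(k, m)
    d <- stats::dhyper(support, m, n, k)
    sum(d[d <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
}

# two-sided exact binomial p by point-probability enumeration
binomOracle <- function(x, n, p) {
    d <- stats::dbinom(0:n, n, p)
    sum(d[d <= stats::dbinom(x, n, p) * (1 + 1e-7)])
}

# mean pair distance of a node subset with the max-finite imputation rule
meanPairDistOracle <- function(D, ix) {
    d <- D[ix, ix][upper.tri(matrix(0, length(ix), length(ix)))]
    if (any(is.infinite(d))) d[is.infinite(d)] <- max(d[is.finite(d)])
    mean(d)
}

randomIgraph <- function(n, p, seed) {
    set.seed(seed)
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
    list(graph = g, adj = adj)
}
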