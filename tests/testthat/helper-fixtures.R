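# In-code fixture builders shared across the suite.

make_meta <- function(ids, morph = "species_1", locus = "mtCOI") {
  data.frame(specimen_id = ids,
             morphospecies_label = rep_len(morph, length(ids)),
             locality = "site_1",
             in_britain_or_ireland = TRUE,
             source = "new",
             locus = locus,
             stringsAsFactors = FALSE)
}

make_alignment <- function(seqs, morph = "species_1") {
  alignment(seqs, make_meta(names(seqs), morph))
}

# wrap an arbitrary symmetric matrix as a k2p_dist for partition/tree tests
make_dist <- function(d, labels = NULL) {
  if (is.null(labels)) labels <- paste0("H", seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)
  structure(list(d = d, sites_used = matrix(100L, nrow(d), ncol(d),
                                            dimnames = dimnames(d)),
                 labels = labels, flagged = matrix(character(0), ncol = 2L)),
            class = "k2p_dist")
}

# random symmetric distance matrix with zero diagonal
random_dist <- function(n, max_d = 0.3) {
  d <- matrix(0, n, n)
  vals <- stats::runif(n * (n - 1) / 2, 0, max_d)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  make_dist(d)
}

# independent oracle: connected components of the graph joining pairs at
# distance <= threshold, via igraph, relabelled by smallest member index
oracle_components <- function(d, threshold) {
  n <- nrow(d)
  adj <- (d <= threshold) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  match(comp, unique(comp))
}

# distance matrix with planted cluster structure: within-cluster distances
# drawn near `intra`, between-cluster near `inter`
clustered_dist <- function(sizes, intra = 0.01, inter = 0.3, jitter = 0.002) {
  n <- sum(sizes)
  cl <- rep(seq_along(sizes), sizes)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      base <- if (cl[i] == cl[j]) intra else inter
      d[i, j] <- d[j, i] <- abs(base + stats::runif(1, -jitter, jitter))
    }
  }
  list(dm = make_dist(d), clusters = cl)
}

# brute-force K2P between two character vectors; deliberately written
# differently from the package implementation (explicit site loop)
brute_k2p <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  bases <- c("A", "C", "G", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (k in seq_along(a)) {
    if (!(a[k] %in% bases) || !(b[k] %in% bases)) next
    n <- n + 1L
    if (a[k] == b[k]) next
    pur <- c(A = "R", G = "R", C = "Y", T = "Y")
    if (pur[[a[k]]] == pur[[b[k]]]) ts <- ts + 1L else tv <- tv + 1L
  }
  P <- ts / n; Q <- tv / n
  list(d = -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)),
       P = P, Q = Q, sites_used = n)
}
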