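# Independent brute-force oracles and tiny fixture helpers.  These never
# call the sketch/DTR code paths they are used to check.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Reverse complement without Biostrings (keeps the oracle independent of
# the package's own I/O helpers).
rc_oracle <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# All distinct canonical k-mers of a sequence, by direct enumeration.
canon_kmers <- function(seq, k = 17) {
  n <- nchar(seq)
  if (n < k) return(character())
  kms <- substring(seq, 1:(n - k + 1), k:n)
  unique(pmin(kms, rc_oracle(kms)))
}

# Exact Jaccard index of the canonical k-mer sets of two sequences.
exact_jaccard <- function(s1, s2, k = 17) {
  a <- canon_kmers(s1, k)
  b <- canon_kmers(s2, k)
  length(intersect(a, b)) / length(union(a, b))
}

# Closed-form Mash distance from an exact Jaccard.
mash_closed_form <- function(j, k = 17) {
  if (j <= 0) return(1)
  min(1, max(0, -(1 / k) * log(2 * j / (1 + j))))
}

# Brute-force all-length DTR scan (longest L whose prefix/suffix differ in
# at most max_mismatch positions), written against character vectors.
brute_dtr <- function(seq, min_len = 10, max_mismatch = 1) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  for (L in seq(n %/% 2, min_len)) {
    if (L < min_len) break
    mism <- sum(ch[1:L] != ch[(n - L + 1):n])
    if (mism <= max_mismatch) return(list(found = TRUE, length = L, n_mismatch = mism))
  }
  list(found = FALSE, length = NA, n_mismatch = NA)
}

# Plain-vanilla MCL (no pruning, fixed iteration count): an independent
# second implementation used to cross-check partitions.
mcl_oracle <- function(adj, inflation = 2, iters = 60) {
  M <- abs(adj)
  diag(M) <- pmax(diag(M), 1)
  M <- sweep(M, 2, colSums(M), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
  }
  g <- igraph::graph_from_adjacency_matrix((M + t(M)) > 1e-8,
                                           mode = "undirected", diag = FALSE)
  memb <- igraph::components(g)$membership
  names(memb) <- rownames(adj)
  memb
}

# Compare two flat partitions up to label permutation.
same_partition <- function(a, b) {
  a <- a[sort(names(a))]
  b <- b[sort(names(b))]
  setequal(
    lapply(split(names(a), a), sort),
    lapply(split(names(b), b), sort))
}

# Minimum spanning tree total weight of a distance matrix.
mst_weight <- function(d) {
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sum(igraph::E(igraph::mst(g))$weight)
}
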