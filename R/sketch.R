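#' Build a strand-neutral MinHash sketch of a nucleotide sequence
#'
#' Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
#' complement) are hashed with a fixed, seeded 64-bit hash (splitmix64,
#' truncated to its top 53 bits so values are exactly representable as R
#' doubles) and the `s` smallest distinct hash values are retained.  k-mers
#' containing non-ACGT symbols (e.g. N runs in draft assemblies) are skipped.
#'
#' @param seq A single nucleotide sequence (character scalar, A/C/G/T case
#'   insensitive).
#' @param k k-mer length; 17 matches the pipeline-wide default.
#' @param s Sketch capacity (number of retained hashes); 3000 is used for
#'   PLS-versus-PLS distance matrices.
#' @param id Source identifier stored in the sketch.
#' @return An object of class `kmer_sketch`: a list with `source_id`, `k`,
#'   `s`, `hashes` (sorted strictly increasing numeric vector of length
#'   `min(s, n_kmers)`), and `n_kmers` (distinct canonical k-mers in the
#'   source).
#' @examples
#' sk <- build_sketch("ACGTACGGTACGATCGATCGTACG", k = 5, s = 100)
#' sk$n_kmers
#' @export
build_sketch <- function(seq, k = 17, s = 3000, id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < k) {
    stop("sequence '", id, "' too short to sketch (", nchar(seq), " < k = ", k, ")")
  }
  raw <- .sketch_seq_cpp(seq, as.integer(k), as.integer(s))
  structure(
    list(source_id = id, k = as.integer(k), s = as.integer(s),
         hashes = raw$hashes, n_kmers = raw$n_kmers),
    class = "kmer_sketch"
  )
}

#' Sketch every sequence in a collection
#'
#' @param seqs Named character vector of sequences.
#' @inheritParams build_sketch
#' @return Named list of `kmer_sketch` objects.  Unsketchable members (too
#'   short) abort with a message listing their ids.
#' @export
build_sketches <- function(seqs, k = 17, s = 3000) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  bad <- names(seqs)[nchar(seqs) < k]
  if (length(bad)) {
    stop("sequence(s) too short to sketch: ", paste(bad, collapse = ", "))
  }
  out <- lapply(names(seqs), function(id) build_sketch(seqs[[id]], k, s, id = id))
  names(out) <- names(seqs)
  out
}

#' Mash-style distance between two sketches
#'
#' The Jaccard index `j` is estimated from the smallest
#' `min(s, |union|)` hashes of the union of the two sketches, and converted
#' to a distance with the Mash estimator `d = -(1/k) * ln(2j / (1 + j))`.
#' Sketches sharing no hashes get distance 1; identical non-empty sketches
#' get 0.
#'
#' @param a,b `kmer_sketch` objects with equal `k`.
#' @return Distance in `[0, 1]`.
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "kmer_sketch"), inherits(b, "kmer_sketch"))
  if (a$k != b$k) stop("sketches have mismatched k (", a$k, " vs ", b$k, ")")
  j <- sketch_jaccard(a, b)
  jaccard_to_distance(j, a$k)
}

#' Bottom-s Jaccard estimate between two sketches
#'
#' @inheritParams mash_distance
#' @return Estimated Jaccard index in `[0, 1]`.
#' @export
sketch_jaccard <- function(a, b) {
  u <- sort(unique(c(a$hashes, b$hashes)))
  su <- min(min(a$s, b$s), length(u))
  if (su == 0L) return(0)
  u <- u[seq_len(su)]
  sum(u %in% a$hashes & u %in% b$hashes) / su
}

#' Convert a Jaccard index to a Mash distance
#'
#' @param j Jaccard index in `[0, 1]`.
#' @param k k-mer length the Jaccard was computed at.
#' @return `-(1/k) * ln(2j/(1+j))`, capped into `[0, 1]`; `j = 0` maps to 1.
#' @export
jaccard_to_distance <- function(j, k) {
  ifelse(j <= 0, 1, pmin(1, pmax(0, -(1 / k) * log(2 * j / (1 + j)))))
}

#' Pairwise Mash distance matrix for a sequence collection
#'
#' @param seqs Named character vector of sequences.
#' @param k,s Sketch parameters.
#' @param sketches Optionally, a pre-built named list of sketches (then
#'   `seqs` is ignored).
#' @return Symmetric numeric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames = sequence ids.
#' @export
pairwise_distance_matrix <- function(seqs = NULL, k = 17, s = 3000, sketches = NULL) {
  if (is.null(sketches)) sketches <- build_sketches(seqs, k = k, s = s)
  ids <- names(sketches)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (jdx in seq(i + 1L, n)) {
        d[i, jdx] <- d[jdx, i] <- mash_distance(sketches[[i]], sketches[[jdx]])
      }
    }
  }
  d
}

#' Distances from one sketch to a list of sketches
#'
#' @param query A `kmer_sketch`.
#' @param sketches Named list of `kmer_sketch` objects.
#' @return Named numeric vector of distances.
#' @export
distances_to_set <- function(query, sketches) {
  vapply(sketches, function(sk) mash_distance(query, sk), numeric(1))
}

# Basic checks shared by consumers of distance matrices.
validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d))) {
    stop("distance matrix needs matching row/column names")
  }
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(d < 0 | d > 1)) stop("distances must lie in [0, 1]")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  invisible(d)
}

#' Serialize sketches to a JSON-lines file
#'
#' One JSON object per line with fields `source_id`, `k`, `s`, `n_kmers`,
#' `hashes`.
#'
#' @param sketches Named list of `kmer_sketch` objects.
#' @param path Output path.
#' @export
write_sketches <- function(sketches, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sk in sketches) {
    # hashes are 53-bit integers stored as doubles; serialize them as
    # decimal strings so no precision is lost in the JSON round trip
    writeLines(jsonlite::toJSON(
      list(source_id = sk$source_id, k = sk$k, s = sk$s,
           n_kmers = sk$n_kmers, hashes = sprintf("%.0f", sk$hashes)),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read sketches from a JSON-lines file
#'
#' @param path Path written by [write_sketches()].
#' @return Named list of `kmer_sketch` objects.
#' @export
read_sketches <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    structure(list(source_id = x$source_id, k = as.integer(x$k),
                   s = as.integer(x$s), hashes = as.numeric(x$hashes),
                   n_kmers = as.numeric(x$n_kmers)),
              class = "kmer_sketch")
  })
  names(out) <- vapply(out, `[[`, "", "source_id")
  out
}

#' Write a distance matrix as TSV with an id header row and column
#'
#' @param d Distance matrix with dimnames.
#' @param path Output path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path Input path.
#' @return Numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
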