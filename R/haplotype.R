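#' Canonical rotation of a circular sequence
#'
#' Returns the lexicographically smallest string over all rotations of the
#' sequence and of its reverse complement (Booth's least-rotation
#' algorithm on both strands).  Cyclic permutations and strand flips of
#' the same circular molecule therefore map to one canonical form.
#'
#' @param seq Nucleotide sequence (character scalar, non-empty).
#' @return Canonical sequence.
#' @export
canonical_rotation <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  min(.least_rotation_cpp(seq), .least_rotation_cpp(revcomp(seq)))
}

#' Prepare circular PLS members for haplotype analysis
#'
#' Members without an exact direct terminal repeat of at least `min_dtr`
#' bp (mismatch = 0, stricter than the completeness screen) are dropped;
#' one terminal copy of the repeat is removed and the remaining sequence
#' is rotation- and strand-normalized with [canonical_rotation()].
#'
#' @param seqs Named character vector of member sequences.
#' @param min_dtr Minimum exact DTR length (default 10).
#' @return data.frame with `member_id`, `seq` (canonical), `dtr_length`;
#'   dropped members are absent.
#' @export
prepare_members <- function(seqs, min_dtr = 10) {
  rows <- list()
  for (id in names(seqs)) {
    dtr <- find_dtr(seqs[[id]], min_len = min_dtr, max_mismatch = 0)
    if (!dtr$found) next
    core <- substr(seqs[[id]], 1L, nchar(seqs[[id]]) - dtr$length)
    rows[[length(rows) + 1L]] <- data.frame(
      member_id = id, seq = canonical_rotation(core), dtr_length = dtr$length,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(member_id = character(), seq = character(),
                      dtr_length = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Gapped alignment strings of a global pairwise alignment.
.gapped_strings <- function(aln) {
  ns <- asNamespace("Biostrings")
  if (exists("alignedPattern", where = ns)) {
    list(p = as.character(Biostrings::alignedPattern(aln)),
         s = as.character(Biostrings::alignedSubject(aln)))
  } else {
    list(p = as.character(Biostrings::pattern(aln)),
         s = as.character(Biostrings::subject(aln)))
  }
}

#' Reference-guided multiple alignment of near-identical members
#'
#' A progressive pairwise scheme adequate above ~99\% identity: the member
#' of median length is the reference, every other member is globally
#' aligned to it ([Biostrings::pairwiseAlignment()]), and the pairwise
#' alignments are merged into common columns, opening shared insertion
#' columns where any member inserts relative to the reference.  An
#' externally produced alignment (one aligned row per member) can be
#' supplied downstream instead.
#'
#' @param seqs Named character vector (normalized members).
#' @param reference Optional reference member id; default: the member with
#'   length closest to the median (ties to the shorter, then lexicographic
#'   id).
#' @return Character matrix (members x alignment columns, gap = `"-"`)
#'   with attribute `reference`.
#' @export
align_members <- function(seqs, reference = NULL) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  lens <- nchar(seqs)
  if (is.null(reference)) {
    med <- stats::median(lens)
    reference <- ids[order(abs(lens - med), lens, ids)][1]
  }
  ref <- seqs[[reference]]
  L <- nchar(ref)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  chars <- list()
  inserts <- list()
  for (id in ids) {
    if (id == reference) {
      chars[[id]] <- strsplit(ref, "")[[1]]
      inserts[[id]] <- list()
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(seqs[[id]]),
      subject = Biostrings::DNAString(ref),
      type = "global", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    g <- .gapped_strings(aln)
    p <- strsplit(g$p, "")[[1]]
    s <- strsplit(g$s, "")[[1]]
    mc <- character(L)
    ins <- list()
    rpos <- 0L
    for (j in seq_along(s)) {
      if (s[j] != "-") {
        rpos <- rpos + 1L
        mc[rpos] <- p[j]
      } else {
        key <- as.character(rpos)
        ins[[key]] <- paste0(if (is.null(ins[[key]])) "" else ins[[key]], p[j])
      }
    }
    chars[[id]] <- mc
    inserts[[id]] <- ins
  }
  width <- integer(L + 1L)  # insertion block after ref position 0..L
  for (id in ids) {
    for (key in names(inserts[[id]])) {
      pos <- as.integer(key) + 1L
      width[pos] <- max(width[pos], nchar(inserts[[id]][[key]]))
    }
  }
  ncol_out <- L + sum(width)
  out <- matrix("-", length(ids), ncol_out, dimnames = list(ids, NULL))
  for (id in ids) {
    row <- character(0)
    for (pos in 0:L) {
      if (pos > 0L) row <- c(row, chars[[id]][pos])
      w <- width[pos + 1L]
      if (w > 0L) {
        insstr <- inserts[[id]][[as.character(pos)]]
        ichars <- if (is.null(insstr)) character(0) else strsplit(insstr, "")[[1]]
        row <- c(row, ichars, rep("-", w - length(ichars)))
      }
    }
    out[id, ] <- row
  }
  attr(out, "reference") <- reference
  out
}

#' Remove members with long indels relative to the reference
#'
#' Any member whose alignment against the median-length reference contains
#' an insertion or deletion run of 2 bp or more is removed; single-base
#' indels are kept (they are counted as haplotype differences).  Columns
#' where both the member and the reference are gapped (insertions private
#' to other members) are neutral and do not break runs.
#'
#' @param msa Alignment matrix from [align_members()].
#' @param reference Reference member id (default: the matrix attribute).
#' @param max_indel Longest tolerated indel run (default 1).
#' @return Filtered alignment matrix (same attribute).
#' @export
filter_msa_members <- function(msa, reference = attr(msa, "reference"),
                               max_indel = 1) {
  stopifnot(reference %in% rownames(msa))
  refrow <- msa[reference, ]
  keep <- vapply(rownames(msa), function(id) {
    mrow <- msa[id, ]
    active <- !(mrow == "-" & refrow == "-")
    state <- ifelse(mrow[active] == "-", "del",
                    ifelse(refrow[active] == "-", "ins", "match"))
    r <- rle(state)
    !any(r$lengths[r$values != "match"] > max_indel)
  }, logical(1))
  out <- msa[keep, , drop = FALSE]
  attr(out, "reference") <- reference
  out
}

#' Collapse aligned members into haplotypes
#'
#' Identical aligned rows (gaps count as a fifth character state, so
#' single-base indels separate haplotypes) merge into one haplotype;
#' pairwise haplotype differences are Hamming distances over alignment
#' columns and therefore reflect all differences in the complete
#' sequences.
#'
#' @param msa Alignment matrix (members x columns).
#' @return Object of class `haplotype_table`: list with `signatures`
#'   (haplotypes x columns character matrix), `members` (named list of
#'   member ids per haplotype), and `table` (summary data.frame).
#' @export
collapse_haplotypes <- function(msa) {
  keys <- apply(msa, 1, paste, collapse = "")
  uk <- unique(keys)
  hap_ids <- sprintf("Hap_%d", seq_along(uk))
  members <- lapply(uk, function(k) rownames(msa)[keys == k])
  names(members) <- hap_ids
  sigs <- msa[match(uk, keys), , drop = FALSE]
  rownames(sigs) <- hap_ids
  structure(
    list(signatures = sigs, members = members,
         table = data.frame(hap_id = hap_ids,
                            n_members = lengths(members),
                            member_ids = vapply(members, paste, "", collapse = ","),
                            stringsAsFactors = FALSE)),
    class = "haplotype_table")
}

#' Hamming distance matrix between haplotype signatures
#'
#' @param sigs Character matrix (rows = haplotypes).
#' @return Integer matrix of pairwise differing-column counts.
#' @export
hap_distances <- function(sigs) {
  n <- nrow(sigs)
  d <- matrix(0L, n, n, dimnames = list(rownames(sigs), rownames(sigs)))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d[i, j] <- d[j, i] <- sum(sigs[i, ] != sigs[j, ])
      }
    }
  }
  d
}

# Minimum-spanning-network edges: pair (i, j) is linked iff its distance
# does not exceed the single-linkage merge level of i and j plus epsilon
# (epsilon = 0 gives the union of all minimum spanning trees).
.msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2L) {
    return(data.frame(from = character(), to = character(), w = numeric(),
                      stringsAsFactors = FALSE))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  coph <- as.matrix(stats::cophenetic(hc))
  idx <- which(upper.tri(d) & d <= coph + epsilon, arr.ind = TRUE)
  data.frame(from = rownames(d)[idx[, 1]], to = colnames(d)[idx[, 2]],
             w = d[idx], stringsAsFactors = FALSE)
}

# Columnwise quasi-median of three signature rows: the majority state, ties
# resolved toward u (the shared network neighbor) for determinism.
.triple_median <- function(u, v, w) {
  ifelse(v == w, v, ifelse(u == v | u == w, u, u))
}

#' Median-joining haplotype network
#'
#' Bandelt's median-joining construction with parameter `epsilon`
#' (default 0, the common PopART setting) and uniform column weights:
#' iteratively builds the minimum-spanning network over the current
#' vectors and, for triples linked through a shared neighbor, adds the
#' columnwise-majority median vector; inferred medians not lying on any
#' shortest (Hamming-geodesic) path between observed haplotypes are
#' pruned, and redundant tie edges (those with an equal-or-shorter
#' alternative path) are removed from the final network.
#'
#' @param haps A `haplotype_table` or a character signature matrix.
#' @param epsilon MSN relaxation parameter (default 0).
#' @param max_rounds Cap on median-addition rounds (default 8).
#' @param max_nodes Safety cap on total nodes (default 500).
#' @return Object of class `mj_network`: list with `nodes` (data.frame
#'   `node_id`, `is_median`, `n_members`), `edges` (data.frame `from`,
#'   `to`, `n_diff`), and `signatures`.
#' @export
median_joining_network <- function(haps, epsilon = 0, max_rounds = 8,
                                   max_nodes = 500) {
  sigs <- if (inherits(haps, "haplotype_table")) haps$signatures else haps
  stopifnot(is.matrix(sigs), nrow(sigs) >= 1L)
  observed <- rownames(sigs)
  n_members <- if (inherits(haps, "haplotype_table")) {
    lengths(haps$members)[observed]
  } else {
    stats::setNames(rep(1L, nrow(sigs)), observed)
  }
  med_count <- 0L
  for (round in seq_len(max_rounds)) {
    d <- hap_distances(sigs)
    E <- .msn_edges(d, epsilon)
    if (!nrow(E)) break
    nbrs <- split(c(E$to, E$from), c(E$from, E$to))
    existing <- apply(sigs, 1, paste, collapse = "")
    new_rows <- list()
    for (u in rownames(sigs)) {
      nb <- unique(nbrs[[u]])
      if (length(nb) < 2L) next
      cmb <- utils::combn(sort(nb), 2L)
      for (c_i in seq_len(ncol(cmb))) {
        m <- .triple_median(sigs[u, ], sigs[cmb[1, c_i], ], sigs[cmb[2, c_i], ])
        key <- paste(m, collapse = "")
        if (!(key %in% existing) && is.null(new_rows[[key]])) new_rows[[key]] <- m
      }
    }
    if (!length(new_rows)) break
    if (nrow(sigs) + length(new_rows) > max_nodes) {
      warning("median-joining node cap reached; stopping early")
      break
    }
    add <- do.call(rbind, new_rows)
    rownames(add) <- sprintf("Med_%d", med_count + seq_len(nrow(add)))
    med_count <- med_count + nrow(add)
    sigs <- rbind(sigs, add)
  }
  # prune medians off every observed-to-observed Hamming geodesic
  d <- hap_distances(sigs)
  medians <- setdiff(rownames(sigs), observed)
  keep_med <- vapply(medians, function(m) {
    if (length(observed) < 2L) return(FALSE)
    for (i in seq_len(length(observed) - 1L)) {
      for (j in seq(i + 1L, length(observed))) {
        x <- observed[i]; y <- observed[j]
        if (d[x, m] + d[m, y] == d[x, y]) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  sigs <- sigs[c(observed, medians[keep_med]), , drop = FALSE]
  d <- hap_distances(sigs)
  E <- .msn_edges(d, epsilon)
  # drop redundant tie edges (an alternative path no longer than the edge)
  if (nrow(E) > 1L) {
    E <- E[order(-E$w, E$from, E$to), ]
    keep <- rep(TRUE, nrow(E))
    for (i in seq_len(nrow(E))) {
      sub <- E[keep & seq_len(nrow(E)) != i, , drop = FALSE]
      if (!nrow(sub)) next
      g <- igraph::graph_from_data_frame(sub, directed = FALSE,
                                         vertices = data.frame(name = rownames(sigs)))
      alt <- igraph::distances(g, v = E$from[i], to = E$to[i], weights = sub$w)[1, 1]
      if (is.finite(alt) && alt <= E$w[i]) keep[i] <- FALSE
    }
    E <- E[keep, , drop = FALSE]
  }
  nodes <- data.frame(
    node_id = rownames(sigs),
    is_median = !(rownames(sigs) %in% observed),
    n_members = ifelse(rownames(sigs) %in% observed,
                       n_members[rownames(sigs)], 0L),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = E$from, to = E$to, n_diff = as.integer(E$w),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, signatures = sigs),
            class = "mj_network")
}

#' Transmission time window from a mutation count
#'
#' Scales a genome-wide molecular clock (`genome_rate` mutations per year
#' on a genome of `genome_len` bp; defaults follow the Helicobacter pylori
#' clock of ~30 mutations/year on ~1.67 Mb) to a plasmid of `plasmid_len`
#' bp: the plasmid-scale rate is
#' `lambda = genome_rate * plasmid_len / genome_len` per year.  Zero
#' observed differences yield the window `[0, 1/lambda]` (upper bound
#' rounded to the nearest year); a positive count yields the point
#' estimate `n_mut / lambda`.
#'
#' @param n_mut Observed nucleotide differences (>= 0).
#' @param plasmid_len Plasmid length in bp (> 0).
#' @param genome_rate Genome mutations per year (default 30).
#' @param genome_len Genome length in bp (default 1670000).
#' @return List with `lambda` (mutations/year on the plasmid) and either
#'   `lower`/`upper` (years, `type = "window"`) or `years`
#'   (`type = "point"`).
#' @examples
#' transmission_window(0, 5600)$upper  # ~10 years
#' @export
transmission_window <- function(n_mut, plasmid_len, genome_rate = 30,
                                genome_len = 1670000) {
  if (plasmid_len <= 0) stop("plasmid length must be positive")
  lambda <- genome_rate * plasmid_len / genome_len
  if (lambda <= 0) stop("scaled mutation rate is zero")
  if (n_mut == 0) {
    list(type = "window", lower = 0, upper = round(1 / lambda), lambda = lambda)
  } else {
    list(type = "point", years = n_mut / lambda, lambda = lambda)
  }
}

#' Write a haplotype table as TSV
#'
#' @param haps A `haplotype_table`.
#' @param path Output path.
#' @export
write_haplotypes <- function(haps, path) {
  stopifnot(inherits(haps, "haplotype_table"))
  write_tsv(haps$table, path)
  invisible(path)
}

#' Export a median-joining network
#'
#' Writes `<prefix>.edges.tsv` and `<prefix>.graphml`.
#'
#' @param net An `mj_network`.
#' @param path_prefix Output prefix.
#' @export
write_mj_network <- function(net, path_prefix) {
  stopifnot(inherits(net, "mj_network"))
  write_tsv(net$edges, paste0(path_prefix, ".edges.tsv"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, paste0(path_prefix, ".graphml"), format = "graphml")
  invisible(path_prefix)
}

#' Write haplotypes as a Nexus-style data block
#'
#' A minimal NEXUS file (TAXA + CHARACTERS blocks) interoperable with
#' population-genetics viewers.
#'
#' @param haps A `haplotype_table`.
#' @param path Output path.
#' @export
write_haplotype_nexus <- function(haps, path) {
  stopifnot(inherits(haps, "haplotype_table"))
  sigs <- haps$signatures
  rows <- apply(sigs, 1, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN TAXA;",
               sprintf("  DIMENSIONS NTAX=%d;", nrow(sigs)),
               "  TAXLABELS", paste0("    ", rownames(sigs)), "  ;", "END;",
               "", "BEGIN CHARACTERS;",
               sprintf("  DIMENSIONS NCHAR=%d;", ncol(sigs)),
               "  FORMAT DATATYPE=DNA MISSING=? GAP=-;", "  MATRIX"), con)
  writeLines(sprintf("    %s %s", rownames(sigs), rows), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
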