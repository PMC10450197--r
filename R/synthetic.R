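#' Random nucleotide sequence
#'
#' Uniform i.i.d. A/C/G/T; uses the current RNG state.  Uniform random
#' sequences model "unrelated" replicons: at k = 17 two of them share
#' k-mers with vanishing probability, so their sketch distance is ~1.
#'
#' @param n Length in bp.
#' @param alphabet Symbols to draw from (default ACGT).
#' @return Character scalar.
#' @export
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Plant random substitutions in a sequence
#'
#' Substitutes `n_sub` distinct random positions with a different base;
#' uses the current RNG state.
#'
#' @param seq Input sequence.
#' @param n_sub Number of substitutions.
#' @return Mutated sequence.
#' @export
mutate_seq <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a labeled reference replicon set with recorded truth
#'
#' Plasmid and chromosome sequences are distinct random-sequence families;
#' relatedness is planted explicitly by copying a family founder with
#' random substitutions (`divergence` per copy), so within-family sketch
#' distances are small and between-family distances are ~1.
#'
#' @param seed Integer seed; the output is a pure function of
#'   `(seed, parameters)`.
#' @param n_plasmids,n_chromosomes Family counts (either may be 0).
#' @param members_per_family Related members per family (1 = no planted
#'   relatives).
#' @param plasmid_len_range,chromosome_len_range Founder length ranges.
#' @param divergence Per-copy substitution fraction (default 0.02).
#' @return List with `seqs` (named character), `truth` (data.frame:
#'   `record_id`, `origin`, `family`, `member`), and `origins` (named
#'   vector).
#' @export
gen_reference_set <- function(seed, n_plasmids = 10, n_chromosomes = 10,
                              members_per_family = 1,
                              plasmid_len_range = c(5000, 20000),
                              chromosome_len_range = c(30000, 60000),
                              divergence = 0.02) {
  restore <- .seed_guard(seed)
  on.exit(restore())
  seqs <- character()
  rows <- list()
  emit <- function(origin, fam, len_range) {
    founder_len <- sample(seq(len_range[1], len_range[2]), 1)
    founder <- random_dna(founder_len)
    for (m in seq_len(members_per_family)) {
      id <- sprintf("%s%02d_m%d", substr(origin, 1, 1), fam, m)
      s <- if (m == 1) founder else
        mutate_seq(founder, round(divergence * founder_len))
      seqs[[id]] <<- s
      rows[[length(rows) + 1L]] <<- data.frame(
        record_id = id, origin = origin, family = sprintf("%s%02d", substr(origin, 1, 1), fam),
        member = m, stringsAsFactors = FALSE)
    }
  }
  for (f in seq_len(n_plasmids)) emit("plasmid", f, plasmid_len_range)
  for (f in seq_len(n_chromosomes)) emit("chromosome", f, chromosome_len_range)
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(), origin = character(),
               family = character(), member = integer(), stringsAsFactors = FALSE)
  list(seqs = seqs, truth = truth,
       origins = stats::setNames(truth$origin, truth$record_id))
}

#' Build a mimic benchmark: held-out query fragments versus a reference DB
#'
#' Per family, a `holdout` fraction of members (at least one, never all)
#' becomes query material and the rest the database side, so no query
#' fragment's parent appears in the DB while its relatives do.  Query
#' fragments are cut with [sample_random_fragments()] for an even length
#' distribution; labels are recorded.
#'
#' @param seed Integer seed.
#' @param refs Output of [gen_reference_set()] with
#'   `members_per_family >= 2`.
#' @param n_per_class Query fragments per class (default 5000 mirrors the
#'   benchmark design; scale down for unit-level work).
#' @param len_range Query fragment length range.
#' @param holdout Held-out member fraction (must be > 0).
#' @return List with `queries` (fragment data.frame incl. `origin` truth),
#'   `db_seqs`, `db_origins`, and `truth` (query labels).
#' @export
gen_mimic_benchmark <- function(seed, refs, n_per_class = 5000,
                                len_range = c(2000, 200000), holdout = 0.2) {
  if (holdout <= 0) stop("holdout fraction must be positive")
  tr <- refs$truth
  held <- character()
  for (fam in unique(tr$family)) {
    ids <- tr$record_id[tr$family == fam]
    if (length(ids) < 2L) {
      stop("family ", fam, " has a single member; cannot hold out")
    }
    n_hold <- max(1L, min(length(ids) - 1L, round(holdout * length(ids))))
    held <- c(held, ids[seq_len(n_hold)])
  }
  db_ids <- setdiff(tr$record_id, held)
  q <- list()
  for (org in c("plasmid", "chromosome")) {
    src <- intersect(held, tr$record_id[tr$origin == org])
    if (!length(src)) next
    frags <- sample_random_fragments(refs$seqs[src],
                                     stats::setNames(tr$origin, tr$record_id)[src],
                                     n = n_per_class, len_range = len_range,
                                     seed = seed + (org == "chromosome"))
    frags$fragment_id <- paste0(org, "_", frags$fragment_id)
    q[[org]] <- frags
  }
  queries <- do.call(rbind, q)
  rownames(queries) <- NULL
  list(queries = queries,
       db_seqs = refs$seqs[db_ids],
       db_origins = stats::setNames(tr$origin, tr$record_id)[db_ids],
       truth = stats::setNames(queries$origin, queries$fragment_id))
}

#' Score benchmark predictions against truth labels
#'
#' Precision = TP / (TP + FP); recall = TP / (number of true plasmid
#' fragments); both reported as one-decimal percentages alongside raw
#' counts.
#'
#' @param predicted_ids Fragment ids called PLS.
#' @param truth Named character vector: origin (`"plasmid"` /
#'   `"chromosome"`) per fragment id (all fragments, called or not).
#' @return List with `tp`, `fp`, `n_true_plasmid`, `precision_pct`,
#'   `recall_pct`.
#' @export
score_benchmark <- function(predicted_ids, truth) {
  if (!length(truth)) stop("empty truth set")
  tp <- sum(truth[predicted_ids] == "plasmid", na.rm = TRUE)
  fp <- length(predicted_ids) - tp
  n_true <- sum(truth == "plasmid")
  list(tp = tp, fp = fp, n_true_plasmid = n_true,
       precision_pct = fraction_summary(tp, tp + fp),
       recall_pct = fraction_summary(tp, n_true))
}

#' Score a benchmark from summary counts
#'
#' The counts form of [score_benchmark()], for published summary numbers:
#' `n_predicted` called PLSs of which `n_false_positive` are wrong, over
#' `n_true_plasmid` true plasmid fragments.
#'
#' @param n_predicted Total predicted PLSs.
#' @param n_false_positive False positives among them.
#' @param n_true_plasmid True plasmid fragments in the query set.
#' @return List with `precision_pct` and `recall_pct` (one-decimal
#'   percentages).
#' @export
score_benchmark_counts <- function(n_predicted, n_false_positive, n_true_plasmid) {
  tp <- n_predicted - n_false_positive
  list(tp = tp, fp = n_false_positive, n_true_plasmid = n_true_plasmid,
       precision_pct = fraction_summary(tp, n_predicted),
       recall_pct = fraction_summary(tp, n_true_plasmid))
}

#' Generate an assembly-graph fixture with known completeness
#'
#' A circular plasmid is fragmented into cycle nodes such that a known
#' prefix of nodes carries exactly `fraction_observed` of the circle; the
#' PLS is the concatenation of those anchor nodes.  Node abundances are
#' `coverage x multiplicity` with multiplicative uniform noise; dead-end
#' decoy nodes hang off the cycle; error-free mate pairs span every cycle
#' junction.
#'
#' @param seed Integer seed.
#' @param plasmid_len Circle length in bp (default 9000).
#' @param fraction_observed Fraction of the circle covered by the PLS, in
#'   (0, 1].
#' @param n_anchor_nodes,n_gap_nodes Cycle nodes inside/outside the PLS
#'   (gap nodes only exist when `fraction_observed < 1`).
#' @param copy_plan Optional integer multiplicities per cycle node.
#' @param coverage Base abundance (default 30).
#' @param noise Relative abundance noise half-width (default 0.1).
#' @param read_len Mate length (default 100).
#' @param n_decoys Dead-end decoy nodes (default 2).
#' @return List with `graph` (an `assembly_graph`), `pls` (named
#'   sequence), `anchors` (ordered anchor node ids), `read_pairs`, and
#'   `truth` (fraction, base abundance, multiplicities).
#' @export
gen_assembly_fixture <- function(seed, plasmid_len = 9000,
                                 fraction_observed = 1,
                                 n_anchor_nodes = 2, n_gap_nodes = 2,
                                 copy_plan = NULL, coverage = 30,
                                 noise = 0.1, read_len = 100, n_decoys = 2) {
  stopifnot(fraction_observed > 0, fraction_observed <= 1)
  restore <- .seed_guard(seed)
  on.exit(restore())
  circle <- random_dna(plasmid_len)
  anchor_len <- round(fraction_observed * plasmid_len)
  if (fraction_observed == 1) n_gap_nodes <- 0L
  cuts_a <- round(seq(0, anchor_len, length.out = n_anchor_nodes + 1L))
  cuts_g <- if (n_gap_nodes > 0)
    round(seq(anchor_len, plasmid_len, length.out = n_gap_nodes + 1L)) else anchor_len
  bounds <- unique(c(cuts_a, cuts_g))
  node_ids <- sprintf("n%02d", seq_len(length(bounds) - 1L))
  node_seqs <- vapply(seq_along(node_ids), function(i) {
    substr(circle, bounds[i] + 1L, bounds[i + 1L])
  }, "")
  mult <- if (is.null(copy_plan)) rep(1L, length(node_ids)) else copy_plan
  abundance <- coverage * mult * (1 + stats::runif(length(node_ids), -noise, noise))
  nodes <- data.frame(node_id = node_ids, seq = node_seqs,
                      abundance = abundance, stringsAsFactors = FALSE)
  m <- length(node_ids)
  edges <- data.frame(from = node_ids, from_orient = "+",
                      to = node_ids[c(seq_len(m)[-1], 1L)], to_orient = "+",
                      stringsAsFactors = FALSE)
  for (dn in seq_len(n_decoys)) {
    did <- sprintf("decoy%02d", dn)
    nodes <- rbind(nodes, data.frame(
      node_id = did, seq = random_dna(500),
      abundance = coverage * (1 + stats::runif(1, -noise, noise)),
      stringsAsFactors = FALSE))
    att <- sample(node_ids, 1)
    edges <- rbind(edges, data.frame(from = att, from_orient = "+",
                                     to = did, to_orient = "+",
                                     stringsAsFactors = FALSE))
  }
  graph <- assembly_graph(nodes, edges)
  anchors <- node_ids[seq_len(n_anchor_nodes)]
  pls <- stats::setNames(substr(circle, 1L, anchor_len), "pls_1")
  # junction-spanning mate pairs, each mate fully inside one cycle node
  pairs <- list()
  for (i in seq_len(m)) {
    a <- node_seqs[i]
    b <- node_seqs[if (i == m) 1L else i + 1L]
    for (r in 1:2) {
      off <- sample.int(50, 1)
      r1 <- substr(a, max(1L, nchar(a) - read_len - off + 1L),
                   max(read_len, nchar(a) - off))
      r2 <- substr(b, off, off + read_len - 1L)
      pairs[[length(pairs) + 1L]] <- data.frame(read1 = substr(r1, 1, read_len),
                                                read2 = r2,
                                                stringsAsFactors = FALSE)
    }
  }
  list(graph = graph, pls = pls, anchors = anchors,
       read_pairs = do.call(rbind, pairs),
       truth = list(fraction = anchor_len / plasmid_len,
                    base_abundance = coverage, multiplicities = mult,
                    cycle_nodes = node_ids, circle = circle))
}

#' Generate a seeded haplotype population with a known mutation tree
#'
#' The ancestor carries a unique rotation anchor (a 10-bp A run followed by
#' a C/G body) so every member's canonical rotation starts at the same
#' circular position, and mutations are biallelic C<->G flips at distinct
#' body positions (infinite-sites), so planted tree distances are exactly
#' additive.  Members are emitted at random rotations and strands with a
#' duplicated terminal repeat, as a circular assembly would present them.
#'
#' @param seed Integer seed.
#' @param ancestor_len Circle length in bp (default 600).
#' @param mutation_tree data.frame with `parent`, `child`, `n_mut`
#'   (every edge carries >= 1 mutation); node names are haplotype labels,
#'   the root is the (unique) parent that never appears as a child.
#' @param members_per_hap Members emitted per haplotype: a single count or
#'   a named vector (0 = haplotype unobserved).
#' @param rotate_and_flip Randomize rotation and strand (default TRUE).
#' @param dtr_len Duplicated terminus length (default 15).
#' @return List with `members` (named sequences), `truth` (tree, haplotype
#'   per member, haplotype core sequences).
#' @export
gen_haplotype_population <- function(seed, ancestor_len = 600, mutation_tree,
                                     members_per_hap = 3,
                                     rotate_and_flip = TRUE, dtr_len = 15) {
  stopifnot(all(mutation_tree$n_mut >= 1))
  restore <- .seed_guard(seed)
  on.exit(restore())
  anchor <- paste0(strrep("A", 10), "CC")
  body_len <- ancestor_len - nchar(anchor)
  body <- random_dna(body_len, alphabet = c("C", "G"))
  root_seq <- paste0(anchor, body)
  haps <- unique(c(mutation_tree$parent, mutation_tree$child))
  root <- setdiff(mutation_tree$parent, mutation_tree$child)
  if (length(root) != 1L) stop("mutation tree must have exactly one root")
  seqs <- stats::setNames(vector("character", length(haps)), haps)
  seqs[[root]] <- root_seq
  body_pos <- sample(seq(nchar(anchor) + 1L, ancestor_len),
                     sum(mutation_tree$n_mut))
  used <- 0L
  pending <- mutation_tree
  while (nrow(pending)) {
    ready <- which(pending$parent %in% names(seqs)[nzchar(seqs)])
    if (!length(ready)) stop("mutation tree is not connected to the root")
    i <- ready[1]
    ps <- strsplit(seqs[[pending$parent[i]]], "")[[1]]
    for (p in body_pos[used + seq_len(pending$n_mut[i])]) {
      ps[p] <- if (ps[p] == "C") "G" else "C"
    }
    used <- used + pending$n_mut[i]
    seqs[[pending$child[i]]] <- paste(ps, collapse = "")
    pending <- pending[-i, , drop = FALSE]
  }
  if (length(members_per_hap) == 1L && is.null(names(members_per_hap))) {
    members_per_hap <- stats::setNames(rep(members_per_hap, length(haps)), haps)
  }
  members <- character()
  hap_of <- character()
  for (h in haps) {
    nm <- members_per_hap[[h]]
    if (is.null(nm) || nm == 0) next
    for (mth in seq_len(nm)) {
      s <- seqs[[h]]
      if (rotate_and_flip) {
        r <- sample.int(nchar(s), 1)
        s <- paste0(substr(s, r, nchar(s)), substr(s, 1, r - 1L))
        if (stats::runif(1) < 0.5) s <- revcomp(s)
      }
      id <- sprintf("%s_m%d", h, mth)
      members[[id]] <- paste0(s, substr(s, 1, dtr_len))
      hap_of[[id]] <- h
    }
  }
  list(members = members,
       truth = list(tree = mutation_tree, hap_of_member = hap_of,
                    hap_seqs = seqs, root = root))
}
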