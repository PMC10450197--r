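#' Find the longest direct terminal repeat (DTR) of a sequence
#'
#' Reports the largest `L >= min_len` (up to half the sequence length) for
#' which the length-`L` prefix and suffix differ in at most `max_mismatch`
#' positions.  A DTR is the assembly signature of a circular replicon.
#'
#' @param seq Nucleotide sequence (character scalar).
#' @param min_len Minimum repeat length (default 10).
#' @param max_mismatch Maximum substitutions tolerated (default 1).
#' @return Object of class `dtr_result`: list with `found`, `length`,
#'   `n_mismatch`.
#' @export
find_dtr <- function(seq, min_len = 10, max_mismatch = 1) {
  stopifnot(is.character(seq), length(seq) == 1L)
  hit <- .dtr_scan_cpp(seq, as.integer(min_len), as.integer(max_mismatch))
  if (hit[1] < 0) {
    structure(list(found = FALSE, length = NA_integer_, n_mismatch = NA_integer_),
              class = "dtr_result")
  } else {
    structure(list(found = TRUE, length = hit[1], n_mismatch = hit[2]),
              class = "dtr_result")
  }
}

# Exact-match seed-free read placement adequate for error-free fixture
# reads: a read maps either as a full substring of the reference (coverage
# 1) or as an overhang at one reference end (partial coverage).  Both
# strands are tried; the best placement is returned as a list with
# `coverage`, `start`, `end` (1-based on the reference).
.map_read <- function(read, ref) {
  n <- nchar(read)
  nr <- nchar(ref)
  best <- list(coverage = 0, start = NA_integer_, end = NA_integer_)
  for (r in c(read, revcomp(read))) {
    pos <- regexpr(r, ref, fixed = TRUE)[1]
    if (pos > 0) {
      cand <- list(coverage = 1, start = pos, end = pos + n - 1L)
      if (cand$coverage > best$coverage) best <- cand
      next
    }
    # overhang off the left end: a suffix of the read matches a ref prefix
    L <- min(n - 1L, nr)
    while (L >= 1L && substr(r, n - L + 1L, n) != substr(ref, 1L, L)) L <- L - 1L
    if (L >= 1L && L / n > best$coverage) {
      best <- list(coverage = L / n, start = 1L, end = L)
    }
    # overhang off the right end: a prefix of the read matches a ref suffix
    L <- min(n - 1L, nr)
    while (L >= 1L && substr(r, 1L, L) != substr(ref, nr - L + 1L, nr)) L <- L - 1L
    if (L >= 1L && L / n > best$coverage) {
      best <- list(coverage = L / n, start = nr - L + 1L, end = nr)
    }
  }
  best
}

.interval_overlap <- function(a1, a2, b1, b2) {
  max(0L, min(a2, b2) - max(a1, b1) + 1L)
}

#' Confirm circularity of a DTR-bearing PLS with paired reads
#'
#' The trailing DTR copy is removed and mate pairs are placed on the
#' trimmed sequence.  A mate is a hit on an end if at least `min_cov` of
#' the read aligns and at least `min_anchor` bp fall inside the `end_window`
#' bp end region outside the DTR.  Circularity is confirmed iff some pair
#' has one mate hitting the left end and the other the right end.
#'
#' @param seq PLS sequence with a found DTR.
#' @param read_pairs data.frame with `read1`, `read2`.
#' @param dtr Optional `dtr_result` (computed if NULL; must be found).
#' @param end_window End-region width in bp (default 300).
#' @param min_cov Minimum aligned fraction of a read (default 0.90).
#' @param min_anchor Minimum bp landing in the end region (default 20).
#' @return `TRUE` if circularity is confirmed.
#' @export
confirm_circular_by_reads <- function(seq, read_pairs, dtr = NULL,
                                      end_window = 300, min_cov = 0.90,
                                      min_anchor = 20) {
  if (is.null(dtr)) dtr <- find_dtr(seq)
  if (!isTRUE(dtr$found)) stop("confirm_circular_by_reads requires a found DTR")
  core <- substr(seq, 1L, nchar(seq) - dtr$length)
  if (is.null(read_pairs) || !nrow(read_pairs)) {
    warning("no reads supplied; circularity not confirmed")
    return(FALSE)
  }
  len <- nchar(core)
  left <- c(dtr$length + 1L, min(end_window, len))   # leading DTR copy excluded
  right <- c(max(1L, len - end_window + 1L), len)
  hit_end <- function(m, win) {
    m$coverage >= min_cov && !is.na(m$start) &&
      .interval_overlap(m$start, m$end, win[1], win[2]) >= min_anchor
  }
  for (i in seq_len(nrow(read_pairs))) {
    m1 <- .map_read(read_pairs$read1[i], core)
    m2 <- .map_read(read_pairs$read2[i], core)
    if ((hit_end(m1, left) && hit_end(m2, right)) ||
        (hit_end(m2, left) && hit_end(m1, right))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Construct an assembly graph object
#'
#' Orientation-aware node/edge model of an assembler graph.  For every
#' stated edge the reverse-complement mirror (flip both orientations and
#' swap endpoints) is added automatically so the graph is consistent
#' regardless of which strand a record was emitted on.
#'
#' @param nodes data.frame with `node_id`, `seq`, `abundance` (non-negative
#'   coverage value).
#' @param edges data.frame with `from`, `from_orient`, `to`, `to_orient`
#'   (orientations `"+"`/`"-"`; an edge joins the end of `from` in its
#'   orientation to the start of `to` in its orientation).
#' @return Object of class `assembly_graph`.
#' @export
assembly_graph <- function(nodes, edges) {
  stopifnot(all(c("node_id", "seq", "abundance") %in% names(nodes)))
  if (any(nodes$abundance < 0)) stop("node abundances must be non-negative")
  if (nrow(edges)) {
    stopifnot(all(edges$from %in% nodes$node_id), all(edges$to %in% nodes$node_id))
    flip <- function(o) ifelse(o == "+", "-", "+")
    mirror <- data.frame(from = edges$to, from_orient = flip(edges$to_orient),
                         to = edges$from, to_orient = flip(edges$from_orient),
                         stringsAsFactors = FALSE)
    edges <- unique(rbind(edges[, c("from", "from_orient", "to", "to_orient")], mirror))
  } else {
    edges <- data.frame(from = character(), from_orient = character(),
                        to = character(), to_orient = character(),
                        stringsAsFactors = FALSE)
  }
  nodes$length <- nchar(nodes$seq)
  structure(list(nodes = nodes, edges = edges), class = "assembly_graph")
}

# SPAdes-style FASTG record name for a node.
.fastg_name <- function(node_id, len, cov) {
  sprintf("EDGE_%s_length_%d_cov_%s", node_id, len, format(cov, trim = TRUE))
}

#' Parse an assembly graph from a FASTG file (SPAdes dialect)
#'
#' Headers look like `>EDGE_1_length_100_cov_20.5:EDGE_2_...,EDGE_3_...';`
#' where a trailing apostrophe marks the reverse-complement orientation of
#' a node; the adjacency list gives the successors of the record's
#' orientation.  Node abundances are the `cov` values.
#'
#' @param path FASTG file path.
#' @return An `assembly_graph`.
#' @export
parse_fastg <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx)) stop("no records in FASTG file: ", path)
  bounds <- c(hdr_idx, length(lines) + 1L)
  parse_name <- function(x) {
    m <- regmatches(x, regexec("EDGE_([^_]+)_length_([0-9]+)_cov_([0-9.eE+-]+)('?)", x))[[1]]
    if (!length(m)) stop("unparseable FASTG node name: ", x)
    list(node_id = m[2], length = as.integer(m[3]), cov = as.numeric(m[4]),
         orient = if (m[5] == "'") "-" else "+")
  }
  node_rows <- list()
  edge_rows <- list()
  for (i in seq_along(hdr_idx)) {
    hdr <- sub("^>", "", sub(";\\s*$", "", lines[hdr_idx[i]]))
    parts <- strsplit(hdr, ":", fixed = TRUE)[[1]]
    self <- parse_name(parts[1])
    seq <- paste(lines[seq(hdr_idx[i] + 1L, bounds[i + 1L] - 1L)][
      !grepl("^>", lines[seq(hdr_idx[i] + 1L, bounds[i + 1L] - 1L)])], collapse = "")
    if (self$orient == "+") {
      node_rows[[self$node_id]] <- data.frame(
        node_id = self$node_id, seq = toupper(seq), abundance = self$cov,
        stringsAsFactors = FALSE)
    } else if (is.null(node_rows[[self$node_id]])) {
      node_rows[[self$node_id]] <- data.frame(
        node_id = self$node_id, seq = revcomp(toupper(seq)), abundance = self$cov,
        stringsAsFactors = FALSE)
    }
    if (length(parts) > 1L) {
      for (nb in strsplit(parts[2], ",", fixed = TRUE)[[1]]) {
        tgt <- parse_name(nb)
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          from = self$node_id, from_orient = self$orient,
          to = tgt$node_id, to_orient = tgt$orient, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edge_rows)) unique(do.call(rbind, edge_rows)) else
    data.frame(from = character(), from_orient = character(),
               to = character(), to_orient = character(), stringsAsFactors = FALSE)
  assembly_graph(do.call(rbind, node_rows), edges)
}

#' Write an assembly graph as FASTG (SPAdes dialect)
#'
#' @param graph An `assembly_graph`.
#' @param path Output path.
#' @export
write_fastg <- function(graph, path) {
  stopifnot(inherits(graph, "assembly_graph"))
  nd <- graph$nodes
  name_of <- stats::setNames(.fastg_name(nd$node_id, nd$length, nd$abundance),
                             nd$node_id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(nd))) {
    for (o in c("+", "-")) {
      self <- paste0(name_of[nd$node_id[i]], if (o == "-") "'" else "")
      succ <- graph$edges[graph$edges$from == nd$node_id[i] &
                            graph$edges$from_orient == o, , drop = FALSE]
      hdr <- if (nrow(succ)) {
        paste0(self, ":", paste0(name_of[succ$to],
                                 ifelse(succ$to_orient == "-", "'", ""),
                                 collapse = ","), ";")
      } else {
        paste0(self, ";")
      }
      writeLines(paste0(">", hdr), con)
      writeLines(if (o == "+") nd$seq[i] else revcomp(nd$seq[i]), con)
    }
  }
  invisible(path)
}

# Oriented igraph over an assembly graph: vertices "<node>:<orient>", edge
# weight = length of the target node, so a closed walk's weight equals the
# bp of all nodes entered.
.oriented_igraph <- function(graph) {
  vs <- c(paste0(graph$nodes$node_id, ":+"), paste0(graph$nodes$node_id, ":-"))
  lens <- stats::setNames(graph$nodes$length, graph$nodes$node_id)
  if (nrow(graph$edges)) {
    ed <- data.frame(from = paste0(graph$edges$from, ":", graph$edges$from_orient),
                     to = paste0(graph$edges$to, ":", graph$edges$to_orient),
                     stringsAsFactors = FALSE)
    ig <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                        vertices = data.frame(name = vs))
    tgt <- sub(":[+-]$", "", igraph::ends(ig, igraph::E(ig))[, 2])
    igraph::E(ig)$weight <- unname(lens[tgt])
  } else {
    ig <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(vs)
  }
  ig
}

#' Shortest circular path through anchor nodes of an assembly graph
#'
#' Among cycles traversing the anchors in order, returns one minimizing
#' total bp (the conservative gap estimate for a length-ratio
#' completeness), found by chaining weighted shortest-path legs between
#' consecutive anchors (and from the last anchor back to the first).
#' Anchors given as bare node ids are tried on both strands and the
#' shorter cycle is kept.
#'
#' @param graph An `assembly_graph`.
#' @param anchors Character vector of node ids, or data.frame with `node`,
#'   `orient` giving the oriented anchor steps in order.
#' @return Object of class `circular_path` (list with `steps` data.frame
#'   `node`/`orient`, `total_len`, `anchors`), or `NULL` when no cycle
#'   exists.
#' @export
shortest_circular_path <- function(graph, anchors) {
  stopifnot(inherits(graph, "assembly_graph"))
  if (is.data.frame(anchors)) {
    cand <- list(anchors)
  } else {
    fwd <- data.frame(node = anchors, orient = "+", stringsAsFactors = FALSE)
    rev_ <- data.frame(node = rev(anchors), orient = "-", stringsAsFactors = FALSE)
    cand <- list(fwd, rev_)
  }
  if (!all(cand[[1]]$node %in% graph$nodes$node_id)) {
    stop("anchor node(s) absent from graph: ",
         paste(setdiff(cand[[1]]$node, graph$nodes$node_id), collapse = ", "))
  }
  ig <- .oriented_igraph(graph)
  best <- NULL
  for (an in cand) {
    p <- .cycle_through(ig, paste0(an$node, ":", an$orient))
    if (!is.null(p) && (is.null(best) || p$total < best$total)) best <- p
  }
  if (is.null(best)) return(NULL)
  steps <- data.frame(node = sub(":[+-]$", "", best$steps),
                      orient = sub("^.*:", "", best$steps),
                      stringsAsFactors = FALSE)
  structure(list(steps = steps, total_len = best$total, anchors = cand[[1]]),
            class = "circular_path")
}

# Minimum-weight closed walk visiting vertex names `vs` in order.
.cycle_through <- function(ig, vs) {
  w <- igraph::E(ig)$weight
  leg <- function(u, v) {
    sp <- suppressWarnings(igraph::shortest_paths(ig, from = u, to = v,
                                                  weights = w, mode = "out",
                                                  output = "both"))
    if (!length(sp$vpath[[1]])) return(NULL)
    list(vpath = names(sp$vpath[[1]]), wt = sum(w[sp$epath[[1]]]))
  }
  m <- length(vs)
  if (m == 1L) {
    # shortest strictly positive closed walk u -> u
    u <- vs[1]
    eids <- igraph::incident(ig, u, mode = "out")
    if (!length(eids)) return(NULL)
    best <- NULL
    for (e in eids) {
      s <- igraph::ends(ig, e)[2]
      if (s == u) {
        cand <- list(steps = u, total = w[which(igraph::E(ig) == e)])
      } else {
        lg <- leg(s, u)
        if (is.null(lg)) next
        cand <- list(steps = c(u, lg$vpath[-length(lg$vpath)]),
                     total = w[which(igraph::E(ig) == e)] + lg$wt)
      }
      if (is.null(best) || cand$total < best$total) best <- cand
    }
    return(best)
  }
  steps <- character()
  total <- 0
  for (i in seq_len(m)) {
    u <- vs[i]
    v <- vs[if (i == m) 1L else i + 1L]
    lg <- leg(u, v)
    if (is.null(lg) || (u != v && length(lg$vpath) == 1L)) return(NULL)
    steps <- c(steps, lg$vpath[-length(lg$vpath)])
    total <- total + lg$wt
  }
  list(steps = steps, total = total)
}

#' Copy number of a node on a circular path
#'
#' Uses the abundance balance `C = (A - min(Ap, Af)) / Abase`, with `A` the
#' node's abundance, `Ap`/`Af` the summed abundances of adjoining off-path
#' nodes on its two ends (adjoining nodes already in the path are not
#' counted), and `Abase` the abundance of the PLS's own node.  The node is
#' flagged multi-copy when `C > 1.8`, except nodes traversed in two
#' opposite orientations, which need `C > 2.8`.
#'
#' @param graph An `assembly_graph`.
#' @param path A `circular_path`.
#' @param step Index into `path$steps`.
#' @param base_abundance `Abase`; must be positive.
#' @return List with `C` and `multi_copy`.
#' @export
node_copy_number <- function(graph, path, step, base_abundance) {
  if (base_abundance <= 0) stop("base abundance must be positive")
  st <- path$steps[step, ]
  ab <- stats::setNames(graph$nodes$abundance, graph$nodes$node_id)
  on_path <- unique(path$steps$node)
  inc <- graph$edges[graph$edges$to == st$node & graph$edges$to_orient == st$orient, ]
  out <- graph$edges[graph$edges$from == st$node & graph$edges$from_orient == st$orient, ]
  Ap <- sum(ab[setdiff(unique(inc$from), on_path)])
  Af <- sum(ab[setdiff(unique(out$to), on_path)])
  C <- (ab[[st$node]] - min(Ap, Af)) / base_abundance
  opposite <- length(unique(path$steps$orient[path$steps$node == st$node])) > 1L
  list(C = unname(C), multi_copy = if (opposite) C > 2.8 else C > 1.8)
}

#' Copy numbers for every step of a circular path
#'
#' @inheritParams node_copy_number
#' @return data.frame with `node`, `orient`, `C`, `multi_copy`.
#' @export
path_copy_numbers <- function(graph, path, base_abundance) {
  rows <- lapply(seq_len(nrow(path$steps)), function(i) {
    cn <- node_copy_number(graph, path, i, base_abundance)
    data.frame(node = path$steps$node[i], orient = path$steps$orient[i],
               C = cn$C, multi_copy = cn$multi_copy, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Validate a circular path with mate pairs spanning every junction
#'
#' `TRUE` iff every consecutive node junction of the path (including the
#' closing junction) is supported by at least one pair whose mates both
#' place at `>= min_cov` coverage, one on each node of the junction.
#' Because every traversal of a multi-copy node contributes its own
#' junctions, such nodes require support to their specific upstream and
#' downstream neighbors.
#'
#' @param graph An `assembly_graph`.
#' @param path A `circular_path`.
#' @param read_pairs data.frame with `read1`, `read2`.
#' @param min_cov Minimum aligned read fraction (default 0.90).
#' @return Logical.
#' @export
validate_path_with_pairs <- function(graph, path, read_pairs, min_cov = 0.90) {
  seqs <- stats::setNames(graph$nodes$seq, graph$nodes$node_id)
  m <- nrow(path$steps)
  maps_to <- function(read, node) .map_read(read, seqs[[node]])$coverage >= min_cov
  for (i in seq_len(m)) {
    a <- path$steps$node[i]
    b <- path$steps$node[if (i == m) 1L else i + 1L]
    ok <- FALSE
    for (r in seq_len(nrow(read_pairs))) {
      if ((maps_to(read_pairs$read1[r], a) && maps_to(read_pairs$read2[r], b)) ||
          (maps_to(read_pairs$read2[r], a) && maps_to(read_pairs$read1[r], b))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Estimate PLS completeness
#'
#' DTR-confirmed circular PLSs are ~100\% complete (`fraction = 1`, method
#' `dtr_circular`).  Otherwise the completeness is the length ratio
#' `L_PLS / (L_PLS + L_G)`.  Under the default `gap` interpretation `L_G`
#' is the summed length of path nodes not covered by the PLS (its anchor
#' nodes), so a PLS covering the whole cycle scores 1; the literal
#' `path_total` reading (`L_G` = all path nodes) is kept behind a switch.
#' A PLS with completeness above `compls_threshold` is a comPLS.
#'
#' @param pls_id Identifier.
#' @param pls_len PLS length in bp.
#' @param path A `circular_path` or NULL (then method is `none`).
#' @param anchor_nodes Node ids of the path covered by the PLS.
#' @param graph An `assembly_graph` (needed when `path` is given).
#' @param dtr_confirmed `TRUE` for the DTR + read-pair route.
#' @param mode `"gap"` (default) or `"path_total"`.
#' @param compls_threshold comPLS threshold (default 0.6, strict).
#' @return data.frame with `pls_id`, `fraction`, `method`, `is_compls`.
#' @export
estimate_completeness <- function(pls_id, pls_len, path = NULL,
                                  anchor_nodes = character(), graph = NULL,
                                  dtr_confirmed = FALSE,
                                  mode = c("gap", "path_total"),
                                  compls_threshold = 0.6) {
  mode <- match.arg(mode)
  if (dtr_confirmed) {
    return(data.frame(pls_id = pls_id, fraction = 1, method = "dtr_circular",
                      is_compls = TRUE, stringsAsFactors = FALSE))
  }
  if (is.null(path)) {
    return(data.frame(pls_id = pls_id, fraction = NA_real_, method = "none",
                      is_compls = FALSE, stringsAsFactors = FALSE))
  }
  stopifnot(inherits(path, "circular_path"), inherits(graph, "assembly_graph"))
  lens <- stats::setNames(graph$nodes$length, graph$nodes$node_id)
  nodes <- unique(path$steps$node)
  lg_nodes <- if (mode == "gap") setdiff(nodes, anchor_nodes) else nodes
  lg <- sum(lens[lg_nodes])
  fraction <- pls_len / (pls_len + lg)
  data.frame(pls_id = pls_id, fraction = fraction, method = "graph_path",
             is_compls = fraction > compls_threshold, stringsAsFactors = FALSE)
}
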