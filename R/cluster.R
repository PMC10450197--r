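#' Flat complete-linkage clusters of a distance matrix
#'
#' Cuts the complete-linkage dendrogram at `cutoff`, which guarantees that
#' every output cluster's maximum pairwise distance is at most `cutoff`
#' (the PLC definition at 0.01, roughly 99\% ANI).
#'
#' @param dm Symmetric distance matrix with matching dimnames, entries in
#'   `[0, 1]`, zero diagonal.
#' @param cutoff Linkage cutoff (default 0.01).
#' @return Named integer vector mapping element id to cluster id.
#' @export
complete_linkage_clusters <- function(dm, cutoff = 0.01) {
  validate_distance_matrix(dm)
  if (nrow(dm) == 1L) return(stats::setNames(1L, rownames(dm)))
  hc <- stats::hclust(stats::as.dist(dm), method = "complete")
  stats::cutree(hc, h = cutoff)
}

#' Markov clustering (MCL) of a graph adjacency matrix
#'
#' Alternates expansion (matrix squaring) and inflation (element-wise power
#' with column renormalization), pruning tiny entries, until the flow
#' matrix changes by less than `tol`; clusters are the connected components
#' of the converged flow.  Self-loops are added (standard MCL practice) so
#' isolated nodes form their own clusters.
#'
#' @param adj Square (weighted) adjacency matrix with dimnames; treated as
#'   undirected.
#' @param inflation Inflation exponent (default 2).
#' @param max_iter Iteration cap (default 100); non-convergence returns the
#'   current partition with a warning.
#' @param tol Convergence tolerance on the max absolute change.
#' @param self_loops Add unit self-loops before normalizing (default TRUE).
#' @param prune Entries below this value are zeroed each iteration.
#' @return Named integer vector mapping node id to cluster id.
#' @export
mcl_cluster <- function(adj, inflation = 2, max_iter = 100, tol = 1e-6,
                        self_loops = TRUE, prune = 1e-8) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) stop("adjacency must be square")
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1L) return(stats::setNames(1L, ids))
  M <- abs(unname(adj))
  if (self_loops) diag(M) <- pmax(diag(M), 1)
  cs <- colSums(M); cs[cs == 0] <- 1
  M <- sweep(M, 2, cs, "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    E <- M %*% M
    E <- E^inflation
    E[E < prune] <- 0
    cs <- colSums(E); cs[cs == 0] <- 1
    E <- sweep(E, 2, cs, "/")
    delta <- max(abs(E - M))
    M <- E
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge in ", max_iter, " iterations")
  g <- igraph::graph_from_adjacency_matrix((M + t(M)) > prune,
                                           mode = "undirected", diag = FALSE)
  memb <- igraph::components(g)$membership
  stats::setNames(as.integer(memb), ids)
}

#' Group PLS records into candidate PLCs and summarize them
#'
#' Clusters the member distance matrix by complete linkage at `cutoff` and
#' picks as representative the longest member of each cluster (ties broken
#' by lexicographic id).
#'
#' @param dm Distance matrix over PLS contig ids.
#' @param lengths Named vector of member lengths.
#' @param cutoff Linkage cutoff (default 0.01).
#' @return data.frame with `plc_id`, `contig_id`, `is_representative`.
#' @export
build_plcs <- function(dm, lengths, cutoff = 0.01) {
  memb <- complete_linkage_clusters(dm, cutoff = cutoff)
  out <- data.frame(plc_id = sprintf("PLC_%04d", unname(memb)),
                    contig_id = names(memb), stringsAsFactors = FALSE)
  out$length <- unname(lengths[out$contig_id])
  out$is_representative <- FALSE
  for (p in unique(out$plc_id)) {
    idx <- which(out$plc_id == p)
    best <- idx[order(-out$length[idx], out$contig_id[idx])][1]
    out$is_representative[best] <- TRUE
  }
  out[order(out$plc_id, out$contig_id), ]
}

#' Retain high-confidence PLCs and set their flags
#'
#' A candidate PLC survives iff at least one member is ~100\% complete
#' (completeness method `dtr_circular` or fraction at least
#' `complete_frac`) or at least one member encodes plasmid backbone genes.
#' Mobility labels are ingested, not computed: a PLC is conjugative if any
#' member is conjugative, and mobilizable if any member is mobilizable and
#' no member is conjugative.
#'
#' @param plc_table Membership table from [build_plcs()].
#' @param backbone Named character vector: comma-separated backbone
#'   categories per contig (as in `pls_result$records$backbone_genes`).
#' @param completeness Optional data.frame with `pls_id`, `fraction`,
#'   `method` (see [estimate_completeness()]).
#' @param mobility Optional data.frame with `contig_id`, `conjugative`,
#'   `mobilizable` (logicals) from external annotation.
#' @param complete_frac Fraction treated as ~100\% complete (default 0.99).
#' @return Per-PLC data.frame with flags and `retained`.
#' @export
retain_high_confidence_plcs <- function(plc_table, backbone,
                                        completeness = NULL, mobility = NULL,
                                        complete_frac = 0.99) {
  plcs <- unique(plc_table$plc_id)
  rows <- lapply(plcs, function(p) {
    members <- plc_table$contig_id[plc_table$plc_id == p]
    rep_id <- plc_table$contig_id[plc_table$plc_id == p & plc_table$is_representative][1]
    has_backbone <- any(nzchar(backbone[members]), na.rm = TRUE)
    has_complete <- FALSE
    if (!is.null(completeness)) {
      cm <- completeness[completeness$pls_id %in% members, , drop = FALSE]
      has_complete <- any(cm$method == "dtr_circular" |
                            (!is.na(cm$fraction) & cm$fraction >= complete_frac))
    }
    conj <- mobi <- FALSE
    if (!is.null(mobility)) {
      mm <- mobility[mobility$contig_id %in% members, , drop = FALSE]
      conj <- any(mm$conjugative)
      mobi <- any(mm$mobilizable) && !conj
    }
    data.frame(plc_id = p, n_members = length(members), representative = rep_id,
               has_complete_member = has_complete, has_backbone = has_backbone,
               conjugative = conj, mobilizable = mobi,
               retained = has_complete || has_backbone,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign network typing groups (NTGs) on the similarity network
#'
#' For each comPLC representative the up-to-`k_nearest` reference plasmids
#' at distance below `cutoff` are selected (ties at the last rank broken by
#' smaller distance, then lexicographic id); pairwise distances over the
#' selected references plus all comPLCs are then recomputed, the unweighted
#' graph with edges at distance below `cutoff` is built, and Markov
#' clustering partitions it into NTGs.  A comPLC with no neighbor below
#' `cutoff` is excluded as a singleton.
#'
#' @param complc_seqs Named character vector of comPLC representative
#'   sequences.
#' @param reference_seqs Named character vector of reference plasmid
#'   sequences (may be empty).
#' @param cutoff Edge threshold (default 0.15).
#' @param k_nearest References retained per comPLC (default 3).
#' @param inflation MCL inflation (default 2).
#' @param k,s Sketch parameters.
#' @return List with `assignments` (data.frame: `element_id`, `role`,
#'   `ntg_id`, `is_singleton_excluded`) and `edges` (data.frame `from`,
#'   `to`, `distance`).
#' @export
assign_network_types <- function(complc_seqs, reference_seqs = character(),
                                 cutoff = 0.15, k_nearest = 3, inflation = 2,
                                 k = 17, s = 3000) {
  csk <- build_sketches(complc_seqs, k = k, s = s)
  chosen_refs <- character()
  if (length(reference_seqs)) {
    rsk <- build_sketches(reference_seqs, k = k, s = s)
    for (id in names(csk)) {
      d <- distances_to_set(csk[[id]], rsk)
      d <- d[d < cutoff]
      if (length(d)) {
        ord <- order(d, names(d))
        chosen_refs <- union(chosen_refs, names(d)[ord][seq_len(min(k_nearest, length(d)))])
      }
    }
  }
  all_seqs <- c(complc_seqs, reference_seqs[chosen_refs])
  dm <- pairwise_distance_matrix(all_seqs, k = k, s = s)
  adj <- (dm < cutoff) * 1
  diag(adj) <- 0
  deg <- rowSums(adj)
  role <- c(rep("complc", length(complc_seqs)), rep("reference", length(chosen_refs)))
  names(role) <- rownames(dm)
  excluded <- names(deg)[deg == 0]
  keep <- setdiff(rownames(dm), excluded)
  ntg <- rep(NA_integer_, nrow(dm))
  names(ntg) <- rownames(dm)
  if (length(keep) == 1L) {
    ntg[keep] <- 1L
  } else if (length(keep) > 1L) {
    ntg[keep] <- mcl_cluster(adj[keep, keep, drop = FALSE], inflation = inflation)
  }
  ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(from = rownames(adj)[ut[, 1]], to = colnames(adj)[ut[, 2]],
                      distance = dm[ut], stringsAsFactors = FALSE)
  assignments <- data.frame(
    element_id = rownames(dm), role = unname(role),
    ntg_id = ifelse(is.na(ntg), NA_character_, sprintf("NTG_%02d", ntg)),
    is_singleton_excluded = rownames(dm) %in% excluded,
    stringsAsFactors = FALSE)
  list(assignments = assignments, edges = edges)
}

#' Export a typing network for external viewers
#'
#' Writes an edge-list TSV and a GraphML file.
#'
#' @param edges data.frame with `from`, `to` (and optional attributes).
#' @param path_prefix Files `<prefix>.edges.tsv` and `<prefix>.graphml` are
#'   written.
#' @export
export_network <- function(edges, path_prefix) {
  write_tsv(edges, paste0(path_prefix, ".edges.tsv"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::write_graph(g, paste0(path_prefix, ".graphml"), format = "graphml")
  invisible(path_prefix)
}
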