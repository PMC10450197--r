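# Tokenize a product description into maximal lower-case alphanumeric tokens.
.product_tokens <- function(products) {
  toks <- regmatches(tolower(products), gregexpr("[a-z0-9]+", tolower(products)))
  unique(unlist(toks))
}

# Centralized keyword rule for phage and backbone screens.
#
# - whole:  token equals the keyword;
# - symbol: short gene symbols (rep, rop, mob, tra, trb, mbp) additionally
#           match as prefixes of tokens of length <= 5 (repA, traG, mobC);
# - prefix: stems (conj, primase, relaxase, resolvase, partition) match as
#           prefixes of any token (conjugal, conjugative, primases).
.match_keyword <- function(tokens, keyword,
                           mode = c("whole", "symbol", "prefix")) {
  mode <- match.arg(mode)
  if (any(tokens == keyword)) return(TRUE)
  if (mode == "symbol") {
    short <- tokens[nchar(tokens) <= 5]
    return(any(startsWith(short, keyword)))
  }
  if (mode == "prefix") return(any(startsWith(tokens, keyword)))
  FALSE
}

.PHAGE_KEYWORDS <- c("terminase", "holin", "head", "tail", "portal", "capsid")

.BACKBONE_KEYWORDS <- data.frame(
  keyword = c("rep", "rop", "primase", "mob", "mbp", "relaxase", "conj",
              "tra", "trb", "resolvase", "partition"),
  mode = c("symbol", "symbol", "prefix", "symbol", "symbol", "prefix",
           "prefix", "symbol", "symbol", "prefix", "prefix"),
  stringsAsFactors = FALSE)

#' Vote a contig plasmid- or chromosome-like against the fragment database
#'
#' Counts reference fragments of each origin at sketch distance below
#' `cutoff`.  The contig is `plasmid_like` iff it hits strictly more plasmid
#' than chromosome fragments, `chromosome_like` iff the reverse (or only
#' chromosome hits), `undetermined` with zero hits, and `ambiguous` with
#' equal non-zero counts (excluded from candidacy and from the marker
#' stage, since it did align to something).
#'
#' @param contig_sketch `kmer_sketch` of the contig.
#' @param db A `fragment_db`.
#' @param cutoff Distance threshold (default 0.15).
#' @return List with `category`, `n_plasmid_hits`, `n_chromosome_hits`.
#' @export
classify_by_reference <- function(contig_sketch, db, cutoff = 0.15) {
  stopifnot(inherits(db, "fragment_db"))
  if (!length(db$sketches)) stop("fragment database is empty")
  d <- distances_to_set(contig_sketch, db$sketches)
  origin <- db$fragments$origin[match(names(d), db$fragments$fragment_id)]
  np <- sum(d < cutoff & origin == "plasmid")
  nc <- sum(d < cutoff & origin == "chromosome")
  category <- if (np == 0 && nc == 0) "undetermined"
    else if (np > nc) "plasmid_like"
    else if (nc > np) "chromosome_like"
    else "ambiguous"
  list(category = category, n_plasmid_hits = np, n_chromosome_hits = nc)
}

#' Marker rule for contigs without reference hits
#'
#' `TRUE` iff the contig encodes at least one plasmid-like gene marker (PGM)
#' and no chromosome-like gene marker (CGM) at `evalue <= evalue_max`.
#'
#' @param contig_annotations Annotation rows for one contig.
#' @param pgms,cgms Marker gene-id sets.
#' @param evalue_max Significance threshold (default 0.001).
#' @export
classify_by_markers <- function(contig_annotations, pgms, cgms,
                                evalue_max = 0.001) {
  g <- contig_annotations$gene_id[contig_annotations$evalue <= evalue_max]
  any(g %in% pgms) && !any(g %in% cgms)
}

#' Phage screen: should a contig be dropped as phage-like?
#'
#' Drops the contig iff any product description contains one of the phage
#' keywords (terminase, holin, head, tail, portal, capsid) as a whole
#' case-insensitive word (maximal alphanumeric token).  This also removes
#' plasmid-phage elements.
#'
#' @param contig_annotations Annotation rows for one contig (needs
#'   `product`).
#' @return `TRUE` if the contig should be dropped.
#' @export
phage_screen <- function(contig_annotations) {
  if (!nrow(contig_annotations)) return(FALSE)
  toks <- .product_tokens(contig_annotations$product)
  any(vapply(.PHAGE_KEYWORDS, function(kw) .match_keyword(toks, kw, "whole"),
             logical(1)))
}

#' Detect plasmid backbone gene categories on a contig
#'
#' Scans product descriptions for the eleven backbone keyword categories
#' (replication, mobilization, conjugation, segregation, stabilization:
#' rep, rop, primase, mob, mbp, relaxase, conj, tra, trb, resolvase,
#' partition) at `evalue <= evalue_max`.  Matching is case-insensitive on
#' maximal alphanumeric tokens; short gene symbols (rep, rop, mob, tra,
#' trb, mbp) also match as prefixes of tokens of length <= 5 (RepA, TraG,
#' MobC), and word stems (conj, primase, relaxase, resolvase, partition)
#' match as token prefixes (conjugal, conjugative).
#'
#' @param contig_annotations Annotation rows for one contig.
#' @param evalue_max Significance threshold (default 1e-10).
#' @return Character vector of matched keyword categories (possibly empty).
#' @export
detect_backbone_genes <- function(contig_annotations, evalue_max = 1e-10) {
  ann <- contig_annotations[contig_annotations$evalue <= evalue_max, , drop = FALSE]
  if (!nrow(ann)) return(character())
  toks <- .product_tokens(ann$product)
  hit <- vapply(seq_len(nrow(.BACKBONE_KEYWORDS)), function(i) {
    .match_keyword(toks, .BACKBONE_KEYWORDS$keyword[i], .BACKBONE_KEYWORDS$mode[i])
  }, logical(1))
  .BACKBONE_KEYWORDS$keyword[hit]
}

#' Two-stage PLS identification with phage screening
#'
#' Stage order: reference vote, then the marker rule on `undetermined`
#' contigs, then the phage screen on the union of candidates.  Contigs
#' shorter than `min_len` are excluded up front.  Backbone gene categories
#' are recorded for every retained record.
#'
#' @param contigs data.frame with `contig_id`, `isolate_id`, `seq`.
#' @param db A `fragment_db`.
#' @param pgms,cgms Marker sets (character vectors; may be empty).
#' @param annotations Annotation data.frame (`element_id`, `gene_id`,
#'   `product`, `evalue`); contigs without rows simply have no gene
#'   evidence.
#' @param cutoff Reference-vote distance threshold (default 0.15).
#' @param evalue_max Marker-stage e-value threshold (default 0.001).
#' @param backbone_evalue_max Backbone-detection e-value threshold
#'   (default 1e-10).
#' @param min_len Contig length floor (default 2000).
#' @param k,s Sketch parameters for the contig sketches.
#' @return List of class `pls_result`: `records` (retained PLSRecords:
#'   `contig_id`, `isolate_id`, `evidence` in
#'   `{candidate_I, candidate_II}`, hit counts, `pgms_found`,
#'   `backbone_genes`, `phage_flag = FALSE`) and `log` (per-contig decision
#'   table over all input contigs).
#' @export
identify_pls <- function(contigs, db, pgms = character(), cgms = character(),
                         annotations = NULL, cutoff = 0.15,
                         evalue_max = 0.001, backbone_evalue_max = 1e-10,
                         min_len = 2000, k = 17, s = 1000) {
  if (is.null(annotations)) {
    annotations <- data.frame(element_id = character(), gene_id = character(),
                              product = character(), evalue = numeric(),
                              stringsAsFactors = FALSE)
  }
  empty_log <- data.frame(
    contig_id = character(), isolate_id = character(), length = integer(),
    stage1 = character(), n_plasmid_hits = integer(),
    n_chromosome_hits = integer(), marker_pls = logical(),
    evidence = character(), phage_flag = logical(),
    pgms_found = character(), backbone_genes = character(),
    decision = character(), stringsAsFactors = FALSE)
  if (!nrow(contigs)) {
    return(structure(list(records = empty_log, log = empty_log),
                     class = "pls_result"))
  }
  logs <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]
    len <- nchar(contigs$seq[i])
    ann_i <- annotations[annotations$element_id == cid, , drop = FALSE]
    row <- list(contig_id = cid, isolate_id = contigs$isolate_id[i],
                length = len, stage1 = NA_character_,
                n_plasmid_hits = NA_integer_, n_chromosome_hits = NA_integer_,
                marker_pls = NA, evidence = NA_character_, phage_flag = NA,
                pgms_found = "", backbone_genes = "", decision = "")
    if (len < min_len) {
      row$decision <- "rejected: below 2 kb floor"
      logs[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
      next
    }
    sk <- build_sketch(contigs$seq[i], k = k, s = s, id = cid)
    ref <- classify_by_reference(sk, db, cutoff = cutoff)
    row$stage1 <- ref$category
    row$n_plasmid_hits <- ref$n_plasmid_hits
    row$n_chromosome_hits <- ref$n_chromosome_hits
    if (ref$category == "plasmid_like") {
      row$evidence <- "candidate_I"
    } else if (ref$category == "undetermined") {
      row$marker_pls <- classify_by_markers(ann_i, pgms, cgms, evalue_max)
      if (isTRUE(row$marker_pls)) {
        row$evidence <- "candidate_II"
        hits <- unique(ann_i$gene_id[ann_i$evalue <= evalue_max & ann_i$gene_id %in% pgms])
        row$pgms_found <- paste(sort(hits), collapse = ",")
      }
    }
    if (is.na(row$evidence)) {
      row$decision <- paste0("not a candidate (", ref$category, ")")
      logs[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
      next
    }
    row$phage_flag <- phage_screen(ann_i)
    row$backbone_genes <- paste(detect_backbone_genes(ann_i, backbone_evalue_max),
                                collapse = ",")
    row$decision <- if (row$phage_flag) "dropped: phage-like keyword"
                    else paste0("retained as ", row$evidence)
    logs[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  log_df <- do.call(rbind, logs)
  records <- log_df[!is.na(log_df$evidence) & log_df$phage_flag %in% FALSE, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, log = log_df), class = "pls_result")
}

#' Write PLS identification results as TSV
#'
#' @param res A `pls_result` from [identify_pls()].
#' @param path Output TSV path (`<path>.log.tsv` also written).
#' @export
write_pls_results <- function(res, path) {
  stopifnot(inherits(res, "pls_result"))
  write_tsv(res$records, path)
  write_tsv(res$log, paste0(path, ".log.tsv"))
  invisible(path)
}
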