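#' Cut labeled replicons into non-overlapping window-sized fragments
#'
#' Each replicon is tiled exactly, in order, by fragments of at most
#' `window` bp (the last fragment may be shorter); replicons shorter than
#' the window stay uncut.  This controls the length bias between 2-200 kb
#' draft contigs and full-length reference chromosomes when estimating
#' sketch distances.
#'
#' @param records Named character vector of replicon sequences.
#' @param origins Named character vector (or unnamed, parallel to
#'   `records`) of origin labels, each `"plasmid"` or `"chromosome"`.
#' @param window Fragment window in bp (default 200000).
#' @return data.frame with columns `fragment_id`, `parent_id`, `origin`,
#'   `start` (0-based half-open offset), `length`, `seq`.
#' @export
fragment_sequences <- function(records, origins, window = 200000) {
  stopifnot(length(records) == length(origins))
  if (is.null(names(records))) stop("records must be named")
  if (!is.null(names(origins))) origins <- origins[names(records)]
  if (!all(origins %in% c("plasmid", "chromosome"))) {
    stop("origins must be 'plasmid' or 'chromosome'")
  }
  rows <- list()
  for (i in seq_along(records)) {
    id <- names(records)[i]
    seq <- records[[i]]
    len <- nchar(seq)
    if (len == 0L) {
      warning("skipping empty sequence: ", id)
      next
    }
    starts <- seq(0L, len - 1L, by = window)
    for (st in starts) {
      fl <- min(window, len - st)
      rows[[length(rows) + 1L]] <- data.frame(
        fragment_id = sprintf("%s|%d", id, st),
        parent_id = id, origin = origins[[i]],
        start = st, length = fl,
        seq = substr(seq, st + 1L, st + fl),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(fragment_id = character(), parent_id = character(),
                      origin = character(), start = integer(),
                      length = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Reduce fragment redundancy by Markov clustering of near-identical pairs
#'
#' Builds the unweighted graph whose edges join fragment pairs at sketch
#' distance below `cutoff`, partitions it with MCL, and keeps one
#' representative per cluster: the longest member, ties broken by
#' lexicographic id.  Clusters mixing plasmid- and chromosome-origin
#' fragments keep one representative per origin so no label class used by
#' the downstream majority vote is silently erased.
#'
#' @param frags Fragment data.frame from [fragment_sequences()].
#' @param cutoff Distance threshold below which fragments are redundant
#'   (default 0.02).
#' @param k,s Sketch parameters.
#' @param inflation MCL inflation (default 2).
#' @param sketches Optional pre-built sketches named by `fragment_id`.
#' @return The retained subset of `frags` (same columns).
#' @export
dedupe_fragments <- function(frags, cutoff = 0.02, k = 17, s = 1000,
                             inflation = 2, sketches = NULL) {
  if (!nrow(frags)) return(frags)
  if (is.null(sketches)) {
    sketches <- build_sketches(stats::setNames(frags$seq, frags$fragment_id),
                               k = k, s = s)
  }
  d <- pairwise_distance_matrix(sketches = sketches)
  adj <- (d < cutoff) * 1
  diag(adj) <- 0
  memb <- mcl_cluster(adj, inflation = inflation)
  keep <- character()
  for (cl in split(names(memb), memb)) {
    sub <- frags[match(cl, frags$fragment_id), , drop = FALSE]
    for (org in unique(sub$origin)) {
      cand <- sub[sub$origin == org, , drop = FALSE]
      cand <- cand[order(-cand$length, cand$fragment_id), , drop = FALSE]
      keep <- c(keep, cand$fragment_id[1])
    }
  }
  frags[frags$fragment_id %in% keep, , drop = FALSE]
}

#' Build the labeled plasmid/chromosome fragment reference database
#'
#' Composition of [fragment_sequences()] and [dedupe_fragments()], with
#' sketches for every retained fragment and recorded provenance.
#'
#' @inheritParams fragment_sequences
#' @inheritParams dedupe_fragments
#' @return An object of class `fragment_db`: list with `fragments`
#'   (data.frame), `sketches` (named list, one per retained fragment), and
#'   `provenance` (parameters used).
#' @export
build_fragment_db <- function(records, origins, window = 200000,
                              cutoff = 0.02, k = 17, s = 1000,
                              inflation = 2) {
  frags <- fragment_sequences(records, origins, window = window)
  sketches <- build_sketches(stats::setNames(frags$seq, frags$fragment_id),
                             k = k, s = s)
  kept <- dedupe_fragments(frags, cutoff = cutoff, inflation = inflation,
                           sketches = sketches)
  structure(
    list(fragments = kept,
         sketches = sketches[kept$fragment_id],
         provenance = list(window = window, dedupe_cutoff = cutoff,
                           k = k, s = s, inflation = inflation,
                           n_input_fragments = nrow(frags),
                           n_retained = nrow(kept))),
    class = "fragment_db")
}

#' Save a fragment database to a directory
#'
#' Writes `fragments.fasta`, `fragments.tsv`, `sketches.jsonl` and
#' `provenance.json`.
#'
#' @param db A `fragment_db`.
#' @param dir Output directory (created if absent).
#' @export
save_fragment_db <- function(db, dir) {
  stopifnot(inherits(db, "fragment_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(stats::setNames(db$fragments$seq, db$fragments$fragment_id),
              file.path(dir, "fragments.fasta"))
  write_tsv(db$fragments[, c("fragment_id", "parent_id", "origin", "start", "length")],
            file.path(dir, "fragments.tsv"))
  write_sketches(db$sketches, file.path(dir, "sketches.jsonl"))
  jsonlite::write_json(db$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a fragment database saved by [save_fragment_db()]
#'
#' @param dir Database directory.
#' @return A `fragment_db`.
#' @export
load_fragment_db <- function(dir) {
  seqs <- read_fasta(file.path(dir, "fragments.fasta"))
  meta <- utils::read.delim(file.path(dir, "fragments.tsv"),
                            stringsAsFactors = FALSE)
  meta$seq <- unname(seqs[meta$fragment_id])
  structure(
    list(fragments = meta,
         sketches = read_sketches(file.path(dir, "sketches.jsonl")),
         provenance = jsonlite::fromJSON(file.path(dir, "provenance.json"))),
    class = "fragment_db")
}
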