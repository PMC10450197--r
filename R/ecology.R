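#' Host range of a PLC
#'
#' Collects the genera of the isolates its member PLSs were derived from,
#' dropping hosts assigned to unknown genera; the PLC is broad-host-range
#' (BHR) when it spans at least two known genera.
#'
#' @param member_isolates Character vector: isolate id per member PLS.
#' @param meta Isolate metadata data.frame with `isolate_id`, `genus`
#'   (genus `"unknown"` marks unassigned hosts).
#' @return List with `genera` (sorted character vector, "unknown" removed)
#'   and `bhr` (logical).
#' @export
host_range <- function(member_isolates, meta) {
  idx <- match(member_isolates, meta$isolate_id)
  if (anyNA(idx)) {
    stop("no metadata for isolate(s): ",
         paste(unique(member_isolates[is.na(idx)]), collapse = ", "))
  }
  genera <- setdiff(sort(unique(meta$genus[idx])), "unknown")
  list(genera = genera, bhr = length(genera) >= 2L)
}

#' Is a PLC present in a metagenome sample?
#'
#' Present iff any member PLS and any sample contig (>= 2 kb) are at sketch
#' distance below `cutoff`.  All members are compared, not just the
#' representative.
#'
#' @param member_seqs Named character vector of member PLS sequences (or a
#'   pre-built list of sketches).
#' @param sample_contigs Named character vector of sample contigs.
#' @param cutoff Presence threshold (default 0.01).
#' @param k,s Sketch parameters.
#' @param member_sketches,contig_sketches Optional pre-built sketch lists
#'   (reused across samples for speed).
#' @return Logical.
#' @export
sample_presence <- function(member_seqs = NULL, sample_contigs = NULL,
                            cutoff = 0.01, k = 17, s = 3000,
                            member_sketches = NULL, contig_sketches = NULL) {
  if (is.null(member_sketches)) member_sketches <- build_sketches(member_seqs, k, s)
  if (is.null(contig_sketches)) {
    keep <- nchar(sample_contigs) >= 2000
    sample_contigs <- sample_contigs[keep]
    if (!length(sample_contigs)) return(FALSE)
    contig_sketches <- build_sketches(sample_contigs, k, s)
  }
  for (msk in member_sketches) {
    if (any(distances_to_set(msk, contig_sketches) < cutoff)) return(TRUE)
  }
  FALSE
}

#' Presence matrix of PLCs across samples
#'
#' @param plc_members Named list: for each PLC, a named character vector of
#'   member sequences.
#' @param samples Named list: for each sample, a named character vector of
#'   contigs.
#' @inheritParams sample_presence
#' @return Logical matrix, PLCs x samples.
#' @export
presence_matrix <- function(plc_members, samples, cutoff = 0.01, k = 17, s = 3000) {
  member_sk <- lapply(plc_members, build_sketches, k = k, s = s)
  sample_sk <- lapply(samples, function(ctgs) {
    ctgs <- ctgs[nchar(ctgs) >= 2000]
    if (!length(ctgs)) return(list())
    build_sketches(ctgs, k = k, s = s)
  })
  out <- matrix(FALSE, length(plc_members), length(samples),
                dimnames = list(names(plc_members), names(samples)))
  for (p in names(plc_members)) {
    for (sm in names(samples)) {
      if (length(sample_sk[[sm]])) {
        out[p, sm] <- sample_presence(member_sketches = member_sk[[p]],
                                      contig_sketches = sample_sk[[sm]],
                                      cutoff = cutoff)
      }
    }
  }
  out
}

#' Per-population prevalence of PLCs
#'
#' Prevalence of a PLC in a population is the number of samples with the
#' PLC divided by the total number of samples in that population; the PLC
#' is flagged highly prevalent when the fraction exceeds `high_prev`
#' (strict) in at least one population.
#'
#' @param presence Logical PLC-by-sample matrix from [presence_matrix()].
#' @param sample_populations Named character vector: population label per
#'   sample (every sample must be labeled).
#' @param high_prev High-prevalence threshold (default 0.10).
#' @return List with `prevalence` (PLC x population numeric matrix) and
#'   `highly_prevalent` (named logical vector over PLCs).
#' @export
prevalence_by_population <- function(presence, sample_populations,
                                     high_prev = 0.10) {
  if (!all(colnames(presence) %in% names(sample_populations))) {
    stop("every sample must carry a population label")
  }
  pops <- sort(unique(sample_populations[colnames(presence)]))
  prev <- matrix(NA_real_, nrow(presence), length(pops),
                 dimnames = list(rownames(presence), pops))
  for (pop in pops) {
    cols <- colnames(presence)[sample_populations[colnames(presence)] == pop]
    if (!length(cols)) {
      warning("population '", pop, "' has no samples; prevalence undefined")
      next
    }
    prev[, pop] <- rowSums(presence[, cols, drop = FALSE]) / length(cols)
  }
  list(prevalence = prev,
       highly_prevalent = apply(prev > high_prev, 1, any, na.rm = TRUE))
}

#' Within-host persistence span of PLCs
#'
#' A PLC is present at a time point if any member is detected in any
#' isolate sampled that day; the span is the number of days between the
#' first and last presence (0 for a single time point).
#'
#' @param plc_presence_days Named list: for each PLC, the integer sampling
#'   days at which it was detected (PLCs never detected are absent).
#' @param thresholds Day thresholds to count PLCs at (default `c(50, 150)`).
#' @return List with `spans` (data.frame `plc_id`, `span_days`) and
#'   `threshold_counts` (named integer vector: PLCs with span at least each
#'   threshold).
#' @export
persistence_span <- function(plc_presence_days, thresholds = c(50, 150)) {
  keep <- vapply(plc_presence_days, length, integer(1)) > 0L
  plc_presence_days <- plc_presence_days[keep]
  spans <- data.frame(
    plc_id = names(plc_presence_days),
    span_days = vapply(plc_presence_days, function(d) max(d) - min(d), numeric(1)),
    stringsAsFactors = FALSE)
  counts <- vapply(thresholds, function(th) sum(spans$span_days >= th), integer(1))
  names(counts) <- paste0(">=", thresholds, "d")
  list(spans = spans, threshold_counts = counts)
}

#' Percentage with half-up rounding to one decimal
#'
#' Reproduces headline ratios of the form "3492/4983 = 70.1\%".
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @return `100 * numerator / denominator` rounded half-up to one decimal.
#' @examples
#' fraction_summary(3492, 4983)  # 70.1
#' @export
fraction_summary <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  floor(1000 * numerator / denominator + 0.5) / 10
}
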