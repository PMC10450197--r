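#' Sample random labeled fragments with an even length distribution
#'
#' Draws `n` contiguous substrings from the supplied replicons.  For each
#' fragment a target length is drawn uniformly over `len_range`, capped at
#' the source length, and a uniform start offset is chosen; the source
#' record is picked uniformly at random.  Fully seeded and reproducible.
#'
#' @param records Named character vector of source replicons (each >= 2 kb).
#' @param origins Origin label per record (`"plasmid"`/`"chromosome"`).
#' @param n Number of fragments to draw.
#' @param len_range Two-element vector, default `c(2000, 200000)`.
#' @param seed Integer seed.
#' @return data.frame with columns `fragment_id`, `parent_id`, `origin`,
#'   `start`, `length`, `seq`.
#' @export
sample_random_fragments <- function(records, origins, n,
                                    len_range = c(2000, 200000), seed = 1) {
  if (n <= 0) stop("n must be positive")
  if (!length(records)) stop("no source records supplied")
  stopifnot(length(records) == length(origins))
  if (!is.null(names(origins))) origins <- origins[names(records)]
  withr_seed <- .seed_guard(seed)
  on.exit(withr_seed())
  src <- sample.int(length(records), n, replace = TRUE)
  lens <- nchar(records)
  want <- round(stats::runif(n, len_range[1], len_range[2]))
  flen <- pmin(want, lens[src])
  start0 <- vapply(seq_len(n), function(i) {
    sample.int(lens[src[i]] - flen[i] + 1L, 1L) - 1L
  }, integer(1))
  data.frame(
    fragment_id = sprintf("frag_%05d", seq_len(n)),
    parent_id = names(records)[src],
    origin = unname(origins[src]),
    start = start0,
    length = as.integer(flen),
    seq = substr(records[src], start0 + 1L, start0 + flen),
    stringsAsFactors = FALSE)
}

# Set the RNG seed locally; returns a restore function.
.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Per-class gene-family frequencies on labeled fragments
#'
#' Frequencies are presence/absence per fragment: a gene hit several times
#' within one fragment counts once.  `FP(g)` is the fraction of plasmid
#' fragments with at least one hit to `g` at `evalue <= evalue_max`; `FC(g)`
#' the chromosome analogue.  The ratio `FP/FC` is `Inf` when `FC = 0` and
#' `FP > 0` (a gene never seen on chromosomes is maximal plasmid evidence).
#'
#' @param annotations data.frame with `element_id`, `gene_id`, `evalue`.
#' @param plasmid_ids,chromosome_ids Character vectors partitioning the
#'   annotated elements (must be disjoint and non-empty).
#' @param evalue_max Significance threshold (default 0.001).
#' @return data.frame (`marker_table`) with `gene_id`, `FP`, `FC`, `ratio`.
#' @export
compute_marker_frequencies <- function(annotations, plasmid_ids, chromosome_ids,
                                       evalue_max = 0.001) {
  if (!length(plasmid_ids) || !length(chromosome_ids)) {
    stop("both element id sets must be non-empty")
  }
  if (length(intersect(plasmid_ids, chromosome_ids))) {
    stop("plasmid and chromosome id sets overlap")
  }
  ann <- annotations[annotations$evalue <= evalue_max, c("element_id", "gene_id")]
  ann <- unique(ann)
  genes <- sort(unique(ann$gene_id))
  np <- length(plasmid_ids)
  nc <- length(chromosome_ids)
  fp <- table(factor(ann$gene_id[ann$element_id %in% plasmid_ids], levels = genes)) / np
  fc <- table(factor(ann$gene_id[ann$element_id %in% chromosome_ids], levels = genes)) / nc
  fp <- as.numeric(fp); fc <- as.numeric(fc)
  ratio <- ifelse(fc > 0, fp / fc, ifelse(fp > 0, Inf, NaN))
  data.frame(gene_id = genes, FP = fp, FC = fc, ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Select plasmid-like and chromosome-like gene markers
#'
#' Genes rare on both classes (`FP < low_freq` and `FC < low_freq`) are
#' removed first.  Among survivors, PGMs are genes with `FP/FC > ratio_min`
#' (including infinite ratios) and CGMs are the `n_cgm` genes with the
#' smallest ratios; ratio ties at the CGM boundary are broken by larger
#' `FC`, then lexicographic `gene_id`.  PGMs and CGMs are disjoint.
#'
#' @param table Marker table from [compute_marker_frequencies()].
#' @param ratio_min PGM ratio threshold (default 7).
#' @param low_freq Low-frequency removal threshold (default 0.002, i.e.
#'   0.2\%).
#' @param n_cgm Number of CGMs to select (default 1400).
#' @return List with `pgm`, `cgm` (character vectors) and `table` (input
#'   table with a `cls` column in `{PGM, CGM, neither, removed}`).
#' @export
select_markers <- function(table, ratio_min = 7, low_freq = 0.002, n_cgm = 1400) {
  if (!nrow(table)) stop("marker table is empty")
  cls <- rep("neither", nrow(table))
  removed <- table$FP < low_freq & table$FC < low_freq
  cls[removed] <- "removed"
  surv <- which(!removed)
  pgm_idx <- surv[table$ratio[surv] > ratio_min & !is.nan(table$ratio[surv])]
  cls[pgm_idx] <- "PGM"
  cgm_pool <- setdiff(surv, pgm_idx)
  if (n_cgm > length(cgm_pool)) {
    warning("n_cgm (", n_cgm, ") exceeds surviving gene count (",
            length(cgm_pool), "); taking all")
    n_take <- length(cgm_pool)
  } else {
    n_take <- n_cgm
  }
  ord <- cgm_pool[order(table$ratio[cgm_pool], -table$FC[cgm_pool],
                        table$gene_id[cgm_pool])]
  cgm_idx <- ord[seq_len(n_take)]
  cls[cgm_idx] <- "CGM"
  table$cls <- cls
  list(pgm = table$gene_id[pgm_idx], cgm = table$gene_id[cgm_idx], table = table)
}
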