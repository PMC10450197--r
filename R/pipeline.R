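#' Default pipeline parameters
#'
#' Every threshold defaults to the workflow's standard value: sketch
#' `k = 17`; reference-vote cutoff 0.15; PLC linkage cutoff 0.01; fragment
#' dedupe cutoff 0.02; marker thresholds (ratio > 7, low frequency 0.2\%,
#' 1400 CGMs); completeness threshold 0.6 with DTR length 10 / mismatch 1;
#' typing-network cutoff 0.15; MCL inflation 2.
#'
#' @return Named list of parameters.
#' @export
default_pipeline_params <- function() {
  list(k = 17, s_db = 1000, s_pls = 3000,
       ref_cutoff = 0.15, plc_cutoff = 0.01, dedupe_cutoff = 0.02,
       marker_ratio_min = 7, marker_low_freq = 0.002, n_cgm = 1400,
       marker_evalue_max = 0.001, backbone_evalue_max = 1e-10,
       compls_threshold = 0.6, dtr_min_len = 10, dtr_max_mismatch = 1,
       network_cutoff = 0.15, mcl_inflation = 2, min_contig_len = 2000)
}

#' Run the identification pipeline end to end
#'
#' Stages: build the labeled fragment database, identify PLSs (reference
#' vote, marker rule, phage screen, backbone detection), compute the PLS
#' distance matrix, cluster into candidate PLCs, and retain
#' high-confidence PLCs.  All stage outputs and a provenance record (the
#' parameters actually used) are written to `out_dir`.
#'
#' @param contigs data.frame with `contig_id`, `isolate_id`, `seq`.
#' @param ref_seqs Named character vector of labeled reference replicons.
#' @param ref_origins Origin label per reference record.
#' @param annotations Optional annotation data.frame.
#' @param pgms,cgms Marker sets (character vectors).
#' @param completeness Optional completeness data.frame
#'   (see [estimate_completeness()]).
#' @param mobility Optional mobility table
#'   (see [retain_high_confidence_plcs()]).
#' @param out_dir Output directory (created).
#' @param params Parameter overrides merged over
#'   [default_pipeline_params()].
#' @return Invisible list with `db`, `pls`, `dm`, `plc_table`,
#'   `plc_summary`, and `out_dir`.
#' @export
run_pipeline <- function(contigs, ref_seqs, ref_origins, annotations = NULL,
                         pgms = character(), cgms = character(),
                         completeness = NULL, mobility = NULL,
                         out_dir = tempfile("plasmidnet_run_"),
                         params = list()) {
  p <- utils::modifyList(default_pipeline_params(), params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  db <- build_fragment_db(ref_seqs, ref_origins, cutoff = p$dedupe_cutoff,
                          k = p$k, s = p$s_db, inflation = p$mcl_inflation)
  save_fragment_db(db, file.path(out_dir, "db"))

  res <- identify_pls(contigs, db, pgms = pgms, cgms = cgms,
                      annotations = annotations, cutoff = p$ref_cutoff,
                      evalue_max = p$marker_evalue_max,
                      backbone_evalue_max = p$backbone_evalue_max,
                      min_len = p$min_contig_len, k = p$k, s = p$s_db)
  write_pls_results(res, file.path(out_dir, "pls.tsv"))

  dm <- NULL
  plc_table <- NULL
  plc_summary <- NULL
  if (nrow(res$records)) {
    pls_seqs <- stats::setNames(
      contigs$seq[match(res$records$contig_id, contigs$contig_id)],
      res$records$contig_id)
    dm <- pairwise_distance_matrix(pls_seqs, k = p$k, s = p$s_pls)
    write_distance_matrix(dm, file.path(out_dir, "pls_distances.tsv"))
    plc_table <- build_plcs(dm, nchar(pls_seqs), cutoff = p$plc_cutoff)
    plc_table$isolate_id <- res$records$isolate_id[
      match(plc_table$contig_id, res$records$contig_id)]
    write_tsv(plc_table, file.path(out_dir, "plc_members.tsv"))
    backbone <- stats::setNames(res$records$backbone_genes, res$records$contig_id)
    plc_summary <- retain_high_confidence_plcs(plc_table, backbone,
                                               completeness = completeness,
                                               mobility = mobility)
    write_tsv(plc_summary, file.path(out_dir, "plc_summary.tsv"))
  }

  jsonlite::write_json(
    list(parameters = p, n_contigs = nrow(contigs),
         n_reference_records = length(ref_seqs),
         n_db_fragments = nrow(db$fragments),
         n_pls = if (is.null(res$records)) 0L else nrow(res$records),
         n_plcs = if (is.null(plc_summary)) 0L else nrow(plc_summary),
         n_retained_plcs = if (is.null(plc_summary)) 0L else sum(plc_summary$retained)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(db = db, pls = res, dm = dm, plc_table = plc_table,
                 plc_summary = plc_summary, out_dir = out_dir))
}
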