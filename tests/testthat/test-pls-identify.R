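make_tiny_db <- function(seed = 601) {
  set.seed(seed)
  recs <- c(plasA = rand_seq(4000), chromA = rand_seq(4000))
  build_fragment_db(recs, c(plasA = "plasmid", chromA = "chromosome"), s = 2000)
}

test_that("reference vote distinguishes plasmid, undetermined and ambiguous", {
  db <- make_tiny_db()
  plas <- db$fragments$seq[db$fragments$origin == "plasmid"]
  chrom <- db$fragments$seq[db$fragments$origin == "chromosome"]

  hit <- classify_by_reference(build_sketch(plas, s = 2000), db)
  expect_equal(hit$category, "plasmid_like")
  expect_equal(c(hit$n_plasmid_hits, hit$n_chromosome_hits), c(1L, 0L))

  set.seed(602)
  none <- classify_by_reference(build_sketch(rand_seq(3000), s = 2000), db)
  expect_equal(none$category, "undetermined")
  expect_equal(c(none$n_plasmid_hits, none$n_chromosome_hits), c(0L, 0L))

  # chimera: half plasmid, half chromosome; oracle confirms both
  # fragments fall below the 0.15 cutoff
  chim <- paste0(substr(plas, 1, 3000), substr(chrom, 1, 3000))
  expect_lt(mash_closed_form(exact_jaccard(chim, plas)), 0.15)
  expect_lt(mash_closed_form(exact_jaccard(chim, chrom)), 0.15)
  amb <- classify_by_reference(build_sketch(chim, s = 2000), db)
  expect_equal(amb$category, "ambiguous")
  expect_equal(c(amb$n_plasmid_hits, amb$n_chromosome_hits), c(1L, 1L))
})

test_that("marker rule needs a PGM and vetoes on any CGM", {
  ann <- function(genes) data.frame(element_id = "c", gene_id = genes,
                                    product = "x", evalue = 1e-5,
                                    stringsAsFactors = FALSE)
  pgms <- c("P1", "P2", "P3")
  cgms <- c("C1")
  expect_true(classify_by_markers(ann("P1"), pgms, cgms))
  expect_false(classify_by_markers(ann(c("P1", "P2", "P3", "C1")), pgms, cgms))
  expect_false(classify_by_markers(ann("other"), pgms, cgms))
  # insignificant hits do not count
  weak <- ann("P1"); weak$evalue <- 0.5
  expect_false(classify_by_markers(weak, pgms, cgms))
})

test_that("phage screen matches whole words only", {
  ann <- function(p) data.frame(element_id = "c", gene_id = "g", product = p,
                                evalue = 1e-20, stringsAsFactors = FALSE)
  expect_true(phage_screen(ann("large terminase subunit")))
  expect_true(phage_screen(ann("phage tail fiber protein")))
  expect_true(phage_screen(ann("Capsid protein")))
  expect_false(phage_screen(ann("curtailed hypothetical protein")))
  expect_false(phage_screen(ann("headless chicken protein")))
})

test_that("backbone keyword categories follow the centralized rule", {
  ann <- function(p, e = 1e-20) data.frame(element_id = "c", gene_id = "g",
                                           product = p, evalue = e,
                                           stringsAsFactors = FALSE)
  expect_equal(detect_backbone_genes(ann("replication protein RepA")), "rep")
  expect_setequal(detect_backbone_genes(ann("conjugal transfer protein TraG")),
                  c("conj", "tra"))
  expect_equal(detect_backbone_genes(ann("plasmid partition protein ParA")),
               "partition")
  expect_length(detect_backbone_genes(ann("hypothetical protein")), 0)
  # long words do not trigger short gene symbols
  expect_length(detect_backbone_genes(ann("transfer and transport protein")), 0)
  # backbone detection uses the stricter e-value
  expect_length(detect_backbone_genes(ann("RepA", e = 1e-5)), 0)
})

test_that("two-stage identification composes with the phage veto", {
  db <- make_tiny_db(604)
  plas <- db$fragments$seq[db$fragments$origin == "plasmid"]
  chrom <- db$fragments$seq[db$fragments$origin == "chromosome"]
  set.seed(605)
  novel <- rand_seq(3000)
  contigs <- data.frame(
    contig_id = c("ctg_p", "ctg_c", "ctg_n"),
    isolate_id = "iso1",
    seq = c(mutate_seq(plas, 40), mutate_seq(chrom, 40), novel),
    stringsAsFactors = FALSE)
  ann <- data.frame(element_id = "ctg_n", gene_id = "P1",
                    product = "mobilization protein MobA", evalue = 1e-20,
                    stringsAsFactors = FALSE)
  res <- identify_pls(contigs, db, pgms = "P1", cgms = "C1", annotations = ann,
                      s = 2000)
  expect_equal(sort(res$records$contig_id), c("ctg_n", "ctg_p"))
  expect_setequal(res$records$evidence, c("candidate_I", "candidate_II"))
  expect_equal(res$records$backbone_genes[res$records$contig_id == "ctg_n"], "mob")
  # no contig carries both evidence classes
  expect_false(any(duplicated(res$records$contig_id)))

  # phage veto removes an otherwise plasmid-like contig
  ann2 <- data.frame(element_id = "ctg_p", gene_id = "g",
                     product = "capsid protein", evalue = 1e-20,
                     stringsAsFactors = FALSE)
  res2 <- identify_pls(contigs[1, ], db, annotations = ann2, s = 2000)
  expect_equal(nrow(res2$records), 0L)
  expect_match(res2$log$decision, "phage")

  # empty genome and short contigs
  empty <- identify_pls(contigs[0, ], db)
  expect_equal(nrow(empty$records), 0L)
  short <- identify_pls(data.frame(contig_id = "s", isolate_id = "i",
                                   seq = rand_seq(500)), db)
  expect_equal(nrow(short$records), 0L)
  expect_match(short$log$decision, "2 kb")
})

test_that("noiseless synthetic benchmark is recovered near-perfectly", {
  refs <- gen_reference_set(701, n_plasmids = 6, n_chromosomes = 6,
                            members_per_family = 2,
                            plasmid_len_range = c(5000, 12000),
                            chromosome_len_range = c(15000, 25000),
                            divergence = 0.03)
  bm <- gen_mimic_benchmark(702, refs, n_per_class = 15, len_range = c(2000, 6000))
  db <- build_fragment_db(bm$db_seqs, bm$db_origins, s = 500)
  contigs <- data.frame(contig_id = bm$queries$fragment_id, isolate_id = "i",
                        seq = bm$queries$seq, stringsAsFactors = FALSE)
  res <- identify_pls(contigs, db, s = 500)
  sc <- score_benchmark(res$records$contig_id, bm$truth)
  expect_equal(sc$fp, 0)
  expect_gte(sc$recall_pct, 95)
})
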