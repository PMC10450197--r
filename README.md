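# plasmidnet

Plasmids drive horizontal gene transfer in the gut microbiome, but most of
what is known about them comes from complete genomes. When bacterial
isolates are sequenced as draft assemblies, plasmids surface only as
anonymous contigs mixed in with chromosomal fragments. `plasmidnet`
implements a desk-scale version of a culturomics-era workflow for pulling
those plasmids back out and characterizing them:

1. **Identification.** Every contig (>= 2 kb) is compared by strand-neutral
   MinHash sketch distance (k = 17, the Mash estimator
   `d = -(1/k) * ln(2j/(1+j))`) against a reference database of labeled
   plasmid and chromosome fragments (<= 200 kb tiles, redundancy-reduced by
   Markov clustering at distance < 0.02). A contig is a *candidate I*
   plasmid-like sequence (PLS) when it hits more plasmid than chromosome
   fragments at distance < 0.15. Contigs with no reference hit are rescued
   as *candidate II* when they encode at least one plasmid-like gene marker
   (PGM) and no chromosome-like marker (CGM); markers are selected from
   per-class gene-family frequencies by the FP/FC ratio rule (> 7 for PGMs,
   bottom 1400 ratios for CGMs, genes below 0.2% frequency on both classes
   removed). Contigs carrying phage keywords (terminase, holin, head, tail,
   portal, capsid) are vetoed; plasmid backbone genes (rep, mob, tra, ...)
   are recorded.
2. **Clustering.** PLSs group into plasmid-like clusters (PLCs) by
   complete-linkage clustering at Mash distance 0.01 (~99% ANI); clusters
   are retained when a member is ~100% complete or carries backbone genes.
3. **Completeness.** Circularity is detected from direct terminal repeats
   (>= 10 bp, <= 1 mismatch) confirmed by junction-spanning read pairs, or
   estimated from the assembly graph as `L_PLS / (L_PLS + L_G)` along the
   shortest circular path through the PLS's nodes, with copy numbers from
   the abundance balance `C = (A - min(Ap, Af)) / Abase`. PLSs above 60%
   completeness are comPLSs.
4. **Typing and ecology.** comPLC representatives join their three nearest
   reference plasmids (< 0.15) in a similarity network partitioned into
   network typing groups (NTGs) by Markov clustering; host range (broad if
   >= 2 known genera), per-population prevalence (> 10% = highly
   prevalent), and within-host persistence spans are tabulated.
5. **Haplotypes.** Circular members are rotation/strand-normalized, aligned,
   collapsed into haplotypes (single-base indels count), and connected in a
   median-joining network; a linear clock (30 mutations/year per 1.67 Mb,
   scaled by plasmid length) converts edge weights into transmission-time
   estimates.

Seeded generators (`gen_reference_set`, `gen_mimic_benchmark`,
`gen_assembly_fixture`, `gen_haplotype_population`) fabricate every input
format the pipeline reads, with recorded ground truth, so the whole chain
is testable without external data.

## Worked example

```r
library(plasmidnet)

refs <- gen_reference_set(7, n_plasmids = 6, n_chromosomes = 6,
                          members_per_family = 2, divergence = 0.03)
bm   <- gen_mimic_benchmark(11, refs, n_per_class = 20, len_range = c(2000, 6000))
db   <- build_fragment_db(bm$db_seqs, bm$db_origins, s = 500)
contigs <- data.frame(contig_id = bm$queries$fragment_id,
                      isolate_id = "iso1", seq = bm$queries$seq)
res <- identify_pls(contigs, db, s = 500)
score_benchmark(res$records$contig_id, bm$truth)
#> $tp
#> [1] 20
#> $fp
#> [1] 0
#> $n_true_plasmid
#> [1] 20
#> $precision_pct
#> [1] 100
#> $recall_pct
#> [1] 100
```

Every held-out plasmid fragment (a mutated relative of a database plasmid)
is recovered as a PLS and no chromosome fragment leaks through: precision
100%, recall 100% on this noiseless benchmark. The zero-mutation
transmission window for a 5.6-kb plasmid under the default clock:

```r
transmission_window(0, 5600)[c("lower", "upper")]
#> $lower
#> [1] 0
#> $upper
#> [1] 10
```

i.e. identical haplotypes found in different environments are estimated to
have diverged within the last ~10 years.

A thin command-line wrapper lives in `inst/scripts/plasmidnet-cli.R`
(`simulate` and `run` subcommands over the same functions).

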