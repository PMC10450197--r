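---
title: "Methods: identifying and characterizing plasmid-like sequences in draft genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and characterizing plasmid-like sequences in draft genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidnet)
```

## The problem

Draft genomes of bacterial isolates arrive as bags of contigs. Plasmids —
extrachromosomal replicons that shuttle resistance and fitness genes
between strains, sometimes across genera — are in there, but nothing in an
assembly labels them. `plasmidnet` reconstructs a complete analysis chain
for this situation: calling plasmid-like sequences (PLSs), grouping them
into plasmid-like clusters (PLCs), judging how complete each sequence is,
typing clusters on a similarity network, measuring host range, prevalence
and persistence, and tracing recent transmission with haplotype networks.
This vignette explains the models, parameters and design choices; the
README shows the user-facing surface.

## Sketch distances

Every similarity decision runs on strand-neutral MinHash sketches.
Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
complement, so contig strand never matters) are hashed and the `s`
smallest values kept. The Jaccard index `j` between two sequences is
estimated from the `min(s, |union|)` smallest hashes of the merged
sketches, then converted to the Mash distance
`d = -(1/k) ln(2j / (1 + j))`, capped at 1 when no hashes are shared.
Distance tracks `1 - ANI` closely near identity, which is what anchors the
pipeline's cutoffs: 0.01 for clustering (~99% ANI, the intra-strain
regime), 0.15 for the reference vote and typing network, 0.02 for
reference redundancy removal.

Numerical choices worth knowing:

* `k = 17` everywhere; `s = 3000` for PLS-versus-PLS matrices, smaller
  capacities for fragment databases where speed matters more than variance.
* The hash is splitmix64 with a fixed seed, truncated to its top 53 bits so
  hash values are exactly representable as R doubles (and survive JSON
  round trips as decimal strings). Truncation costs nothing detectable at
  sketch scale: the collision probability across a 3000-hash sketch is
  ~`3000^2 / 2^53`.
* k-mers containing non-ACGT symbols are skipped, not substituted — draft
  genomes contain N runs, and substituting would fabricate sequence.
* When `s` is at least the union size, the estimator degenerates to the
  exact Jaccard; the test suite exploits this to check the sketch path
  against brute-force k-mer enumeration.

## The reference database and the two-stage caller

Reference replicons are tiled into non-overlapping fragments of at most
200 kb (most plasmids are shorter and stay uncut). Tiling controls the
length asymmetry between 2–200 kb query contigs and multi-megabase
chromosomes, which would otherwise inflate sketch distances. Near-identical
fragments (distance < 0.02) are collapsed by Markov clustering (MCL,
inflation 2.0) to one representative per cluster — the longest member, ties
broken lexicographically. A cluster that mixes plasmid- and
chromosome-origin fragments keeps one representative *per origin*: the
downstream vote counts labels, and silently erasing a label class would
bias it. Whether the original procedure clustered a weighted or unweighted
graph is not documented; we cluster the unweighted `< 0.02` adjacency and
expose the choice.

Identification is two-staged, in a fixed order:

1. **Reference vote.** A contig hitting strictly more plasmid than
   chromosome fragments at distance < 0.15 is a candidate I PLS. Ties with
   non-zero counts are *ambiguous* and excluded from both candidacy and the
   marker stage — they did align to something, so they are not
   "undetermined"; this is the conservative-precision reading. Zero hits
   means undetermined.
2. **Marker rule.** Undetermined contigs become candidate II PLSs when
   they encode at least one plasmid-like gene marker (PGM) and no
   chromosome-like marker (CGM) at e-value <= 0.001.

Markers come from gene-family frequencies on labeled fragments: `FP(g)`
and `FC(g)` are the fractions of plasmid / chromosome fragments encoding
`g` (presence/absence per fragment, not copy number — multi-copy hits count
once). Genes rare on both classes (< 0.2%) are removed; PGMs have
`FP/FC > 7`; CGMs are the 1400 smallest ratios. `FC = 0` with `FP` above
the floor is treated as an infinite ratio and qualifies as a PGM — a gene
never seen on chromosomes is maximal plasmid evidence. Ties at the CGM
boundary break by larger `FC`, then gene id, so selection is deterministic.

Both candidate classes then pass a phage screen: any product description
containing a phage keyword (terminase, holin, head, tail, portal, capsid)
as a whole word vetoes the contig, which also removes plasmid–phage
elements. Keyword matching is centralized in one rule: products are split
into maximal alphanumeric tokens, lowercased; phage keywords must match a
whole token; backbone keywords match a whole token, and the short gene
symbols (rep, rop, mob, tra, trb, mbp) additionally match as prefixes of
tokens of length <= 5 (RepA, TraG, MobC), while stems (conj, primase,
relaxase, resolvase, partition) match as token prefixes (conjugal,
conjugative). The single-keyword phage veto is the strictest defensible
reading of a manual curation step; `mbp` is matched literally although it
is ambiguous (maltose-binding vs mobilization), and both decisions are
visible in the per-contig decision log.

## Clustering and retention

PLSs cluster into PLCs by complete-linkage hierarchical clustering cut at
distance 0.01, which guarantees every cluster's *maximum* pairwise
distance is within the cutoff — the property the PLC definition needs,
and the reason average or single linkage would be wrong here. The PLC
representative is its longest member. A candidate PLC is retained when at
least one member is ~100% complete or carries backbone genes; conjugative
and mobilizable flags are ingested from external annotation (a PLC is
mobilizable only if no member is conjugative, so the flags are mutually
exclusive).

## Completeness

Two routes, in order of confidence:

* **DTR + read pairs.** A direct terminal repeat (prefix and suffix of
  length >= 10 agreeing up to 1 mismatch; the longest such length is
  reported) marks a likely circular sequence. The trailing repeat copy is
  trimmed and mate pairs are placed on the trimmed sequence; a mate is an
  end hit when >= 90% of it aligns and >= 20 bp fall inside the 300-bp end
  window outside the repeat. One pair with a hit on each end confirms
  circularity, and the PLS is scored 100% complete.
* **Assembly graph.** Otherwise the PLS is anchored to its best-hit nodes
  in the orientation-aware assembly graph (FASTG, SPAdes dialect; reverse
  records are normalized to orientation flags, and every edge's
  reverse-complement mirror is added). The shortest circular path through
  the anchors, by total bp rather than hop count — completeness is a
  length ratio, so the length-minimal cycle is the conservative gap
  estimate — is found by chaining weighted shortest-path legs between
  consecutive anchors. Because this is Dijkstra per leg, the search is
  polynomial and needs no visit caps. Copy numbers come from the abundance
  balance `C = (A - min(Ap, Af)) / Abase`, where `Ap`/`Af` sum the
  abundances of adjoining nodes *not on the path* at the node's two ends;
  `C > 1.8` flags multi-copy, except nodes traversed in opposite
  orientations, which need `C > 2.8`. The path is accepted only when every
  consecutive junction (including the closing one) is spanned by a mate
  pair with both mates at >= 90% coverage.

Completeness is `L_PLS / (L_PLS + L_G)`. Read literally as "all nodes in
the shortest path", `L_G` would score a perfectly complete single-node
plasmid near 0.5, contradicting the ~100% route; we therefore interpret
`L_G` as the summed length of path nodes *not covered by the PLS* (the
gap), which makes the two routes agree, and keep the literal reading
available behind `mode = "path_total"`. Completeness above 0.6 (strict)
makes a comPLS.

Read placement in this package is exact-substring matching with
end-overhang handling — sufficient for the error-free mate pairs the
fixture generator emits, and the contract (coverage >= 0.9, anchor >=
20 bp) rather than the mapper is what the functions promise. Real
sequencing data should be mapped externally if error tolerance matters.

## Typing, ecology

For each comPLC representative, its up-to-3 nearest reference plasmids at
distance < 0.15 join the typing network; pairwise distances over the
union are recomputed, edges drawn below 0.15 (unweighted, matching the
network definition), singleton comPLCs with no neighbor excluded, and MCL
partitions the rest into network typing groups. MCL is implemented in the
package (expansion by matrix squaring, element-wise inflation with column
renormalization, pruning, convergence on max change; clusters are the
connected components of the converged flow) because no installed R
package provides it; inflation defaults to 2.0 and is configurable since
the original's setting is not recorded.

Host range counts the distinct known genera of member isolates — hosts of
unknown genus are excluded — and two or more genera make a broad-host-range
(BHR) PLC. A PLC is present in a metagenome sample when *any* member is
within 0.01 of *any* contig (>= 2 kb) of the sample; all members are
compared, not just the representative, with sketches reused across
samples to contain cost. Prevalence is presence count over population
size, flagged above 10% (strict). Persistence is the day span between
first and last detection in a donor's isolates, presence at a time point
meaning any isolate sampled that day — the reading consistent with
detection "in any isolates across different time points"; span >= 50 days
is the headline threshold.

## Haplotype networks and the transmission clock

Only members with an exact (mismatch-free) DTR of >= 10 bp enter — stricter
than the completeness screen, because haplotype calling cannot tolerate an
uncertain terminus. One terminal repeat copy is trimmed and the sequence is
normalized to the lexicographically smallest rotation over both strands
(Booth's algorithm), a deterministic, orbit-invariant replacement for an
unspecified reformatting script; any shared-anchor scheme would give the
same downstream distances. Members are aligned to the median-length member
by global pairwise alignment and merged into common columns — a progressive
scheme adequate above 99% identity; an external alignment can be
substituted. Members with indel runs >= 2 bp against the reference are
removed; single-base indels stay and count as differences (gap is a fifth
character state), so haplotype distances reflect *all* differences between
the complete sequences, and members of one haplotype are 100% identical.

The median-joining network iterates: build the minimum-spanning network
(union of all minimum spanning trees; epsilon relaxes the inclusion level,
default 0 as in common PopART use) and, for every pair of edges sharing a
node, add the columnwise-majority median of the triple when it is new
(ties resolve toward the shared neighbor). Inferred medians not on any
Hamming geodesic between observed haplotypes are pruned, and redundant tie
edges — those with an equal-or-shorter alternative path — are removed from
the final network. On tree-like (infinite-sites) data this yields the
optimal network: the test suite checks the enumerated star optimum, planted
mutation-tree recovery, and that total network weight never exceeds the
observed minimum-spanning-tree weight. With recurrent mutation the network
legitimately keeps reticulations, and that bound no longer applies.

The clock scales a genome-wide rate (default 30 mutations/year on a
1.67-Mb genome, the Helicobacter pylori benchmark) to the plasmid:
`lambda = rate x plasmid_len / genome_len` per year. Zero observed
differences yield the window `[0, 1/lambda]` (upper bound rounded to the
nearest year — about 10 years for a 5.6-kb plasmid); `n` differences give
the point estimate `n / lambda`. This is a linear clock, not a calibrated
phylogeny; it dates divergence, not transfer events.

## What the synthetic generators model — and what they do not

The generators are pure functions of `(seed, parameters)`. Unrelated
replicons are uniform random sequences (at k = 17, sharing k-mers with
vanishing probability, so between-family distances sit at ~1);
relatedness is planted explicitly by copy-with-mutations, making expected
distances analytically predictable. The benchmark generator mirrors a
hold-out design: per family, held-out members supply query fragments
while their relatives form the database, so queries never meet their own
parent. Assembly fixtures cut a random circle into cycle nodes at exact
planted fractions, attach dead-end decoys, draw abundances as
`coverage x multiplicity x (1 + U(-noise, noise))` (default noise 10%),
and emit error-free junction-spanning mate pairs. The haplotype generator
plants a unique rotation anchor (an A-run the C/G body cannot imitate) so
canonical rotations of all members align column-for-column, and mutations
are biallelic C/G flips at distinct positions — the infinite-sites model.

Consequently, passing tests demonstrate the *contracts*: vote arithmetic,
cutoff behavior, path and copy-number algebra, network optimality on
tree-like data. They do not demonstrate robustness to real-genome
composition (GC skew, repeats, shared mobile elements between plasmids
and chromosomes), sequencing error, or alignment ambiguity at lower
identity — on real data the reference database quality and the external
annotations dominate performance, as the precision/recall gap between the
noiseless synthetic benchmark (perfect) and the published mimic benchmark
(99.4% / 80.0%) illustrates.

Problem sizes in the shipped tests and acceptance script are deliberately
desk-scale (tens of replicons, thousands of bases, five seeds): the
quantities being checked are arithmetic identities and planted-truth
recoveries whose outcomes are size-stable, so small inputs exercise the
same code paths the full-size workflow would.

## Known limitations

* The reference-free stage depends entirely on externally produced
  annotation tables; no ORF calling or protein search is performed.
* Read placement is exact-match; the completeness read-confirmation
  contract is therefore only meaningful for low-error reads or externally
  produced mappings.
* The progressive pairwise MSA can misplace insertions between members
  when two members insert different sequence at the same reference
  position; at the > 99% identity regime the filter targets, this is rare
  and bounded to single columns.
* MCL inflation, the dedupe graph weighting, and the completeness `L_G`
  interpretation are documented choices where the original procedure is
  underspecified; all are exposed as parameters.
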