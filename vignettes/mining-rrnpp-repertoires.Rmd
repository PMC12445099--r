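---
title: "Mining RRNPP quorum-sensing repertoires: models and design choices"
author: "RRNPPminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining RRNPP quorum-sensing repertoires: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

RRNPPminer detects cytoplasmic peptide-binding quorum-sensing regulators
of the RRNPP superfamily (Rgg, ComR, PlcR, PrgX families) in bacterial
genomes, clusters them into similarity clusters, discovers the short
coding sequences that may encode their auto-inducing peptides (AIPs,
notably the short hydrophobic peptides, SHPs, of Rgg systems), and
summarises regulator repertoires across strains. A peptide-chemistry
module supports mass-spectrometry bookkeeping (GRAVY hydropathy,
monoisotopic masses, crosslink mass deltas, m/z). A synthetic-genome
generator with a complete ground-truth manifest makes every stage
testable offline.

This vignette records the models, the tunable parameters with their
defaults and rationale, the numerical choices, and the limits of what a
green test establishes.

# The detection model

## Profile construction

A single generic profile HMM is built from a multiple alignment of bait
regulators spanning the four families (`buildProfile`). Alignment
columns with gap fraction <= 0.5 become match states. Match emissions
are column residue counts blended with the Robinson–Robinson background
through a pseudocount of total weight `pseudocountWeight`; insert
states emit the background; transitions are estimated from the observed
gap structure with Laplace (+1) smoothing.

`pseudocountWeight` defaults to **5**. With ~33 sequences per column, a
weight of 1 makes a residue unseen in the column score about -3.5 nats,
much harsher than the Dirichlet-mixture priors of standard profile
builders; in practice that over-penalty makes the local alignment trim
noisy termini of genuine full-length homologs, which then fail the
"alignment starts at profile position <= 10" filter. Weight 5
reproduces the soft-prior behaviour (mismatches cost roughly 1.5–2
nats) and full-length homologs align end to end.

## Local alignment and scoring

Search (`searchProfile`) runs a plan7-like **local** Viterbi over the
match/insert/delete state graph, implemented in C++ in this package
(no external search binary is invoked anywhere, including in tests).
Local entry into match state k carries probability
`2(M-k+1)/(M(M+1))` (the standard local-entry distribution); exit from
any match state is free (uniform local exit). Scores are log-odds
against an i.i.d. background null, reported in bits. Per-column
posteriors come from forward–backward over the same graph; the forward
and backward total log-likelihoods agree to 1e-6 by construction (a
property test enforces this), and the Viterbi score never exceeds the
forward score.

## E-values

E-values are calibrated per profile (`calibrateEvalues`): Viterbi bit
scores of `nRandom = 1000` i.i.d. background-composition sequences are
fitted to a Gumbel law by maximum likelihood (scale via a one-
dimensional root solve, location in closed form), and
`E(s, D) = D exp(-lambda (s - mu))` for a database of D sequences. The
calibration seed is recorded in the profile. The effective database
size is the number of proteins actually searched; no further
correction is applied. A sanity test checks that among 1000 fresh
random sequences the number with E <= 1 stays in [0, 5].

## Hit filters

Hits are kept iff E-value <= 1e-5 AND profile start <= 10 AND profile
coverage >= 0.90. All three boundaries are **inclusive**, and coverage
is defined on the profile (match-state) span,
`(profile_end - profile_start + 1)/M`, pairing it with the
profile-start rule. Filtering is idempotent and order preserving.

## Column filtering

The hit alignment columns are filtered by consensus posterior:
a column is retained iff the mean forward–backward posterior over the
hits spanning it is >= 0.85. The engine computes real posteriors, so
the threshold operationalises the usual "high consensus posterior"
annotation glyphs; 0.85 is configurable. If no column qualifies the
single best column is kept, so the mask is never empty.

# Clustering and classification

**Identity.** Pairwise identity between two hits is computed on the
retained-column alignment as identical columns divided by mutually
non-gap columns (0 when no such column exists). The denominator choice
is recorded per pair in the identity matrix for audit.

**Clusters** are connected components of the graph with an edge where
identity **strictly exceeds** 0.90 (the Results phrasing "more than
90%"); an inclusive `>=` switch exists because the Methods phrasing
("cutoff of 90%") is ambiguous. Components are ordered by size then by
lexicographically smallest member, so output is deterministic.

**Family transfer.** Each cluster representative (its
lexicographically smallest member) is aligned to every bait with
Smith–Waterman (BLOSUM62, gap open 11 / extend 1, via Biostrings). The
best bait is the highest-scoring alignment — blastp best-hit semantics
— with identity, coverage and bait order as tie-breaks. Ranking by raw
local identity instead is pathological (short spurious segments reach
high identity) and was rejected. Identity < 40% to the best bait sets
the "-like" suffix.

**Naming.** Cluster identifiers are
`subfamily_scope_counter_` (e.g. `SHP/Rgg_Sthermo_6_`): the scope token
names the species when the cluster is species specific and the
salivarius group (`gp_sali`) when it spans at least two species;
the counter runs per (family, scope) in input order, so names are a
pure function of the deterministic input ordering.

**Context genes.** CDSs overlapping 2-kbp windows on both sides of a
regulator are clustered by all-against-all Smith–Waterman with an edge
requiring a Karlin–Altschul E-value <= 1e-3 (gapped BLOSUM62 constants
lambda = 0.267, K = 0.041) and an aligned span covering >= 70% of
**both** sequences.

# Short-CDS discovery

The detector is a two-class per-ORF posterior, the directly testable
equivalent of a genome-wide coding HMM. Candidate ORFs run from an
ATG/GTG/TTG start to the first in-frame stop, protein length 7–60 aa
inclusive, enumerated on the forward sequence and on the reverse
complement with exactly the same model, so strand symmetry is exact to
machine precision (the mirror test asserts equality at 1e-9).

The coding model is a 61-sense-codon usage table (a positional 3 x 4
nucleotide mode is available); the background is an order-2 Markov
chain over nucleotides; both are Laplace smoothed and trained on the
annotated CDSs / full sequence of five training genomes. The
confidence of a span is

`conf = pi L_C / (pi L_C + (1 - pi) L_B)`

computed in log space, with coding prior `pi = 0.5` so the 0.01
acceptance threshold is purely likelihood-ratio driven. A trailing
stop codon is excluded from both likelihoods. Nested ORFs sharing a
stop are deduplicated keeping the longest (the source texts are silent;
longest-ORF is the common convention). Neighborhood restriction keeps
candidates whose span intersects the half-open window
`[hit_start - 300, hit_end + 300)`, clamped at the contig start.

# AIP annotation

Five SHP features are scored on each candidate peptide: length 20–26
aa; an N-terminal Lys within the first three residues (published
precursors have K at positions 2–3, with two outliers caught by the
other features); a C-terminal stretch of >= 5 hydrophobic residues
(Kyte–Doolittle > 0, Gly permitted, because published mature forms end
in G-rich tails); a C-terminal Gly; and a central acidic residue (D/E
in the C-terminal half, not the final residue). A candidate with no
seed support is called SHP at score >= 3 of 5 — the threshold at which
every published SHP precursor passes while random peptides rarely do
(a null simulation in the test suite checks this).

Known-AIP transfer uses best global-alignment identity against a seed
set (default threshold 40%). The mature form is predicted as the
suffix starting at the **last** D/E in the **C-terminal half** of the
precursor: several precursors carry acidic residues near the N-terminus
(position 2 of `MEKVSKILPILILVMDIIIIVGG`) that are not cleavage sites,
and the C-terminal-half rule reproduces every published D/E-initial
mature form. Precursors without such a residue return `NA` and are
flagged; curated exceptions (e.g. a Cys-initial mature form) are
handled by an override table, never by bending the rule.

Orientation relative to the regulator is computed from forward-axis
geometry (divergent / convergent / co_upstream / co_downstream) and is
invariant under reverse-complementing the contig.

# Repertoire analytics

The repertoire matrix is binary strain x cluster presence/absence
(paralogs collapse to 1). Profile distance is the Hamming count of
differing clusters; the mean pairwise difference averages **unordered
distinct pairs** (sampling two strains without replacement); the
with-replacement variant, differing by (n-1)/n, is available. Heatmap
ordering uses average-linkage agglomeration on Hamming distances
(the linkage is not named in the source material; average linkage is
the common choice for binary pangenome profiles) with deterministic
tie-breaking via the sorted strain ordering. Cluster-representative
trees use neighbor joining on (1 - identity) distances with negative
branch lengths clamped at zero, followed by midpoint rooting — a
documented stand-in for approximate-ML reconstruction with resampling
support, which is out of scope.

# Peptide chemistry

Residue monoisotopic masses are derived from elemental compositions
and the monoisotopic atomic masses (H 1.0078250319, C 12, N
14.0030740052, O 15.9949146221, S 31.97207069; proton 1.00727646688),
which doubles as the formula-counting oracle in tests. Crosslink
deltas are encoded elementally: one C–C crosslink loses H2
(-2.01565 Da); two crosslinks lose H4 (-4.03130 Da); the
sactipeptide-type C–S crosslink plus Arg-to-N-methyl-ornithine
conversion loses N2H2 (-30.02180 Da). Report rounding follows print
precision: GRAVY 2 dp, deltas 5 dp, m/z 4 dp. Carbamidomethylation
(+57.02146 Da) is available as a named modification for alkylated
Cys-initial peptides, off by default.

One published GRAVY value (1.91 for `EGIIVIVVG`) is inconsistent with
the Kyte–Doolittle mean of that string (2.42) and exactly equals the
value for `EGIIVIGVG`; it is treated as a suspected transcription
erratum and excluded from the asserted set of seven.

# The synthetic world

`syntheticConfig()` defaults define the stated world of the acceptance
tests:

* 20 genomes (7 + 7 + 6 over the three salivarius-group species), one
  200-kbp contig each; 110 ordinary genes per genome (120–400 aa,
  codons i.i.d. from the usage table). Real streptococcal genomes are
  ~85% coding; the reduced density keeps desk-scale runtimes while
  leaving realistic intergenic background for decoys.
* Background: order-2 Markov chain at ~39% GC with mild
  autocorrelation. Codon usage: Robinson–Robinson amino-acid marginals
  with A/T-biased wobble, mimicking a low-GC streptococcus. The
  coupling between the generator's codon usage and the detector's
  coding model is intentional and is exactly what the
  parameter-recovery tests measure.
* 33 baits drawn as indel-free mutants (identity 0.75–0.95) of four
  family prototypes that themselves descend from one ancestor at ~0.6
  identity — the shared TPR/HTH architecture of the superfamily. With
  unrelated prototypes a single generic profile cannot cover minority
  families end to end, and the prescribed 100%-recall property would be
  ill-posed.
* 5 regulator clusters: centres at 0.85 identity to their source bait
  (every planted homolog therefore stays >= 60% identical to a bait);
  between-centre identity <= 0.70 enforced by rejection sampling.
  `withinClusterIdentity = 0.95` is the target **pairwise** identity
  among members, so members are drawn at (1 + 0.95)/2 to the centre;
  a member-to-centre reading would put pairwise identities at ~0.90,
  exactly on the clustering cutoff.
* AIP genes from five published SHP precursor templates planted
  verbatim within 300 bp of 80% of regulator loci, in per-cluster
  orientations; each planted AIP is preceded by an in-frame stop codon
  so its span is exactly the longest ORF for its stop, making
  manifest-coordinate recovery well defined under the keep-longest
  dedup rule. A rejection guard re-assembles a genome if background
  accidentally spells a template in any reading frame.
* Decoy short ORFs at 0.1 per kbp (random peptides back-translated
  with uniform synonymous codons), and a three-protein shared context
  pool planted at regulator flanks.

Everything is a pure function of `rngSeed`: reruns are bit identical.

**What the generator does not emulate** — and hence what a green test
does not establish: insertions/deletions and alignment uncertainty
(baits are indel-free, so the columnwise alignment is trivially
correct); site-rate heterogeneity and realistic phylogenetic
covariance; horizontal transfer; genome fragmentation into many
contigs; pseudogenes and partial CDSs; ribosome-binding sites and
operon structure; real codon-usage variation among genomes. Recovery
results on this world bound the pipeline's correctness, not its
sensitivity on real RefSeq data.

# Numerical choices and degenerate inputs

* Probability rows are validated to sum to 1 within 1e-9.
* Forward/backward agreement is asserted at 1e-6; strand symmetry and
  midpoint balance at 1e-9.
* Ties in clustering order resolve by size then lexicographic member;
  naming counters are per (family, scope) in input order.
* Codons containing N translate to X; X scores 0 log-odds in every
  emitting state of the profile.
* An empty proteome yields an empty hit table; a hitless corpus stops
  the pipeline after filtering; a regulator feature missing from the
  annotation is skipped in AIP annotation.
* The retained-column mask is never empty; `predictMatureForm`
  requires length >= 8 and returns `NA` rather than guessing.

# Reproducing the full-scale study

The corpus-scale numbers of the original survey (thousands of hits
across hundreds of RefSeq genomes) require downloading the RefSeq
assemblies and the authors' curated bait alignment; the pipeline
supports that path — `readGenBank` on `_genomic.gbff` files,
`readBaitAlignment` on the curated alignment, then `mineCorpus` — but
no test or script depends on network access, and desk-scale acceptance
rests entirely on the synthetic world above.
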