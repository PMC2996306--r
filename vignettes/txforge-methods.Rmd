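---
title: "txForge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{txForge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txForge)
```

# Scope

txForge curates a de novo transcriptome for an organism without a reference
genome, starting from short paired-end RNA-seq reads, and then exploits the
curated contig set for polymorphism, expression and protein-divergence
analysis. The workflow is: read QC → iterative multi-k de Bruijn assembly →
target-based contig clustering (conspecific ESTs, then heterospecific
peptides) → ORF- and homology-based contig validation → reciprocal best-hit
(RBH) 1:1 orthology → SND calling and depth-corrected nucleotide diversity →
RPKM expression → divergence binning and functional-category enrichment.
Every stage is exercisable end to end on synthetic data with known ground
truth; no external downloads or binaries are required.

# Read QC

A read is removed when more than 33% of its bases are `N` or more than 34%
have Phred quality below 20 (a Q20 base has a 1% expected error rate:
`phredErrorRate(20) == 0.01`). Suspected poly-A tails are removed by
discarding reads with strictly more than 33% adenine. All three boundaries
are strict ("more than"); fractions are computed over the full read length
including Ns, case-insensitively. Only adenine is counted by default — a
reverse-strand poly-T filter exists behind `alsoT = TRUE` but is off,
because cDNA poly-A contamination is what the filter targets. Mates are
filtered independently; `dropPairs = TRUE` discards a pair when either mate
fails. Longer cycles can be cut to a fixed length (e.g. 87 → 75 bp) with
`trimTail()`, which never pads shorter reads.

# Iterative multi-k assembly

RNA-seq coverage is extremely heterogeneous across transcripts, and a
single de Bruijn hash length k cannot serve both abundant and rare
transcripts: high-k graphs resolve repeats in well-covered transcripts but
fragment poorly covered ones, low-k graphs do the opposite. The package
therefore runs *exploratory* unitig assemblies at k = 21, 25, 31, 35, 41,
49 and 59, re-assembles the reads left unused by the k = 21, 35, 49 and 59
runs at k = 57, k-merises **all** resulting contigs in *summary* assemblies
at k = 29, 39 and 49, and re-assembles those outputs in a final summary
assembly at k = 39. All hash lengths are odd, so a k-mer can never equal
its own reverse complement and the bidirected graph stays unambiguous.

The unitig assembler is deliberately minimal: canonical k-mer counting, a
node-centric graph with implicit (k-1)-overlap edges, and maximal
non-branching path extraction with deterministic (lexicographic) output
order. There is no bubble popping and no paired-end scaffolding — ambiguous
`N` runs introduced by distance scaffolding produce edge effects in
downstream short-read mapping, which is exactly what the curation pipeline
tries to avoid. The `Assembler` contract (reads + k → contigs) is a single
function boundary (`assembleOnce()` internally), so an external assembler
can stand in without touching the orchestration.

Coverage cutoffs: read-stage graphs drop k-mers seen once
(`minKmerCoverage = 2`), which removes the vast majority of isolated
sequencing-error k-mers at typical error rates; summary stages keep
everything (`summaryKmerCoverage = 1`) because each input contig is a
single observation and any higher cutoff would delete uniquely assembled
contigs. Sequences shorter than a stage's k are skipped at that stage with
a logged warning.

# Target-based clustering

Fragmented contigs that belong to one transcription unit are joined around
an external *target* they both match.

**EST stage.** ESTs are first collapsed to unique sequences (exact
duplicates and substrings on either strand removed, longest kept). Contigs
are matched to ESTs by nucleotide local search at E ≤ 1e-6; per EST group,
(1) a contig-EST match must have an alignment score strictly greater than
50 + 3 × (length of the shorter sequence); (2) local-search scores are
divided by the group maximum and contigs below 0.7 are discarded; (3) if
more than one contig remains, the pairwise alignment scores against the
EST are renormalised and again cut at 0.7; (4) the surviving contigs'
sequence overhanging the EST's edges is attached: the output is
(longest left overhang) + EST + (longest right overhang), and the
survivors are consumed.

A design point worth stating explicitly: contig-EST alignments here are
*ends-free* (end gaps cost nothing). With end gaps penalised, the absolute
rule in (1) cannot be satisfied by any partial contig-EST overlap — the
score of the overlapping region is eaten by the end-gap penalties — and
partial overlap is precisely the situation clustering exists to fix. Under
the package's nucleotide scale (match +5, mismatch −4, gap −10/−1), rule
(1) effectively demands a clean overlap covering more than
(50 + 3L)/5 ≈ 10 + 0.6 L positions of the shorter sequence, which is a
sensible "most of the shorter sequence must align" criterion. The 0.7
normalised-score cutoffs are strict at the boundary in the discarding
direction (a member at exactly 0.7 survives).

**Peptide stage.** Contigs not consumed by the EST stage are matched to a
heterospecific predicted peptide set by translated search, assigned to
their single best-scoring peptide (consumption must be exclusive), and
filtered at the same normalised 0.7. Groups of exactly two survivors are
merged when their ends-free alignment has a normalised score strictly
above 90; if their peptide HSPs do not overlap they are instead bridged
with an `N` run of 3 nt per missing residue between the HSPs (floor of one
N when HSPs abut). In groups of three or more, all pairs are aligned,
pairs scoring strictly above 80 are marked joinable, and transitively
connected members are merged in peptide-coordinate order; unconnected
members stay separate. Disagreeing columns in a merge take the base of the
higher-scoring contig (ties: first by id, logged). Contig orientation is
normalised to the target strand/frame before any join; groups with
ambiguous orientation are logged and left unjoined.

The clustering thresholds live on two different scales by design: the
"50 + 3L" rule is an absolute score (3L cannot be satisfied on a 0–100
scale), while the >80/>90 rules are percent-identity-like normalised
scores over non-gap columns (absolute raw scores of 80–90 would be
trivially exceeded by any decent overlap).

# Validation and orthology

For every contig the best *type A* ORF (Methionine to stop) and best
*type B* ORF (merely stop-free) are extracted across all six frames; ties
break by frame order +1, +2, +3, −1, −2, −3, then leftmost. The type A ORF
is kept unless the type B ORF extends upstream of it all the way to the
contig's 5' boundary in its frame — the signature of a start codon
truncated off the contig — or no type A exists. Codons containing N
translate to `X` and never count as stops; runs of ≥ 10 Ns (scaffold gaps)
split a contig into independently scanned segments. Contigs whose selected
ORF is shorter than 50 aa are discarded, and the final set additionally
requires at least one evidence tag — a match at E ≤ 1e-6 (uniform across
all sources) to a proteome or domain database. The per-source membership
counts and the "core" count of contigs hit in all four proteome sources
are tallied. `n50()` reports the largest L such that contigs of length ≥ L
hold at least half of the assembled bases.

1:1 orthologues are assigned by reciprocal best hits: a one-directional
best hit is declared only when a query has a single hit or the
second-best/best score ratio is strictly below 0.7 (exact ties therefore
block declaration); per-query scores are single best HSP scores, the
conservative reading when HSPs could be summed. Reference peptides shorter
than 50 aa are removed before either direction. The resulting pair set is
a partial bijection by construction.

# SND calling and diversity

A *short nucleotide discrepancy* (SND; SNP or short indel) is called at a
pileup site when: reads contribute only at mapping quality ≥ 20 (enforced
at pileup parsing; the classic text dialect carries an optional per-read
MAPQ column, and a per-file constant is assumed otherwise, since the
minimal dialect cannot represent per-read MAPQ); the site is covered by at
least 6 reads; the alternative allele is observed at least t(d) times,
with t(d) = 2 for depth ≤ 80 and max(2, ⌈0.025 d⌉) above (errors are
expected to be singletons but accumulate linearly with depth); and exactly
one alternative allele reaches t(d). Indel alleles compete with SNP
alleles under the same threshold, and each distinct indel string is its
own allele.

Raw per-contig diversity is the SND count divided by the *callable length*
(positions at depth ≥ 6). Because a genuinely polymorphic site can fail to
be called when too few alternative reads are sampled, raw diversity
underestimates the true rate at low coverage. The correction divides by a
detection probability Φ(d) = P(Binom(d, 0.5) ≥ t(d)) — the chance that a
biallelic site with alleles at equal pool frequency yields enough
alternative reads at depth d — evaluated at the contig's median depth over
callable positions (rounded half up). This binomial model is the package's
own read-depth ascertainment correction, stated as such; a user-supplied
Φ(d) can be substituted through the `phi` hook of `detectProb()` and
`contigDiversity()`. On synthetic pileups with planted heterozygosity
π₀ = 0.01 at uniform 10× depth (1,000 contigs × 1 kb), mean adjusted
diversity recovers π₀ within Monte-Carlo error while the raw value
underestimates it — the test suite and acceptance script recompute this.

Expression is summarised as RPKM = c·10⁹/(N·L); when N equals the summed
counts, Σ RPKM·L(kb) = 10⁶ exactly, which the tests assert as an algebraic
conservation check. Read mapping itself is out of scope: alignments enter
as pileups, and the synthetic generator produces them.

# Divergence and enrichment

Protein divergence of an orthologous pair is the proportion of alignment
columns that differ (gap columns count as differences by default; a
gap-excluded mode exists), with protein distance √p. Pairs below 30%
identity are excluded before analysis — automated alignment is unreliable
at that divergence and fabricates mismatches. Divergence is binned
Low/Intermediate/High either at fixed cutoffs (≤ 0.058 / ≥ 0.138, the
package's reference values for mosquito-scale interspecific comparisons)
or at empirical terciles: the Low cutoff is the ⌊n/3⌋-th smallest value
and the High cutoff the (n − ⌊n/3⌋ + 1)-th, so distinct values split
n/3 ± 1 per bin and exactly n/3 when 3 | n.

Group contrasts (e.g. immune-annotated pairs vs all pairs) use a two-sided
Mann-Whitney U test — exact by enumeration when the product of group sizes
is ≤ 10⁴ and tie-free, tie-corrected normal approximation otherwise.
Category enrichment tests each functional category with ≥ 15 annotated
records by a χ² goodness-of-fit (df = 2) of its Low/Intermediate/High
counts against expected proportions; the default expectation is the global
bin proportions of the full record set, which under tercile binning are
equal thirds — making the two natural phrasings of "expected" coincide —
with `expected = "equal"` forcing exact thirds. Significance uses a
Bonferroni-adjusted per-test level α/m with m the number of categories
actually tested; multi-annotated records count in every category, and
annotation families (e.g. component/function/process) should be analysed
as separate calls, each with its own m.

# Synthetic data: what it does and does not emulate

The generators produce random CDS transcripts (ATG + uniform sense codons
+ stop; expected GC is 94/183 ≈ 0.514 because the excluded stop codons are
AT-rich), diverged orthologous peptide sets (per-site substitution at a
chosen rate, per-family overridable so one "immune-like" block can be
elevated), transcript fragments with known intervals, paired reads with
planted biallelic sites at pool frequency 0.5 and uniform per-base errors,
pileups (aggregated from reads, or simulated directly per site for
large-scale calibration), multinomial expression counts and
block-structured category labels. Everything is a pure function of its
arguments including the seed.

Read tiling has two modes. `"uniform"` draws fragment starts at random,
like shotgun sequencing. `"even"` places fragments (insert = read length,
both mates covering the fragment from opposite strands) on an even grid
that always includes both transcript termini, guaranteeing ≥ 2
observations of every position. The even mode exists because exact
end-to-end reconstruction is the property of interest in the assembler
tests, and under uniform starts the expected terminal k-mer multiplicity
at 30× / 75 bp is below the graph's coverage cutoff of 2 — end loss there
is a property of shotgun sampling, not of the assembler.

What passing tests on these fixtures do **not** show: robustness to real
UTRs, isoforms, codon bias, coverage biases, chimeric reads or realistic
quality-score decay; none of these are modelled. The fixtures certify the
algorithmic rules, not field performance.

# Numerical and interface choices

* Internal coordinates are 0-based half-open (ORF calls); pileups and
  tabular hits convert to/from 1-based inclusive only at format
  boundaries. Minus-strand tabular hits are normalised to start ≤ end with
  the orientation kept in a flag.
* Alignment scales: nucleotide +5/−4 with affine gaps −10/−1 (first gapped
  position costs the opening penalty); protein BLOSUM62 with −11/−1.
  Karlin-Altschul constants (λ = 1.28, K = 0.46 nucleotide; λ = 0.267,
  K = 0.041 protein) are stock approximations; all decisions depend only
  on e-value ordering and the uniform 1e-6 threshold, never on absolute
  e-values. The dynamic programming itself runs on the Biostrings
  alignment engine; seeding (11-nt / 3-aa exact words) and e-values are
  computed here.
* FASTQ is Sanger Phred+33 only; quality characters far beyond `J` warn
  of probable Phred+64 input rather than being silently reinterpreted.
* The pipeline driver (`runPipeline()`, `exec/txforge`) stores content
  hashes of every stage's inputs, outputs and parameters in a manifest;
  unchanged stages are skipped and a corrupted intermediate re-runs its
  stage and everything downstream. All intermediates are plain standard
  formats so any stage can be run standalone.
* Problem sizes in the test suite and acceptance script — 2–6 transcripts
  of 0.3–1 kb for assembly/clustering/orthology, 1,000 × 1 kb site-level
  pileups for diversity calibration, 300 records for tercile checks —
  are chosen so each property is measured with comfortable statistical
  margin while the whole suite stays quick to run routinely.

# Known limitations

The assembler resolves no repeats beyond unitig boundaries and performs no
error correction; the local search implements none of the edge-effect or
sum-statistic corrections of mature search tools, so its e-values are
comparable only within a run; the detection-probability correction assumes
biallelic sites at pool frequency 0.5 (a site-frequency-spectrum knob
exists only in the generator, not the correction); and enrichment treats
annotation labels as exchangeable, with no ontology structure.
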