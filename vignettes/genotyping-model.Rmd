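---
title: "Breakpoint-graph SV genotyping: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint-graph SV genotyping: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(graphsv)
```

This vignette is the package's own account of its method: the models and
their assumptions, the parameters that matter, what the simulator does and
does not emulate, and the design choices made where the design was
genuinely open. The README shows the end-to-end workflow; here we explain
why it is built the way it is.

## Coordinates and SV encoding

VCF input and output are 1-based; internally all coordinates are also
1-based inclusive, the native convention of R and of the Bioconductor
string/range infrastructure this package builds on (`substr`, `IRanges`),
which keeps every slicing operation free of `+1` adjustments. A site's
`begin` is the last reference base before the event and `end` the last base
of the event, so the affected span is `(begin, end]` — exactly the VCF
symbolic-allele convention (`POS`, `END`), which makes round-tripping
through VCF trivially correct.

Each SV contributes one or two **breakpoints**: the positions where its
haplotype diverges from or converges back to the reference. The graph
stores, per breakpoint, at most `l_bp` bases of the alternative haplotype
adjacent to the junction. The default `l_bp = 152` matches common short
read lengths: a read cannot span more alternative sequence than its own
length, so longer breakpoint sequences add graph size without adding
signal; the parameter is exposed for cohorts with other read lengths. The
per-type splicing rules (deletion removes `(begin, end]`; insertion adds
sequence at `begin`; tandem duplication repeats its span, giving a single
junction where the span's end meets its own start; inversion
reverse-complements the span in place, giving two junctions) are stated
operationally in `make_breakpoints()` and verified in the tests against an
independent string-splice oracle. Insertions with only a left- or
right-assembled fragment yield a single breakpoint; sites with no
derivable junction sequence are rejected, and imprecise
deletions/duplications without alternative sequence can still be genotyped
by the coverage model alone.

Variants whose reference spans overlap cannot be serialized into one DAG;
the later-added allele is demoted to an independent biallelic overlay
record genotyped against the reference backbone. This is a deliberate
simplification: nested variation inside SVs is out of scope for an acyclic
local graph.

Windows: small-variant regions tile at 50 kb; SV regions are 1.2 Mb with a
200 kb overlap, so both breakpoints of almost any SV fall into one graph.
Sites genotyped in two overlapping windows keep the higher-GQ call, ties
going to the earlier window.

## Read support and the realignment engine

A read supports an allele when its best local alignment overlaps that
allele; equally good alignments to both alleles support both. The original
formulation relies on a k-mer-indexed graph aligner; this package instead
scores reads by semi-global alignment (whole read against a window of the
candidate haplotype; match 1, mismatch −2, gap open 5, gap extend 1,
both orientations) against junction-centered contexts of the reference and
the full local alternative haplotype. Contexts keep `read_flank = 161`
bases on each side of a junction — just over one read length — so a
junction-crossing read always fits inside the context it belongs to.

Which reads are aligned at all is decided from their linear placements
first. Only reads that could place at least `min_anchor = 16` bases on
both sides of a junction (taking soft-clipped bases and the unknown
placement of unmapped mates into account) are realigned. The informative
read multiset for a site is the reads overlapping its breakpoints; placed
reads near a site that cannot cross any junction are recorded as
supporting both alleles, a tie that multiplies every genotype's
likelihood by one and so leaves the call untouched. This classification
is not an optimization only. Scoring non-junction reads against junction
contexts either loses them (they fit no context) or actively misleads:
for tandem duplications shorter than the context, reference reads match
the borrowed span sequence and masquerade as SV support, and counting
deletion-interior reads as reference evidence swamps the handful of
junction-crossing reads that carry the heterozygous signal. Deciding
support by junction-crossing capability is the graph semantics, computed
cheaply from placements.

A read whose best score falls below `min_score_frac = 0.65` of the perfect
score supports neither allele. The cutoff is this package's configuration
value — published descriptions of the original tool do not state one — and
it is deliberately loose: at a 1% base error rate a full-length read loses
about 3 points per error, so even ten errors leave a read far above the
threshold, while random sequence falls far below it. Reads supporting
neither allele enter the likelihood with the penalty term below, which
cancels across genotypes and therefore cannot flip a call.

## Genotype likelihoods

For a biallelic site with alleles x, y and read multiset R,

$$L(R \mid G_{xy}) = \prod_{r \in R} L(r \mid G_{xy}), \qquad
L(r \mid G_{xy}) = \begin{cases}
1 & \text{both } x \text{ and } y \text{ supported by } r\\
1/2 & \text{exactly one supported}\\
\varepsilon_r & \text{neither supported}
\end{cases}$$

with $\varepsilon_r = 2^{-8}$ for a paired read whose mate also mapped onto
the graph and $2^{-4}$ otherwise: a confidently anchored pair that
contradicts both alleles is stronger evidence against a genotype than a
stray single read. Products are computed in log space; the tests check
them against a literal product oracle to 1e−12 relative tolerance for all
support patterns up to 12 reads. An empty read set leaves all three
genotypes equally likely (GQ 0). Multi-allelic sites are genotyped as two
or more biallelic sites — two distinct SV events at one position in one
sample are not expected — and read support for the other alternatives maps
to "neither" in each biallelic view.

The **coverage model** applies to deletions and duplications (including
inverted duplications) spanning at least 100 bp; below that, fewer than
five positions are sampled at the 20 bp step and the median is unstable.
Coverage is read every 20 bp on a fixed grid; `c_in` is the lower median
inside the span and `c_out` the lower median over two 1000 bp flanking
windows — long enough for a stable estimate, short enough that, with the
simulator's 2 kb minimum spacing and in real data at typical SV densities,
they rarely overlap a neighbouring SV (grid positions inside other SVs of
the window are excluded from the flank medians regardless). Lower medians
keep the pseudo-read counts integral. For a deletion, the decrease
`max(0, c_out − c_in)` supports the SV and `c_in` the reference; for a
duplication the increase supports the SV and — our interpretation, since
only the deletion case is fully specified in the literature — the baseline
`c_out` supports the reference. Pseudo-reads are unambiguous and unpaired,
so $\varepsilon = 2^{-4}$.

Each model calls its maximum-likelihood genotype with
GQ = round(10·log10 of the best/second-best ratio), capped at 99 — a
conventional phred-scaled definition, chosen here because the original
"genotyping quality" is not given a formula. The aggregated call is the
call of the model with the higher GQ, ties going to the breakpoint model,
which exists for every SV type.

Cohort post-processing drops sites at which no sample has a non-reference
genotype. A configurable high-confidence flag (median GQ ≥ 20, call rate
≥ 0.9, at least one carrier by default) is additionally annotated; its
thresholds are this package's convention, exposed as parameters rather
than claimed from elsewhere.

## Merging discovery callsets

Sites from many single-sample VCFs are grouped by a single left-to-right
sweep over (contig, begin)-sorted input: a site joins a group if it is of
the same type, within 100 bp in size and 200 bp at both begin and end of
*some* member (growth is transitive), and no member lies more than 10 kb
away — the cap that keeps groups in repetitive regions from growing
without bound. Whether the original merging iterates to a fixpoint or
sweeps once is not documented; the single sorted sweep is deterministic,
linear after sorting, and its partition/idempotence behaviour is tested.
When several open groups qualify, the site joins the one whose current
modal endpoint pair is nearest in |Δbegin| + |Δend| — a deterministic,
locality-preserving tie-break of our own choosing. The representative is a
member with the most common (begin, end) pair, ties to the smallest
coordinates, and its INFO string is carried to the output verbatim, with
genotype columns never consulted and non-PASS records included. Insertions
carry `end = begin`, so their position criterion is a single-position
check plus the size criterion on SVLEN.

## Evaluation machinery

Truth extraction decomposes multi-allelic records, left-normalizes each
ref/alt pair, keeps alleles with a length difference of at least 50 bp
(deletion if the reference allele is longer, insertion otherwise), and
restricts to high-confidence regions expanded by 25 bp so that imprecise
breakpoints at region edges are not unfairly lost. Matching is greedy
one-to-one, nearest pair first by max(Δbegin, Δend), requiring the type to
match and both breakpoint distances to be within the precision threshold;
greedy rather than optimal bipartite matching because at 50 bp thresholds
and SV-scale spacing the two differ negligibly while greedy is simple and
deterministic. One truth SV validates at most one call; recall is matched
truth over truth, FDR unmatched calls over calls. Size bins (50–99,
100–249, 250–499, 500–999, 1000–1999, ≥ 2000 bp) pin the conventional
extremes; interior cuts are our convention. DUP-vs-INS matching is off by
default but available, since callers disagree on the representation of
tandem duplications.

Trio statistics: a Mendelian error is an offspring genotype impossible
under biallelic transmission given the parents. The transmission rate
counts, per heterozygous parent, whether the SV allele reached the
offspring, but only where the received allele is uniquely determined by
the three genotypes — het × het with a het child is ambiguous and skipped
rather than given fractional credit. For germline alleles the expected
rate is 50%; the per-site histogram should be symmetric about it, and
systematic deficits flag false positives or somatic events.

## The simulator: what it emulates, what it does not

The simulator defines the package's study conditions: a uniform-random
contig, SVs of all four types with sizes uniform on 100–1000 bp planted at
least 2 kb apart (so the 1000 bp coverage flanks never collide), founder
allele frequency 0.25 — segregating SVs are mostly rare, and this keeps
all three genotype classes present while making homozygous-alternate
duplications (see below) a minority — Mendelian transmission with each
site transmitted independently (free recombination, so per-site
transmission statistics are i.i.d. fair coin flips), 30× coverage, 151 bp
reads, ~450 ± 60 bp fragments, 1% uniform base error, constant Q30-style
qualities (the models are quality-blind). Reads receive naive linear
placements by projecting fragments through the haplotype's block map:
bases crossing a planted junction are soft-clipped, reads wholly inside an
insertion are emitted unmapped at their mate's position — exercising the
extraction rule for clipped and unmapped-with-mapped-mate reads — and
everything is written as sorted, indexed BAM. Fixture scale (a 250 kb
contig with 20 SVs per type and one sequenced trio; a 600 kb, 200-site,
4-family/48-trio pedigree at the genotype level) keeps a full run around a
minute while giving a few hundred genotypes per run.

Real data differ in ways the simulator deliberately ignores: no repeats or
segmental duplications (the main source of ambiguous breakpoint homology),
no GC or coverage bias, no indel sequencing errors, no mapping-quality
structure, no somatic events. Passing recovery tests therefore
demonstrates the correctness of the machinery under its own model, not
cohort-level accuracy on a real genome.

## Numerical and degenerate-input choices

Likelihoods live in natural-log space and are exact products (no
underflow at realistic depths; the oracle tests pin equality). Support
ties require exact score equality (a 1e−9 slack absorbs floating-point
noise only). Breakpoint sequences truncated below 16 bp at contig edges
are dropped with a warning; an SV losing all its breakpoints is rejected.
Coverage medians over empty sample sets make the coverage model signal
"not applicable" (a typed condition), and the caller falls back to the
breakpoint model, as it does for insertions and inversions. Empty windows,
empty cohorts and empty site lists all produce valid empty outputs.

## Known limitations

Homozygous tandem duplications are intrinsically ambiguous to both models:
the duplicated haplotype still contains the reference junction sequence,
so breakpoint support is split roughly 1:1, and the coverage increase at
homozygosity equals `c_out`, which the pseudo-read construction also reads
as heterozygous-like. These sites dominate the residual errors in the
recovery tests (~1–3% of trio genotypes at the default allele frequency).
Read-pair insert-size evidence, which could resolve them, is out of scope,
as are base-quality-aware scoring, phasing, nested variation, and
single-breakpoint (breakend) coverage genotyping. SVs whose breakpoints
fall into different windows are genotyped per breakpoint and merged by
higher GQ; such sites are rare under the 1.2 Mb/200 kb windowing but less
accurate.
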