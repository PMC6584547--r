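---
title: "Methods: HLA class-I genotyping by a variational Bayes read mixture"
author: "hlacall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA class-I genotyping by a variational Bayes read mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlacall)
```

## The problem

The HLA class-I genes (HLA-A, -B, -C on chromosome 6p21.3) are the most
polymorphic loci in the human genome: public registries list tens of
thousands of alleles, and most alleles differ from their closest relatives
at only a handful of positions. Calling a diploid HLA genotype from
whole-genome short reads therefore faces two coupled difficulties: almost
every read aligns well to many alleles at once, and some allele pairs are
*identical* over the exons that most typing assays read (exons 2 and 3,
which encode the peptide-binding domain), so they can only be separated by
variation that lies in introns or flanking regions. Reference panels that
carry full-length genomic allele sequences, rather than exon-only ones,
are what make that separation possible, which is also why augmenting a
base panel with full-length, population-specific alleles improves calling
in that population.

`hlacall` implements this whole workflow as a self-contained toolkit:
nomenclature and panel handling, panel augmentation, read-evidence
scoring, the mixture model, a depth-based diploid caller, concordance
evaluation, and a seeded simulator so every part is testable without
external data or an external mapper.

## The read-mixture model

Let the panel hold alleles $j = 1, \dots, M$ and let fragment
$i = 1, \dots, N$ carry an alignment log-likelihood $\ell_{ij}$ against
allele $j$ (sparse: only alleles the fragment aligns to). The generative
model is

$$\theta \sim \mathrm{Dirichlet}(\alpha_0, \dots, \alpha_0), \qquad
  a_i \mid \theta \sim \mathrm{Categorical}(\theta), \qquad
  r_i \mid a_i = j \sim \exp(\ell_{ij}),$$

i.e. each fragment is drawn from one (unknown) allele of proportion
vector $\theta$. `hla_mixture()` fits the posterior by mean-field
variational Bayes with factorisation $q(z)\,q(\theta)$ and coordinate
updates

$$z_{ij} \propto \exp\{\psi(\alpha_j) - \psi(\textstyle\sum_k \alpha_k)\}
  \, e^{\ell_{ij}}, \qquad
  \alpha_j = \alpha_0 + \textstyle\sum_i z_{ij},$$

iterated until the mean absolute change of $\alpha$ falls below `tol`.
The evidence lower bound is computed each iteration and is non-decreasing
(the suite asserts this to $10^{-8}$ slack). Initialisation is uniform
responsibilities — deterministic, so calls are exactly reproducible; no
random restarts are used because the coordinate updates on this model
behave like a soft winner-take-all and the quantities the caller consumes
(dominant depths) are insensitive to the initial point in all instances
we generate.

An EM mode (`method = "em"`) maximises the observed-data likelihood of
the same mixture. Because $\log \sum_j \theta_j e^{\ell_{ij}}$ is concave
in $\theta$, EM attains the global maximum, which makes it a clean
cross-check: the suite compares it against direct numerical maximisation,
and compares the VB posterior mean against *exact* integration (for two
alleles the marginal likelihood is a polynomial in $\theta_1$, so
posterior moments reduce to Beta functions — no quadrature error).

### Numerical choices

* All per-fragment normalisations subtract the row maximum before
  exponentiating; likelihood ratios across the panel span hundreds of log
  units.
* `alpha0 = 0.2` per allele by default: the true diploid mixture has at
  most two alleles per gene among dozens to hundreds of candidates, so a
  sparsity-favouring prior below 1 is appropriate. It is exposed as an
  argument (and CLI flag) because it is a modelling choice, not a fact.
* `tol = 1e-6` on mean $|\Delta\alpha|$, `max_iter = 1000`; the fits in
  the test suite converge in well under 100 iterations.
* An empty evidence matrix is an error; a gene with no evidence simply
  receives zero depth and fails in the caller.

## Read evidence

Alignment scores use a flat per-base error model: a base is correct with
probability $1-\varepsilon$ and a specific wrong base has probability
$\varepsilon/3$, so an ungapped alignment with $m$ matches and $x$
mismatches scores $m\log(1-\varepsilon) + x\log(\varepsilon/3)$. The
default $\varepsilon = 0.01$ is deliberately flat (base qualities are not
modelled); it only needs to rank alleles per fragment, and mismatch-count
differences dominate any plausible per-base refinement at these
divergences.

`evidence_from_sam()` ingests SAM/BAM against the panel: primary and
secondary alignments are kept (multi-mapping is the point), substitution
counts come from `NM` (minus indel bases) or `MD`, records aligning less
than `min_aligned_frac = 0.9` of the read are dropped to suppress
spurious partial hits within the highly similar HLA cluster, and mates
aligned to the same allele contribute one summed evidence row per
fragment. A fragment with only one aligned mate keeps that mate's
likelihood unpenalised — conservative, and avoids inventing an
insert-size model.

`naive_align()` exists so the package needs no external mapper: exact
k-mer seeds (k = 21) at the start, middle and end of the read propose
diagonals on both strands; fully contained placements are scored by
Hamming distance and the best placement per allele with at most
`max_mismatches = 6` mismatches is kept. Six mismatches on a 100-base
read intentionally retains cross-allele candidates (at 2 % divergence a
wrong allele costs about two mismatches), because the mixture — not the
aligner — is meant to resolve the multi-mapping. It is ungapped by
design; indels are out of scope throughout.

## The diploid caller

Per-allele normalised depth is
$d_j = \sum_i z_{ij}\,b_i / L_j$ (expected aligned bases over allele
length). `call_gene()` first collapses alleles to the reporting
resolution (default 2 fields, the protein-defining level) *summing depths
within a collapsed name* — so 3rd/4th-field variants pool their support
before ranking — then applies a three-way rule with the sample's
genome-wide mean depth $g$:

* fail if the top depth $d_1 < \delta g/2$;
* heterozygous (top two) if $d_2 \ge \tau d_1$ and $d_2 \ge \delta g/2$;
* homozygous otherwise.

Defaults $\tau = 0.4$, $\delta = 0.3$: each heterozygous allele should
carry about half the gene's coverage, so a genuine second allele sits
near $d_2/d_1 \approx 1$ and a mis-attributed twin or noise allele sits
far below; both thresholds are exposed because no printed values exist
for them — the fail condition in particular is this package's own
definition. Ties in the ranking break on the lexicographically smallest
name, so calls are invariant to allele order and to common rescaling of
all depths. `genome_mean_depth` is a required input (from simulator
truth, or supplied by the user); estimating it genome-wide is outside
this package's scope.

## Evaluation conventions

Accuracy is *allele-level*: each sample-gene truth contributes two
slots, a called pair earns the maximum number of matched slots over the
two pairings, and per-gene accuracy is $100\,n_{correct}/n$ rounded
half-up to one decimal. A call slot may hold `"fail"`, which matches
nothing; a whole-gene fail fills both slots. The shipped
`sjs_discordances()` table encodes a published per-type discordance
summary at exactly this granularity, and `build_discordance_dataset()`
expands it into slot-level records so that `accuracy_table()` and
`discordance_table()` recompute the published percentages and round-trip
the counts — an arithmetic, fully deterministic check of the evaluation
machinery.

`feature_identity_groups()` partitions a gene's alleles by identity of
their concatenated exon-2/3 subsequences (G-group-style ambiguity);
`project_to_exon23()` returns everything an exon-2/3-only assay could
report for a genotype, which is how the simulator emulates
hybridisation-style typing, and `ambiguity_report()` annotates
method-vs-method conflicts with whether the conflicting alleles fall in
one group.

## The simulator

`make_panel()` emulates a class-I locus: ~3 kb alleles with 8 exons
(lengths 73, 270, 276, 276, 117, 33, 48, 5 — approximating a class-I
transcript) separated by introns/UTRs that fill the remaining length.
Alleles of a gene derive from a shared ancestral sequence, each mutated
at rate $d/2$ so that two alleles differ at close to
`inter_allele_divergence` (default 0.02) per site. Engineered *twin
pairs* copy all exon subsequences from one allele to its partner, so the
pair is identical across every exon — in particular exons 2+3 — while
still differing in introns. Confining the discriminating variation to
introns is deliberate: it reproduces the situation where an exon-only
reference cannot separate the pair at all, while a full-length panel
can, with no partial signal leaking through non-2/3 exons. Accidental
exon-2/3 collisions between non-twin alleles (probability a fraction of
a percent per gene at the default divergence) are repaired by re-drawing
the colliding allele's exon-2/3 sites; the engineered structure is then
*verified* post hoc via `feature_identity_groups()`, never assumed. All
sampling draws from a single seeded stream in a documented order, so
panels, reads and FASTQ files are bit-reproducible.

`simulate_reads()` draws per-haplotype Poisson read counts with mean
$\mathrm{cov}/2 \cdot L/\mathrm{read\_len}$, uniform positions, unbiased
strands, and i.i.d. substitution errors at `err_rate` with positions
logged — the bookkeeping the evidence tests check against. What it does
*not* emulate: indels, quality-score structure, coverage bias, PCR
duplicates, paired-insert realism beyond a normal fragment length, real
MHC haplotype structure or linkage. Passing tests on this simulator
therefore demonstrate the statistical machinery (multi-mapped read
apportionment, zygosity discrimination, twin resolution), not robustness
to every artefact of real sequencing data.

## Study sizes used by the tests and acceptance script

The simulated study is 3 genes × 20 alleles, 50 diploid samples at 30×
with 0.5 % error for overall recovery, and 20 homozygous-twin samples
for the full-length-vs-exon-only comparison; these sizes give roughly
300 and 120 evaluated allele slots, enough that recovery failures of the
kind the model could plausibly make (twin confusion, zygosity errors)
would be visible, while a full run stays comfortably interactive. The
tiny-instance oracle checks use $N \le 6$, $M \le 3$, where exact
integration and direct optimisation are trivially reliable.

## Known limitations

* Ungapped evidence: indel-containing reads lose their placement or are
  dropped; real data would route through an external mapper via
  `evidence_from_sam()`.
* The caller works on marginal depths, not a joint diploid likelihood
  per gene; an explicit two-allele model could in principle squeeze more
  out of low coverage.
* `genome_mean_depth` must be supplied; there is no genome-wide
  estimator.
* Class II loci (and paralog-rich regions like KIR) raise additional
  copy-number and paralogy issues that this class-I-shaped toolkit does
  not address.
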