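# hlacall

Diploid HLA class-I genotyping from short reads by a variational Bayes
read-mixture model over an allele reference panel.

## The problem

HLA-A, -B and -C are extremely polymorphic and mutually similar, so a
short read from one allele typically aligns well to many alleles of the
panel. Worse, some allele pairs are byte-identical across exons 2 and 3
(the peptide-binding-domain exons that most typing assays read) and
differ only in introns — such pairs can only be separated against a
*full-length* reference panel. `hlacall` is a toolkit for this whole
problem, aimed at people building or evaluating sequence-based HLA typing:

* **Nomenclature & panels** — parse `GENE*XX:YY[:..][N|L|S|C|A|Q][G]`
  names, read/write panel FASTA with a BED-like feature sidecar
  (0-based half-open exon/intron/UTR coordinates), and **augment** a base
  panel with full-length population-specific alleles
  (`merge_panels()`: byte-identical duplicates collapse onto the base
  name, recorded as aliases).
* **Read evidence** — score SAM/BAM alignments (`evidence_from_sam()`,
  NM/MD-aware, keeps secondary alignments, merges mate pairs) or use the
  built-in seed-and-extend aligner (`align_reads()`) so no external
  mapper is needed.
* **Inference** — `hla_mixture()` fits allele proportions
  $\theta \sim \mathrm{Dir}(\alpha_0)$ for the mixture
  $r_i \mid a_i = j \sim e^{\ell_{ij}}$,
  $a_i \sim \mathrm{Cat}(\theta)$ by variational Bayes
  ($z_{ij} \propto e^{\psi(\alpha_j) - \psi(\sum_k \alpha_k)}
  e^{\ell_{ij}}$, $\alpha_j = \alpha_0 + \sum_i z_{ij}$), with an EM
  maximum-likelihood mode as a cross-check, and returns per-allele
  expected counts and normalised depths.
* **Calling** — `call_genotypes()` turns depths into per-gene diploid
  calls at 2-field resolution with an explicit fail state
  (heterozygous iff the second depth is both a fraction `tau` of the
  first and above a minimum tied to half the genome-wide mean depth).
* **Evaluation** — allele-level accuracy tables, discordance listings
  and exon-2/3 ambiguity reports (`accuracy_table()`,
  `discordance_table()`, `ambiguity_report()`,
  `feature_identity_groups()`).
* **Simulation** — `simulate_dataset()` builds seeded synthetic panels
  (8-exon, ~3 kb alleles, engineered exon-identical "twin" pairs that
  differ only in introns) and diploid read sets with full ground truth.

## Worked example

Simulate one 30× diploid sample against a 3-gene × 20-allele panel and
type it:

```r
library(hlacall)
sim <- simulate_dataset(panel_spec(seed = 1), n_samples = 1, seed = 2)
subset(sim$truth, sample == "sim001")
#>   sample gene allele1 allele2
#> 1 sim001    A A*06:01 A*15:01
#> 2 sim001    B B*06:01 B*08:01
#> 3 sim001    C C*17:01 C*20:01

calls <- hla_type(sim$reads[["sim001"]], sim$panel,
                  genome_mean_depth = 30, sample = "sim001")
calls
#> diploid genotype call(s):
#>  sample gene status allele1 allele2 depth1 depth2
#>  sim001    A called A*15:01 A*06:01  14.87  14.40
#>  sim001    B called B*08:01 B*06:01  15.68  14.75
#>  sim001    C called C*20:01 C*17:01  14.58  13.92
```

All six allele calls match the simulated truth; each heterozygous allele
carries close to half the 30× gene coverage (depths ≈ 15), which is what
the caller's `tau`/`delta` thresholds key on. The underlying fit is
attached:

```r
attr(calls, "fit")
#> VB read-mixture fit: 2646 fragments, 60 alleles; 14 iteration(s), converged
#>   top alleles by expected count:
#>     B*08:01        count    470.5  theta 0.1771  depth  15.68
#>     A*15:01        count    446.0  theta 0.1679  depth  14.87
#>     B*06:01        count    442.5  theta 0.1665  depth  14.75
#>     C*20:01        count    437.4  theta 0.1646  depth  14.58
```

The evaluation machinery works from printed discordance counts too: the
shipped SJS summary expands into slot-level records whose accuracy table
reproduces the published per-gene percentages:

```r
ds <- build_discordance_dataset(sjs_discordances())
accuracy_table(ds$calls$v2, ds$truth)
#>   gene   n n_correct accuracy_pct
#> 1    A 228       226         99.1
#> 2    B 228       223         97.8
#> 3    C 228       228        100.0
```

A thin CLI over the same functions lives at `inst/cli/hlacall.R`
(subcommands `simulate`, `build-panel`, `score`, `infer`, `call`,
`evaluate`).

## The methods vignette

`vignettes/hla-read-mixture-methods.Rmd` documents the model and its
assumptions, the evidence and caller parameters (with defaults and
rationale), what the simulator does and does not emulate, numerical
choices, and known limitations.
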