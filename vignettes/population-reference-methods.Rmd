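---
title: "Methods: cohort analyses behind a population genome reference"
author: "popref developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort analyses behind a population genome reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popref)
```

# Scope and problem

Building a genome reference for an under-represented population involves a
set of cohort-level analyses downstream of the heavy lifting (read mapping,
variant calling, assembly): deciding which variants are common in the
cohort, which of those are specific to the population relative to external
reference panels, how the cohort's linkage-disequilibrium (LD) structure
affects the transferability of GWAS results obtained in other ancestries,
which assembly sequence is missing from the reference (non-reference
insertions), how per-individual structural-variant (SV) call sets collapse
into non-redundant events, how a base assembly is complemented from an
alternative assembly and scored for base-level quality (QV), and how phasing
completeness and runs of homozygosity (ROH) summarize the donor. `popref`
implements exactly these downstream steps. Discovery tools (mappers,
callers, assemblers, phasers, ROH detectors) are out of scope; their outputs
are this package's inputs.

Because the motivating cohort data are access-restricted, every input format
has a synthetic generator with the statistical structure the analyses
assume, and each generator writes a ground-truth sidecar consumed by
recovery tests.

# Cohort allele statistics and population-specific variants

For each biallelic site, with $n$ genotyped diploid individuals and alt
allele count $c$, the alternative-allele frequency is $\hat p = c/(2n)$ and
the minor-allele frequency $\mathrm{MAF} = \min(\hat p, 1-\hat p)$.
Multi-allelic records are split into one row per alternative allele before
statistics, matching the per-allele semantics of panel databases. Sites with
$n = 0$ are flagged, never dropped.

*Common* variants satisfy MAF strictly above 5% **and** at least 100
genotyped individuals; both readings of the literal definitions are strict/
inclusive as stated, and boundary cases are tested. The cohort definition is
sometimes phrased on the alternative-allele frequency instead of the MAF;
`select_common(measure = "alt_af")` exposes that reading, with MAF as the
default.

*Population-specific* variants are common variants that every external panel
either fails to detect or reports below 1%. The lookup key is
`(contig, pos, ref, alt)` after splitting; an allele mismatch conservatively
counts as "not detected". Whether the rarity rule should be applied per
panel population or per aggregated panel is not decidable from the source
material; the implementation applies it per panel-table row, which is the
stricter reading when a table carries one row per population.

The cohort's *major allele* at a site is alt when $\hat p > 0.5$ and ref
otherwise; an exact tie keeps the reference allele, so a major-allele
reference never differs from the standard reference without cohort evidence.

# GWAS tag SNPs and LD proxies

Associations are processed per trait. A locus is an associated variant
$\pm 1$ Mb; clustering is greedy by association strength (p-value scale,
smaller is stronger): take the strongest remaining association, absorb
everything within the window, repeat. Strength ties break by lower
(contig, position), which makes the procedure invariant to input order.
"Replicated" is operationalized as associations from at least two distinct
study identifiers within the locus; the threshold is configurable because
the source material does not define replication precisely.

LD is measured as the squared Pearson correlation of genotype dosages
(composite LD). This needs no phase information and is therefore applicable
to any pair of cohorts; haplotype-based $r^2$ via EM is a possible extension
but is deliberately not the default, since phase is not assumed available.
Proxies of a tag are sites within the same $\pm 1$ Mb window (the proxy
search window is taken equal to the locus window; the source is silent on
this, and the window is a flag) with $r^2$ strictly above 0.8. The tag site
itself is excluded by site key — a *distinct* site duplicating the tag's
dosages is a genuine proxy with $r^2 = 1$. Pairs with fewer than 10
pairwise-complete genotypes, and monomorphic candidates, are skipped; a tag
that is absent or monomorphic in a population is reported "not assessable"
rather than silently given zero proxies, because absent tags are themselves
a headline statistic of cross-ancestry comparisons.

Proxy-set comparisons report shared/only percentages both exactly and
rounded half away from zero (so 28.57 prints as ~29, matching the usual
"~29%/~71%" reporting style); an empty side has undefined percentages
(`NA`), never 0 or 100.

# Non-reference insertion regions

Input is per-base read depth of previously-unmapped reads over assembly
contigs, one track per sample. A base qualifies when more than 5 reads
(strict; an `--inclusive` flag switches to $\ge$, since the two phrasings
"more than 5" and "minimal coverage of 5" both occur in the field) cover it
in at least 10 samples; an insertion region is a maximal run of at least
500 bp of qualifying bases. The qualifying sample *set* may vary along the
region — read literally, the criterion is per base — so the reported
support is the minimum per-base count, a conservative summary. Coordinates
are 0-based half-open throughout (BED/BedGraph convention).

# SV collapsing

Within each (sample, type, contig) stratum, intervals sharing at least 1 bp
merge by single linkage; abutting intervals do not merge ("overlapping"
read literally), and calls never merge across samples or types — the
conservative reading that keeps per-type counts meaningful. Translocations
carry breakpoint pairs, not intervals, and merge only on agreement within a
window that defaults to 0 bp (exact). The implementation is a sort-and-sweep;
tests compare it against a pairwise-merge fixpoint oracle and check
idempotence and permutation invariance.

# Meta-assembly gaps, patches, and QV

Gaps are the complement of base-assembly alignment coverage within each
reference contig. Patch candidates are gaps strictly longer than 800 kb with
zero centromere overlap (any overlap excludes; `max_centromere_overlap`
relaxes this). Patches are extracted from the alternative assembly through
colinear alignment blocks mapping equal-length intervals; minus-strand
blocks yield the reverse complement. A gap covered by no block or spanning
several is reported unpatchable, not guessed — resolving multi-block gaps
would require re-alignment, which is upstream of this package.

QV is $-10\log_{10}(d/G)$ where $d$ is the weighted count of homozygous
assembly-vs-read differences with quality at least 10 (SNV = 1 bp, indel =
allele-length difference; equal-length multi-base substitutions count
differing positions, a documented extension since the literal indel rule
would weight them 0) and $G$ is the effective genome size — the number of
assembly bases with short-read coverage, supplied as a scalar or derived
from a depth track with threshold $\ge 1$. Heterozygous differences reflect
the diploid donor rather than assembly error and are excluded. With $d = 0$
the error rate is below detection resolution; the report carries
$-10\log_{10}(1/G)$ flagged as a lower bound instead of infinity.

# Phasing and ROH summaries

The phased fraction is reported over two denominators — all variants (the
headline convention of linked-read phasing reports) and heterozygous
variants only — because the published convention is ambiguous and only
heterozygous sites can carry phase. A gene (1-based inclusive span, length
$end - start + 1$) is *eligible* when shorter than 100 kb (strict) with at
least two heterozygous variants, and *single-block* when all its
heterozygous variants are phased into one phase set. Long-ROH totals sum,
per individual, segment lengths strictly greater than 5 Mb.

# The synthetic world

`sim_config()` fixes the stated world; generators derive independent random
sub-streams from one master seed, so a fixed configuration yields
byte-identical files.

* **Cohort**: 110 diploid individuals (the emulated cohort size), 2000 sites
  on a regular grid over a 2 Mb contig, per-genotype dropout 5% (a modest
  stand-in for a cohort mixing 13 high- and 97 low-coverage genomes).
* **Haplotype model**: founder-pool copying. Per LD block, every haplotype
  is a copy of one of 6 founder haplotypes whose alleles are Bernoulli draws
  at a per-site frequency (uniform on [0.05, 0.95] by default); founder
  choices redraw at block boundaries with probability 1 by default (fully
  independent blocks). This realizes high within-block and near-zero
  cross-block $r^2$ with no coalescent machinery, and it makes the true
  allele frequency exactly the founder-pool mean, so the observed allele
  count is Binomial$(2n, p)$ — a closed-form oracle for recovery tests.
* **Block lengths**: 100 kb by default, 10 kb for the "shorter blocks"
  population. These are free parameters, not calibrated values — the source
  material describes its cohort's LD only qualitatively (shorter blocks, as
  known for African ancestries); what the tests establish is the *direction*
  of the proxy-count contrast, not its magnitude.
* **`ld_block_length = Inf`** is the documented single-block limit (with a
  2-founder pool it yields perfect pairwise LD). A *finite* block length
  longer than the shortest contig is rejected; the infinity escape hatch
  resolves the tension between that sanity check and the limit case.
* **Depth tracks**: Poisson background around a low mean (unmapped-read
  depth is sparse); planted intervals set exactly `carrier_depth` in exactly
  `n_carrier_samples` samples, so threshold boundaries are sharp and
  testable. The dense base-by-sample matrix is capped at 5e7 cells — the
  generator targets assembly-contig scale (tens of kb), not whole genomes.
* **Interval fixtures** (SVs, coverage gaps, phase blocks, ROH) are built
  truth-first: the ground truth is planted and the observable input is
  constructed around it (SV truth intervals are split into overlapping
  source calls; coverage is emitted as the complement of planted gaps; phase
  summaries are fixed as counts and then realized), so recovery tests never
  re-derive truth through the code under test. ROH segments live on a
  virtual ~249 Mb chromosome because multi-Mb runs cannot fit test-scale
  contigs.

What the generators do **not** emulate: realistic site-frequency spectra,
coalescent genealogies, sequencing error, genotype-likelihood uncertainty,
reference bias, or segmental duplication structure. A green test therefore
establishes algorithmic correctness on data with the assumed structure, not
end-to-end fidelity on real cohorts.

# Numerical and testing choices

* Percentages round half away from zero (integer for proxy sharing, one
  decimal for phased fractions); exact fractions are always retained.
* All threshold comparisons follow the quoted wording: MAF > 5% strict,
  $\ge$ 100 individuals inclusive, panel AF < 1% strict, $r^2$ > 0.8
  strict, depth > 5 strict by default, run length $\ge$ 500 bp inclusive,
  $\ge$ 10 samples inclusive, gaps > 800 kb strict, quality $\ge$ 10
  inclusive, ROH > 5 Mb strict.
* The brute-force $r^2$ equivalence check enumerates all ordered dosage
  vector pairs exhaustively for lengths 2–4 and samples 2000 seeded pairs
  per length for 5–8: full enumeration at length 8 alone would be $3^{16}$
  pairs, far beyond a minutes-scale budget, and the sampled check has the
  same power against implementation error.
* The strict-boundary proxy test pins $r^2 = 1$ (exactly representable)
  rather than a fraction like 27/34, whose computed value differs from the
  exact rational by one ulp.
* The end-to-end demo (`run_all`) scores its synthetic difference table
  against a 5 Mb demo-scale effective genome size; the QV it prints is a
  demonstration of the formula, not an assembly claim.

# Limitations

Proxy computation is quadratic in sites within a window and intended for
locus-scale scans, not genome-wide LD matrices. The VCF writer emits
GT-only records; richer FORMAT fields are read (via VariantAnnotation) but
not written. Translocation merging uses breakpoint quantization, which can
split pairs straddling a quantization boundary when a nonzero window is
used. Per-panel rarity, the proxy search window, and the replication
threshold are documented choices where the source material is silent; all
are exposed as arguments.
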