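---
title: "Models and methods behind riphewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riphewas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models, parameter choices and
numerical conventions of the package, and states plainly what the
synthetic-data generators do and do not emulate.

## The recombinant-inbred genotype model

A two-parent recombinant-inbred (RI) strain is a fully inbred mosaic of the
two parental genomes; genotypes are coded 0 and 2 with no heterozygous calls.
Along a chromosome, `simulate_ri_genotypes()` draws the first marker's allele
with probability 1/2 and switches the allele between adjacent markers with
probability

    R = 4r / (1 + 6r),

where `r` is the single-meiosis recombination fraction obtained from the cM
gap through Haldane's map function `r = (1 - exp(-2d))/2`. This is the
standard map expansion for an RI line fixed by repeated sibling mating, and
it is the model choice we make: the inbreeding scheme is not dictated by the
analysis, but BXD-like panels are sib-mated, and this expansion reproduces
their haplotype-block structure (short-range discordance inflated roughly
four-fold, saturating at 1/2 for unlinked markers). The Markov construction
implies no interference beyond what the expansion itself encodes.

## The phenome generator

Each trait is `g + e` with `e ~ N(0, sigma^2)` and `sigma` chosen against the
realized genotype variance so the planted marker explains exactly the
requested fraction of trait variance in expectation; null traits are pure
standard normals, and missingness is completely at random. These are
stand-ins: no generative model for a real phenome (scale heterogeneity,
trait–trait correlation, shared environmental structure, genetic background
from unplanted loci) is claimed, which is why a green power test establishes
sensitivity of the scan under idealized i.i.d. Gaussian noise, not
performance on a real phenome. Trait categories are drawn uniformly from a
15-term controlled vocabulary purely so grouping code paths are exercised.

## Haplotype blocks, marker mapping and the correlation scan

Markers with identical strain-distribution patterns in consecutive map
positions are one haplotype block; the leftmost member represents the block
(any member is equivalent by construction, since the genotype vectors are
identical). Variants map to the nearest block marker by physical distance
within ±1 Mb, ties broken toward the lower coordinate.

The scan statistic is the Pearson correlation over pairwise-complete strains
with the exact t transform for its two-tailed p-value. Conventions:

* minimum pairwise-complete `n` is 6 — below that a trait is skipped with an
  explicit status rather than contributing an unstable estimate;
* `|r| = 1` maps to `p = 0` to avoid the 0/0 in the t transform;
* zero variance in either vector is a skip status, not an error.

## Storey q-values

`storey_qvalues()` estimates the null proportion from
`pi0(lambda) = #{p > lambda} / (m (1 - lambda))` on the grid 0.05–0.95 (step
0.05), smooths with a cubic polynomial, evaluates at the largest lambda and
clamps into (0, 1]. Then `q_i = min_{p_j >= p_i} pi0 * m * p_j / rank(p_j)`,
capped at 1. With fewer than 20 p-values the smoother is unreliable and pi0
falls back to 1, making the procedure exactly Benjamini–Hochberg (a property
the tests assert). Q-values are computed per scan family — one marker against
one phenome — matching how per-scan Manhattan plots are drawn; the
alternative (one global family across all markers) would couple unrelated
scans and is deliberately not used.

## Variant consequence classification

Internal coordinates are 0-based half-open everywhere; conversion happens
only at the VCF (1-based) and GFF3 (1-based inclusive) boundaries and is
covered by round-trip tests. Codon calls are computed on the coding strand;
splice donor means the first two intronic bases and acceptor the last two, in
coding-strand orientation — the canonical GT/AG convention. Indels are
left-normalized (VCF parsimony) before classification; a boundary-spanning
indel receives the most severe class among the features it touches, and
multi-transcript variants the most severe class across transcripts, with the
fixed severity order stop_gain > stop_loss > frameshift > splice >
missense > in-frame > synonymous > UTR > intronic > intergenic. Stop-loss is
called from the natural stop codon only; no downstream-stop search is
attempted. Transcripts whose CDS length is not a multiple of 3 are flagged
incomplete and receive only non-coding classes; for an exonic position inside
such a broken CDS neither UTR label is truthful, so the package reports a
distinct `noncoding_transcript` class ranked just above the UTRs.

## Noncoding impact scores

The score is the product `S = F * M`. `F` is 1 for any overlap with a known
regulatory element, else the overlapped conserved element's score (maximum if
several), else missing; regulatory overlap wins when both apply because
direct regulatory evidence is stronger than conservation alone — the sources
define no precedence, so this is our choice, logged in the output. `M` maps
the raw per-base conservation value through the empirical CDF of the whole
track; whether the original mutation score was raw or transformed is not
knowable from the sources, and the CDF mapping is our decision — it is
monotone, scale-free and pins the most conserved position to exactly 1.

A missing component is replaced by half the smallest positive value of that
component observed across the scoring pass. Any value strictly between 0 and
the observed minimum satisfies the stated rule ("a non-zero value less than
all observed scores"); half-minimum is deterministic and scale-free. This
forces two-pass evaluation, and a scalar call that needs the minimum without
being given one errors rather than guessing. Both components missing gives
S = 0, so S > 0 always implies some evidence.

Comparative calls on alignment columns need at least two mammalian taxa;
invariant-in-mammals positions with a differing variant residue are likely
deleterious, strengthened to "enhanced" when non-mammals agree too, and any
variability among mammals (in particular within rodents or primates) makes
the call unlikely-deleterious.

## CNV calling by event-wise testing

Windows are 100 bp and non-overlapping. The baseline is the median and the
dispersion a MAD-derived s.d. of unmasked windows — robust statistics,
because the CNVs being sought contaminate a mean/s.d. baseline. Each window
gets Gaussian upper/lower tail probabilities kept on the log scale (tail
probabilities underflow past z ≈ 38 otherwise). Runs form at the per-window
threshold `alpha^(1/min_consec)` per tail, so a minimal qualifying run can
meet the event-level alpha; event significance is Fisher's combination over
member windows, capped at the smallest representable double.

That per-window threshold is deliberately permissive (0.25 at the defaults),
which lets a strong event drag adjacent baseline windows into its run. Run
edges are therefore refined before filtering: an edge window whose count sits
closer to the baseline than to the event mean is trimmed. Without this step
roughly one planted-event boundary in eight lands two or more windows off;
with it, boundaries are window-exact on strong events, and under the null
trimming only shrinks chance runs. Events must still span ≥ 10 windows and
≥ 1 kb at event p ≤ 1e-6; these three constraints are asserted on every
emitted call. There is no GC correction, and gains and losses cannot overlap
by construction since direction is fixed within a run.

Depth noise is Poisson in the generator — `Poisson(depth_mean * ratio / 2)`
per window with copy ratio 2 as the diploid baseline. Real depth tracks are
overdispersed and GC-biased; the Poisson world is the stated one, so the
caller's measured power (planted 30-kb 4x events at 30x depth) is an upper
bound on real-data behavior.

## The clinical arm

ICD9 codes map to hierarchical phecodes. A case needs mapped code instances
on at least two distinct dates — "distinct dates" is our reading of "two
codes", guarding against same-visit duplicates. Instances of descendant
phecodes count toward the parent (distinct dates pooled across the
descendant set). Exactly one instance makes the person neither case nor
control; carriers of any code in a phecode's control-exclusion set are
likewise removed from its control pool. Phenotypes need at least 20 *cases*:
the threshold could also be read as cases+controls, but 20 cases is the
standard PheWAS convention and is what the package implements.

The scan is logistic regression of case status on additive genotype plus
age, sex and three principal components (consumed as covariate columns;
ancestry inference is out of scope), fit by iteratively reweighted least
squares with tolerance 1e-8 and at most 25 iterations. The genotype
coefficient's two-tailed Wald p is reported; non-convergence or separation
(unbounded coefficients, or fitted probabilities saturating by class) yields
a status flag and no p-value. QC removes samples with call rate ≤ 99% first,
then SNPs with call rate ≤ 95% or MAF ≤ 1% on the retained samples — all
strict inequalities.

The cohort generator plants one additive effect with a configurable odds
ratio at a configurable MAF, with baseline prevalence 10%, genotype-independent
background diagnoses at 5% per leaf phecode, and a 90% chance that an
affected person accrues ≥ 2 distinct-date codes. These rates are realistic
orders of magnitude for a common-disease phecode in an EHR but are not fit to
any real cohort.

## Pipeline, formats and determinism

All intermediates are plain TSV/CSV/FASTA/GFF3/VCF/BED/bedGraph — inspectable
and diff-able. Readers lean on rtracklayer, Biostrings and VariantAnnotation;
the package's own writers are minimal emitters whose output is verified by
round-trip through those parsers. One master seed is split into per-stage
substreams (`derive_seed()`), so a fixed seed yields bit-identical pipeline
output and any stage can be re-run in isolation from cached intermediates.
The CLI takes a JSON configuration file; JSON was chosen over YAML because
the R toolchain this package targets ships a JSON parser but no YAML parser.

## Known limitations

* The RI model ignores crossover interference and segregation distortion.
* The phenome generator has no trait–trait correlation structure except what
  planted markers induce; FDR results on it say nothing about correlated
  phenomes.
* The CNV caller is single-sample and read-depth only; split-read and
  paired-end evidence, multi-sample genotyping and GC correction are out of
  scope.
* Coding-SNP impact predictions (SIFT/PolyPhen-style) are consumed as
  precomputed columns if present, never computed.
* PC group scans mean-impute missing trait values after scaling; with heavy
  missingness PC1 shrinks toward imputed zeros.
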