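---
title: "recscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{recscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`recscan` implements family-based discovery of fully penetrant
autosomal-recessive disease variants: concordance mapping on SNP-array
genotypes, a staged prioritization cascade over WGS variant calls,
codon-level consequence annotation, and validation statistics
(segregation, allelic association, identity-by-descent). This vignette is
the package's own account of the underlying models, the conventions that
had to be fixed where more than one reasonable choice existed, and what
the simulation-based tests do and do not demonstrate.

## The inheritance model

Everything downstream assumes a single biallelic causal variant with
*complete penetrance* under a recessive model: an individual is affected
if and only if it carries two copies of the causal allele. Three
consequences structure the code:

* every affected individual is homozygous for the causal allele;
* every parent of an affected individual is an *obligate carrier* and, if
  unaffected, must be heterozygous;
* no unaffected individual may be homozygous for the causal allele.

Incomplete penetrance, phenocopies, compound heterozygosity and X-linked
or dominant models are out of scope; where real data violate the model,
the segregation checker reports named violations
(`affected_not_hom_alt`, `unaffected_hom_alt`,
`parent_of_affected_without_alt`, `mendelian_error`) rather than
silently tolerating them.

## Concordance mapping

A marker is *concordant* when every case is homozygous for the marker's
minor allele, every obligate-carrier parent is heterozygous, and every
control carries at most one minor allele. Conventions fixed here:

* **Minor allele** — the allele at sample frequency < 0.5 over all
  genotyped individuals; monomorphic markers are skipped. At a frequency
  of exactly 0.5 the alternate allele is treated as minor: with cases
  homozygous and parents heterozygous, small samples land on 0.5 easily,
  and dropping those markers would discard exactly the configuration the
  scan looks for. The choice is deterministic and symmetric variants of
  it would only relabel the same marker set.
* **Missing genotypes** — a missing call in any required individual makes
  the marker non-concordant. This is the conservative, all-individuals
  reading of the selection rule; the alternative (ignore missing) would
  admit markers supported by fewer observations than the rest.
* **Controls** — by default, every genotyped individual that is neither a
  case nor a parent of a case. Explicit role assignment overrides this.

**Region clustering** merges concordant markers whose gap is at most the
merge window (default 5,000,000 bp — the scale over which within-breed dog
LD persists) by *single linkage* per chromosome, with an inclusive
boundary (`gap <= window`). Fixed-width windows were the plausible
alternative; single linkage was chosen because it is
parameterization-free apart from the window, produces regions whose
bounds are actual marker positions, and guarantees the partition
properties the tests assert (disjoint regions, no two regions within one
window of each other).

**Ranking** is by marker count descending, then marker density
(markers/Mb) descending, then (chromosome, start) ascending. Count and
density are the two published criteria ("frequency and density"); their
interaction was never formalized at source, so the lexicographic order
(count first) is a package convention, and the final coordinate key makes
the order total and stable.

## The prioritization cascade

Stages run in a fixed order: hard filters, known-variant exclusion,
candidate-region restriction, protein-altering classification,
inheritance concordance, deleteriousness gate. Counts are tracked per
stage, separately for SNVs and indels, and are non-increasing by
construction. Conventions:

* **Hard-filter boundaries are strict, exactly as printed.** An SNV fails
  iff QD < 2.0, FS > 60.0, MQ < 40.0, HaplotypeScore > 13.0,
  MQRankSum < −12.5 or ReadPosRankSum < −8.0; an indel (or MNP) iff
  QD < 2.0, FS > 200.0 or ReadPosRankSum < −20.0. A record sitting
  exactly at every bound passes; boundary fixtures pin this down.
* **Absent annotations never fail a filter.** Callers do not emit every
  annotation for every record (rank-sum statistics need heterozygotes,
  HaplotypeScore is caller-dependent), and hard-filtering tools skip
  missing annotations rather than failing them. Records are never
  imputed.
* **Known-site matching requires allele identity**, not just position:
  a novel allele at a known polymorphic site is still a candidate.
* **Inheritance concordance** automates what was historically a manual
  genotype inspection: every case must be called hom-alt, every carrier
  het, and any configured control not hom-alt; a missing genotype among
  cases or carriers fails the record (all sequenced individuals must be
  cleanly called — the closest mechanizable reading of a visual quality
  check). The control clause exists for generality but is empty in the
  classic quartet design (two cases + two parents), which sequences no
  unaffected non-carriers.
* **Deleteriousness gate**: keep score < 0.05. Truncating classes
  (stop-gained, frameshift) without a score pass, because score tools
  routinely leave truncating variants unscored and a nonsense variant is
  the very signal the cascade exists to find; other unscored records are
  dropped and counted.
* **MNPs** are classified at cascade granularity (class `mnp`, no
  amino-acid resolution) and are excluded by the protein-altering stage;
  in practice they are also removed by inheritance checks. Indels are
  classified in-frame/frameshift by length mod 3 only.

## Consequence annotation

Variants are projected onto the spliced CDS in translation order
(minus-strand genes counted from the 3′-most genomic CDS base, with
alleles complemented), the affected codon is mutated and both codons are
translated with the standard genetic code (translation table 1 — the
target genes are nuclear). Classification precedence: synonymous,
stop-gained, stop-lost, start-lost (codon 1 losing ATG), missense. The
codon index is `((cds_pos − 1) div 3) + 1`; a stop gained at codon *k*
leaves a *k* − 1 residue peptide. HGVS-style names are emitted at SNV
resolution (`c.58A>T`, `p.Lys20*`, `p.Ser7=` for synonymous, `p.Met1?`
for start loss); the full HGVS grammar (intronic offsets, duplications,
extensions) is out of scope. Indels straddling an exon/CDS boundary are
flagged `unsupported` and reported rather than guessed at. An SNV whose
stated reference allele disagrees with the gene model's sequence raises a
reference-consistency error — that situation always indicates a
coordinate or annotation bug and must not be absorbed silently.

## Validation statistics

**Allelic association.** Genotype counts are collapsed to the 2×2 allele
table (two alleles per individual) and the Pearson chi-square statistic
with 1 df is computed in closed form, *without* continuity correction —
the plain allelic test, which is what reproduces published values of this
test family. The p-value is the upper-tail chi-square probability from
R's `pchisq`, whose incomplete-gamma implementation is accurate in double
precision far below the 1e−34 scale these tests reach; a naive
single-precision or unguarded `1 − CDF` evaluation would underflow, which
is why the tests pin p-values near 1e−14 and 1e−34 against independent
oracles (`chisq.test(correct = FALSE)` and the complementary error
function). Monomorphic tables raise an error instead of returning NaN.

**Identity by descent.** The method-of-moments estimator: per marker, the
expected probabilities of sharing 0/1/2 alleles identical-by-state given
0/1/2 alleles identical-by-descent are computed from sample allele
frequencies with falling-factorial (finite-sample) bias corrections,
summed over markers, and inverted against observed IBS counts to give
(Z0, Z1, Z2), which are clamped to [0, 1] and renormalized;
PI_HAT = Z1/2 + Z2. Frequencies should come from a reference panel
(e.g. the unrelated founders) rather than the tested pair's relatives; the
estimator takes them, and the effective sample size behind them, as
explicit arguments. Markers with frequency 0 or 1 are uninformative and
dropped; an estimate is refused below a configurable marker minimum
(default 50). LD pruning before IBD is unnecessary at simulation scale
and is left to the caller for dense real data (LD inflates the variance,
not the expectation, of PI_HAT).

## The synthetic-data generator

The generator emulates the study conditions the package targets, scaled
to desk size:

* **Genome**: 3 chromosomes × 1 Mb, 4 two-exon genes per chromosome with
  45 bp of CDS in exon 1 (so coding positions past c.45 fall in exon 2),
  random ORF-clean CDS. The causal gene has a 521-codon CDS with codon 20
  fixed to AAA; the causal SNV is A>T at CDS position 58 (stop-gained,
  p.Lys20*, 19-residue product) — the geometry of the motivating
  discovery — with missense/synonymous variants configurable.
* **LD model**: non-overlapping perfect-LD blocks (default 100 kb; the
  real megabase scale shrunk with the genome). All markers in a block
  copy a per-block haplotype backbone whose frequency is drawn from
  [0.1, 0.5]. A coalescent simulator would be more faithful but the
  concordance scan only needs block-scale correlation; perfect blocks
  make the within-block LD property exactly testable in the no-crossover
  limit.
* **Array**: 120 markers per chromosome on a jittered grid (even coverage
  guarantees markers flank the causal gene inside its block); allele
  labels are drawn with ref < alt lexicographically so PED round trips
  are exact. The real array's per-chromosome density is not knowable from
  desk data; these defaults are documented as package choices.
* **Pedigree**: one sire × two dams (litters of 4 and 3 — full sibs plus
  the half-sib case structure of family designs), plus 9 unrelated
  founder controls; ~19 genotyped individuals, matching the
  order of magnitude of a 14-dog family panel. Breeding founders start
  heterozygous for the causal allele (they are obligate carriers in any
  informative family); other founders draw it at a configured frequency
  (default 0.1), and the generator rejection-samples (bounded at 1000
  attempts, seed advancing deterministically) until at least two
  non-founder individuals are affected and no founder is.
* **Recombination**: crossovers per meiosis per chromosome are Poisson
  with mean rate × Mb/100 (default 1 cM/Mb), placed uniformly — Haldane,
  no interference.
* **WGS callset**: the causal record plus 240 background records (20%
  placed in CDS, 12% indels, 3% MNPs) genotyped for the quartet (two
  cases + two parents, configurable) directly from the gene-dropped
  diplotypes. Each applicable hard-filter annotation fails independently
  at 2% per background record; 30% are flagged known; coding background
  records score below 0.05 with probability 5% (the rest ≥ 0.05), the
  causal record always scores < 0.05, non-coding records are unscored.

**What passing tests show — and don't.** The simulator realizes exactly
the model the pipeline assumes: full penetrance, a single causal SNV,
perfect within-block LD, clean genotypes with no array error or missing
calls. Recovery statistics (causal variant survives the cascade, causal
region ranks first) therefore validate the *machinery*, not the method's
power on real data, where genotyping error, phenocopies, incomplete
annotations and polygenic confounding all degrade concordance. The noise
the simulator does model (filter failures, known-variant contamination,
tolerated coding background) is the noise the cascade claims to remove.

## Problem sizes and determinism

The test suite runs the default simulation across 20 seeds for recovery
statistics, 2,000 replicates for the binomial phenotype check, 20 seeds ×
2,000 unlinked markers for IBD calibration, and exhaustive enumeration
(64 codons × 9 substitutions) for the SNV classifier — sizes chosen so
the whole suite completes in a couple of minutes on one core while
keeping Monte-Carlo standard errors well inside the asserted tolerances.
All randomness flows from a single integer seed; identical seed and
configuration reproduce byte-identical artifacts (fixed header lines, no
timestamps, deterministic column order), which the tests assert by
hashing emitted files.

## Known limitations

* Biallelic analysis only; multi-allelic VCF sites are split per ALT and
  genotypes referencing another ALT become missing for that record.
* No genotype likelihoods, phasing, or imputation; dosage is hard-called.
* The concordance scan is exact pattern matching, not linkage analysis:
  no LOD scores, no recombination-aware region boundaries.
* HGVS output covers SNVs and simple indel classes only.
* The association test is a single-site 2×2 chi-square; no
  genome-wide correction, permutation p-values, or exact tests (Fisher's
  test is available in base R as a cross-check at small counts).
* IBD estimates assume markers are informative and frequencies are
  estimated from an adequate panel; with tens of markers or panel sizes
  below ~30 the clamping step dominates and estimates compress toward
  the boundary.
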