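---
title: "Catalog construction and cross-host comparison: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catalog construction and cross-host comparison: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magcat)
```

`magcat` builds dereplicated species catalogs from bacterial genome
assemblies and compares catalogs across hosts. This vignette explains the
models and conventions the package implements, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where the method left room.

## 1. Quality filtering

checkM-style completeness and contamination estimates are combined into a
single quality score,

$$Q = \text{completeness} - 5 \times \text{contamination},$$

both in percent. The factor 5 penalizes contamination heavily: a genome that
is 95% complete but 10% contaminated scores 45 and is excluded. Thresholds
follow the MIMAG-aligned catalog convention and are applied with their
literal boundary semantics:

| parameter    | default | boundary                                  |
|--------------|---------|-------------------------------------------|
| `n50_min`    | 5000 bp | strict: N50 must *exceed* 5000            |
| `score_min`  | 50      | inclusive: Q = 50 is kept (only < 50 out) |
| `hq_score`   | 90      | strict: Q = 90 is *not* high quality      |

Contamination has no upper cap — multi-strain reference genomes can reach
100% — so Q may be strongly negative. An optional `passes_chimerism` column
(an upstream GUNC-style screen, not reimplemented here) is AND-ed into the
filter when present. Whether N50 refers to contigs or scaffolds is decided
by whatever records the input FASTA contains; the package does not
distinguish them.

## 2. ANI by MinHash sketching

Each genome is reduced to the `sketch_size` (s, default 5000) smallest
64-bit hashes of its canonical k-mers (k odd, default 21; a k-mer's
canonical form is the lexicographic minimum of itself and its reverse
complement, so strands are interchangeable). k-mers containing N are
skipped, which is why ambiguity codes are normalized to N on FASTA read.
Hashes are truncated to 53 bits so they remain exact in R doubles; the hash
seed is recorded in sketch files, and sketches with different seeds refuse
to be compared. Determinism across runs is guaranteed; hash equality with
other sketching tools is not a goal.

The Jaccard index of two genomes is estimated from the merged bottom-s set,
and converted to ANI with the Mash transform in its exact (exponential)
form:

$$\widehat{\mathrm{ANI}} = \left(\frac{2j}{1+j}\right)^{1/k},
\qquad j = 0 \mapsto \mathrm{ANI}\ 0.$$

**Why the exponential form.** The familiar linearization
$1 - d = 1 + \tfrac{1}{k}\ln\tfrac{2j}{1+j}$ equals
$1 + \ln(t)$ for true per-site identity $t$ under the substitution model,
i.e. it is biased low by $\approx (1-t)^2/2$ — about 0.005 at ANI 0.90,
which would consume the whole calibration budget at the low end of the
relevant range. The exponential form is the exact inverse of
$j = w/(2-w)$ with $w = t^k$ and recovers simulated targets
{0.90, 0.95, 0.97, 0.99} without bias (the test suite checks a ±0.005 band
on means over 10 seeds). Both forms agree to first order; at $j = 0.5$,
$k = 21$ they differ in the fourth decimal (0.98088 vs 0.98069).

Pairs are only *reported* at ANI ≥ 0.8 (`report_min`). A pair below the
floor is treated downstream as "no edge", never as ANI 0 — the transform is
too noisy there to mean anything, and sub-floor similarity must not
influence clustering.

`exact_jaccard()` computes the exact Jaccard over full canonical k-mer sets
through an independent string-based path (Biostrings reverse complement, no
hashing); it exists as a validation oracle and for the generator's
rejection checks, not as a faster substitute for sketching.

## 3. Species clustering

Genomes passing QC are pre-clustered into connected components of the
ANI ≥ 0.8 graph; exact hierarchical clustering then runs per component.
Within a component, average-linkage agglomeration on $d = 1 - \mathrm{ANI}$
is cut so that genomes merged strictly below $d = 0.05$ (ANI > 95%, strict)
share a species. Numerical conventions:

* unreported pairs are imputed at $d = 0.3$ — far above any plausible cut,
  so they never drive a merge but still allow transitive cluster membership
  through reported pairs;
* the strict inequality is realized as a cut height of
  $1 - \text{threshold} - 10^{-9}$;
* merge ties break deterministically (smallest cluster indices in the
  brute-force reference; `stats::hclust` is the production path and is
  tested for partition equality against that reference on random instances
  of up to 12 genomes — ties have measure zero under continuous ANI draws).

The representative of each species maximizes

$$\mathrm{Score} = Q + 0.5\,\log_{10}(\mathrm{N50}) + 100\,[\text{isolate}],$$

with ties broken by lexicographically smallest genome id. The log base is
not fixed by the formula's source; base 10 is the declared convention here,
keeping the contiguity term in the single digits (0.5 per decade of N50) so
the +100 isolate term dominates any realistic quality difference.

## 4. Taxonomy comparison

Lineages are GTDB-style seven-rank strings
(`d__;p__;c__;o__;f__;g__;s__`). Ranks left unnamed by the classifier get
deterministic placeholder names
`<prefix><deepest named ancestor>-<anchor>-<rank letter>` (e.g.
`g__Muribaculaceae-SP001-g`), anchored at the species id. This replaces
manual curation of novel taxa with a reproducible surrogate: placeholders
are injective across anchors, idempotent under re-filling, and private to
their catalog — they never match between catalogs, which is exactly the
behaviour wanted when counting overlap (a novel, unnamed genus cannot be
"shared" by name).

Overlap at a rank is counted against the *reference* host's taxa: the
denominator is every distinct reference taxon at that rank (placeholders
included — they are real, just unnamed, taxa), and a taxon is shared when
its non-placeholder name occurs in the other catalog, or — at species rank —
when the input table flags it as shared (the flag encodes an upstream
cross-catalog ANI > 95% match, which is the dereplication module's job when
raw genomes are available). Display rounding is integer percent above
species rank and one decimal at species rank. Note one unavoidable
wrinkle: a fraction like 88/109 = 80.7% is sometimes quoted as "80%" in
prose; nearest-integer display gives 81. The package reports the exact
fraction alongside the display value.

## 5. Compositional statistics

Count tables (samples × taxa) are compositional; all comparisons run on the
centered log-ratio scale. Per sample: closure, multiplicative zero
replacement, then $x_i \mapsto \ln x_i - \overline{\ln x}$. The replacement
substitutes $\delta$ for zeros and rescales non-zeros by $1 - \delta z$
($z$ = number of zeros), preserving closure; the default
$\delta = 1/N^2$ with $N$ the number of taxa. CLR uses the natural log
(only relative comparisons are consumed downstream). CLR rows sum to zero
to within 1e−9 and are invariant to per-sample count scaling.

Mapping rate is the per-sample row sum divided by the sample's total read
count. Cross-host mean-abundance correlation (Pearson) runs over the union
of taxa, imputing a host's minimum observed mean for taxa absent from that
host.

KEGG-module presence uses the inclusive ¾-step rule
(`steps_present / steps_total ≥ 0.75`, so 6 of 8 counts); module abundance
per sample is the summed relative abundance of module-carrying genomes.
Group differences use Welch's unequal-variance t test
(Welch–Satterthwaite df, two-sided p; t = 0, p = 1 for identical constant
groups) with Benjamini–Hochberg step-up adjustment. Whether differential
module testing should run on raw relative abundances or CLR values is not
fixed by convention; **CLR is the default** here (`transform = "clr"` in
`differential_test()`), with `"none"` available, and the choice is visible
in the call rather than hidden in output.

## 6. The synthetic-data generator

The generator exists so that every stage is testable offline with known
truth. Its stated world:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 20 | species count |
| `strains_per_species` | 2–5 | uniform per species |
| `genome_length` | 100 kb | ancestor length |
| `within_species_ani` | 0.97 | realized pairwise strain identity |
| `between_species_ani` | 0.90 | upper bound between species |
| `target_n50` | 20 kb | fragmentation target |
| completeness | U[60, 100] | metadata only |
| contamination | U[0, 8] | metadata only |
| isolate flag | one strain per species w.p. 0.3 | |

Divergence is substitution-only (each site mutated independently to a
different base), so target ANI is interpretable as 1 − substitution rate
and the exact k-mer oracle stays meaningful. Because two strains are
mutated independently from their ancestor, the per-branch retention $a$ is
solved from the pairwise identity $p = a^2 + (1-a)^2/3$
(`branch_identity()`), so `within_species_ani` is the *realized pairwise*
ANI between strains, not a branch rate. Between-species ancestors are
derived from a shared root when the bound is ≥ 0.75 (so pre-clustering is
genuinely exercised: everything lands in one component and average linkage
must do the splitting) and checked against the exact oracle on a subsample
of pairs, with regeneration on failure.

Deliberate simplifications — and therefore what a green test does *not*
establish: no indels or rearrangements, no sequencing error or read-level
simulation, contamination is metadata only (no foreign contigs), no GC or
repeat structure beyond i.i.d. bases, and genome sizes far below real
bacterial genomes (sketch error scales with genome size, so real-data error
at s = 5000 is smaller than in these tests, but alignment-based ANI
disagreement with sketch ANI is not modelled at all). `target_n50` defaults
to 20 kb so that fragmentation does not interact with the N50 > 5000 filter;
the quality filter still removes a realistic fraction of genomes through
the metadata draws (Q < 50 happens at roughly one third frequency under the
defaults), which is why recovery checks compare against truth restricted to
QC-passing genomes — exclusions are reported, not lost.

Under the default metadata world an entire species occasionally fails QC;
the recovered cluster count then equals the number of truth species *among
kept genomes*, and the adjusted Rand index against that truth is the
recovery criterion.

## 7. Degenerate inputs and numerical conventions

* FASTA: ambiguity codes → N on read; empty files and malformed headers are
  errors with line numbers; `.gz` transparent.
* Sketching: genomes without a single valid k-mer error
  ("genome too short for k"); even k is rejected; sketches saturate (and
  then equal the exact Jaccard) when a genome has fewer than s distinct
  k-mers.
* `jaccard_estimate` divides by the merged bottom-set size, which is
  min(s, |union|).
* All-zero composition rows cannot be closed and error; δ·zeros ≥ 1 errors
  as "delta too large".
* Correlation needs ≥ 3 taxa after the union; fewer is "degenerate".
* `fragment_to_n50` accepts any target up to the sequence length (targets
  above half the length yield a single contig) and retries sampling until
  the realized N50 lands in [0.5, 2] × target.
* Every stochastic entry point takes a seed; `simulate_*` functions default
  to the ambient RNG so one outer seed drives a whole simulated world.

## 8. Known limitations

Sketch ANI is not alignment ANI: systematic offsets of a few tenths of a
percent against alignment-based tools are expected and irrelevant to the
95% boundary at these divergences, but this package should not be used to
report ANI values where alignment-grade accuracy matters. The placeholder
taxonomy is a surrogate for curation — it preserves counting semantics, not
nomenclature. Chimerism screening, completeness/contamination estimation,
read classification and module annotation are consumed as inputs, never
recomputed. Strain-level sub-clustering below the species boundary is out
of scope.
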