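---
title: "Classifying dual-Cas9 repair outcomes with dualcut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dual-Cas9 repair outcomes with dualcut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A pair of Cas9 nucleases targeted to two neighbouring genomic sites — for
example an SpCas9 and an SaCas9 or NmCas9 tethered as one fusion protein —
generates two blunt double-strand breaks more or less synchronously. Canonical
non-homologous end joining then mostly re-ligates the two outer ends,
excising the intervening segment. Amplicon deep sequencing of the locus
therefore observes a characteristic spectrum of products, which `dualcut`
classifies into seven mutually exclusive repair-outcome classes:

* `UNEDITED` — the wild-type sequence (substitution-only differences are
  treated as sequencing/PCR noise, never as lesions);
* `SP_INDEL`, `PARTNER_INDEL`, `BOTH_INDEL` — small insertions/deletions
  confined to one or both cut sites;
* `PRECISE_DELETION` — the exact junction of the two predicted blunt cut
  positions, with no other change;
* `IMPRECISE_DELETION` — loss of the intervening segment with a junction
  that deviates from the exact cut-to-cut join;
* `INVERSION` — the intervening segment reinserted in reverse complement.

The package also quantifies class rates with negative-control background
subtraction, summarises GUIDE-seq off-target tables into specificity ratios,
and enumerates composite dual-PAM target sites genome-wide.

## Cut-site model

Each enzyme is modelled by its protospacer length, PAM, and a blunt cut
`cut_offset` nucleotides 5' of the PAM on the protospacer strand (default 3
for all three enzymes; configurable, which absorbs staggered-cut
alternatives). Coordinates are 0-based and half-open throughout, and cut
junctions are integer split points — the number of reference bases to the
left of the break — which makes junction concatenation arithmetic exact:

```
precise  = wt[0:cut_a] + wt[cut_b:]
inversion = wt[0:cut_a] + revcomp(wt[cut_a:cut_b]) + wt[cut_b:]
```

## Classification by candidate alignment

Every consolidated molecule is aligned globally (affine gaps; match +2,
mismatch −3, gap open −5, gap extend −1 per base; a length-L gap costs
`open + L·extend`) against three candidate references: wild type, precise
deletion, and inversion. The scheme is pinned purely for reproducibility —
any consistent scoring separates the candidates, whose score differences
are dominated by the 60-bp default segment. The best-scoring candidate
(ties broken wild type → precise → inversion) selects the branch:

* **precise best** — no indel events means `PRECISE_DELETION`; any indel
  event means `IMPRECISE_DELETION`. In a precise-best alignment every indel
  is junction-borne, so no positional test is needed; this also makes the
  call independent of where a gap slides inside a repeat.
* **inversion best** — `INVERSION`.
* **wild-type best** — a deletion event covering at least half of the
  intervening segment is a segmental, hence `IMPRECISE_DELETION`. This
  subsumes deletions spanning both cuts and, importantly, also catches
  junction-shifted deletions that lie strictly between the cuts and touch
  neither cut window; with the default 60-bp segment and 20-bp maximum
  simulated indel length the two regimes cannot collide. Smaller indel
  events are attributed to a cut when their left-normalised interval comes
  within `window` (default ±5 bp, chosen to cover typical NHEJ footprints
  while excluding distal artifacts) of the junction: near `cut_a` only →
  `SP_INDEL`; near `cut_b` only → `PARTNER_INDEL`; near both →
  `BOTH_INDEL`. Molecules with no indel near either cut are `UNEDITED`
  provided their gap-excluded identity passes 0.9.

Alignment identity is gap-excluded — matches divided by aligned
(non-gap) columns — so a clean segmental deletion has identity ≈ 1 against
the wild type. The read-mapping quality filter of a mapping-based pipeline
is translated into this space: molecules under 0.9 identity are
`UNCLASSIFIED` (counted, excluded from class tallies), and
`large_deletion_mode` bypasses the filter for libraries where deletions
dominate. Indel events are left-normalised (shifted to their leftmost
equivalent placement) before any positional test, the same convention VCF
uses, so event coordinates are deterministic inside repeats.

## UMI consolidation

Reads are quality-filtered first: mean Phred strictly above 30 and minimum
per-base score strictly above 24 (both read as strict inequalities). The
unique molecular identifier (default 10 nt, 5' end) is then split off, reads
are grouped by exact UMI match, and each group is consolidated to at most
one molecule: the plurality payload is emitted only when it was observed
base-for-base identical at least `min_support = 4` times. Ties on the count
break toward the lexicographically smallest sequence, for determinism. No
fuzzy UMI merging is attempted — the four-identical-reads rule already
suppresses UMI sequencing-error artifacts, and exact matching keeps the
procedure order-independent.

The consolidation rule is deliberately conservative and its yield depends
strongly on read length and error rate: a copy supports its molecule only
if the entire UMI + payload is error-free, so with a 200-nt amplicon,
10-nt UMI and per-base substitution error e the support probability is
`(1−e)^210` (≈ 0.66 at e = 0.002), and molecules with few PCR copies are
dropped. At copy counts uniform on 4–30 this loses roughly 7–8% of
molecules; the package reports rejected groups explicitly so the loss is
visible rather than silent.

## Composite-site enumeration

Guide sites are found by scanning both strands for protospacer+PAM windows
whose PAM matches the enforced pattern core — `NGG` for SpCas9 (expanded
set `{NNG, NGN}`), `GRRT` at its canonical offset within `NNGRRT` for
SaCas9, `GATT` within `NNNNGATT` for NmCas9; leading `N` positions carry no
constraint beyond being A/C/G/T. A site containing any non-ACGT letter is
discarded, so assembly gaps can never produce phantom sites.

Composite sites pair an SpCas9 site with a partner site under a spacing
constraint on the gap between the nearest edges of the two full sites
(protospacer + PAM): 10–30 bp in canonical mode, 10–100 bp in expanded
mode. Orientation is read along the SpCas9 protospacer strand: the partner
downstream of the SpCas9 site gives the active configurations — D1 (same
strand) and D2 (opposite strand) — while D3/D4 are the partner-first mirror
images. Defining orientation relative to the SpCas9 strand rather than to
reference coordinates makes D1/D2 counts invariant under reverse
complementation of the genome, which a leftmost-site convention would
violate; the label mapping is exposed and remappable because the drawn
convention is not uniquely fixed by site geometry alone. The distance
between the two predicted cut junctions is annotated against a 200-bp
functional window — the separation under which a tethered pair remains
active — but never filters results.

## What the simulator does and does not emulate

`simulate_library()` draws molecules from a configurable mixture over the
seven classes (defaults: 20% unedited, 60% precise deletion, 5% each
imprecise/Sp-indel/partner-indel, 2.5% each both-indel/inversion — a
fusion-nuclease-like spectrum), tags each with a random UMI (collisions
allowed and recorded), replicates it by a uniform 4–30 copy-count
distribution standing in for PCR amplification bias, and applies
independent per-base substitution errors (default 0.1%) to every copy.
Qualities are constant Q37; the quality filter is exercised with crafted
records instead. Three generator choices are worth spelling out:

* **No sequencing indel errors by default.** Substitutions never create
  alignment gap events, so the class of a molecule is invariant under the
  error model and closure tests are exact. An indel-error rate exists for
  stress testing and is off by default.
* **Homopolymer runs are capped at 3 nt** in simulated references, and
  every planted indel is accepted only if its left-normalised placement
  stays within the attribution window of its cut. Both ends of the check
  (generator and classifier) use the same normalisation, so an indel can
  never slide out of its window inside a repeat and truth recovery is
  deterministic rather than merely probable.
* **Imprecise junction offsets exclude equal shifts.** The two junction
  offsets are drawn uniformly from ±1..10 but resampled while equal:
  shifting both ends by the same amount yields a product that differs from
  the precise-deletion product only by substitutions, which an indel-based
  taxonomy cannot (and should not) distinguish from a precise deletion.

`simulate_genome_with_sites()` plants composite sites into a random
background and then scrubs the background of accidental composites under
the queried parameter window: background partner-PAM cores are destroyed
first, then an enumerate-and-mask loop mutates one required PAM base (G→T,
C→A) of every remaining spurious pair until the scan returns exactly the
planted truth. In expanded mode any planted G is readable as both `NNG` and
`NGN` one base apart, so the generator uses a single-G SpCas9 PAM (`TGA`)
and pins the planted spacing to the window's upper edge, pushing the twin
reading out of range. Scrubbed backgrounds are therefore locally
AT-enriched around planted sites — a fixture property, not a biological
one.

The generator does not model realistic Illumina error profiles, PCR
chimeras, or amplification bias beyond the copy-count distribution, so
passing tests demonstrate correctness of the computational pipeline, not
robustness to every real-data failure mode.

## Quantification

Class rates are percentages of total molecules. Background subtraction
takes the mean of the (typically triplicate) negative-control rates per
class and floors the difference at zero — negative lesion rates are
meaningless; the same subtraction applies positionally to the indel catalog
matched exactly by (class, event type, reference position, length). The
precise-deletion fraction divides the precise-deletion rate by the summed
rate of all six lesion classes; corrected rates are used when present,
since nuclease-dependent rates are the quantity of interest, and the raw
variant remains available. The logit helper clamps boundary fractions to
`[ε, 1−ε]` with `ε = 1/(2·total molecules)` — half a molecule's worth of
rate — before transforming; Benjamini–Hochberg adjustment delegates to
`stats::p.adjust`. Downstream ANOVA/t-tests are deliberately out of scope:
the package exports logit-transformed tables any statistics environment can
consume.

GUIDE-seq specificity ratios divide on-target unique reads by the summed
unique reads over all identified off-target sites; a nuclease with
on-target signal and no off-target reads reports `Inf` (perfect
specificity) and the no-reads-anywhere case reports `NA`. Peak calling is
consumed as a table, never recomputed.

## Problem sizes and numerical choices

The bundled tests run the classifier closure at 7 × 1,000 error-free
molecules, mixture recovery at 10,000 molecules with 0.1% substitution
error, UMI consolidation at 500 molecules with copies uniform on 4–30 and
0.2% error, and site-finder/oracle comparisons on a 100-kb genome — sizes
at which multinomial sampling error (±1.5% per class at n = 10,000) and the
package's runtime are both well behaved on a single CPU. Alignment uses
32-bit integer scores with a guard against sequence pairs beyond ~40 Mcells;
amplicons here are two orders of magnitude smaller.

## Known limitations

* Inversions are detected only as full-segment inversions; inversion
  junctions carrying additional indels still classify as `INVERSION` only
  when the inversion candidate wins the score comparison.
* Mismatch-tolerant off-target search, guide-efficacy scoring and
  chromatin context are out of scope.
* The per-position indel catalog is defined by this package's alignment
  convention and is not comparable base-for-base with mapper-specific
  catalogs.
* UMI grouping is exact-match; heavily error-inflated UMIs fragment groups
  and lower yield, as quantified above.
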