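---
title: "Microsatellite band-pattern barcoding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite band-pattern barcoding: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msbarcode)
```

## The problem and the procedure

Microsatellites are tandem repeats of short (1–6 bp) motifs whose unit
count varies between closely related lineages. Amplifying a handful of
such loci and reading the product sizes off a gel gives each laboratory
strain a reproducible molecular signature, usable for identity checks and
contamination screens in clonal cultures. `msbarcode` models the entire
desk side of this workflow — repeat detection, in-silico PCR,
band-pattern fingerprinting, pairwise discrimination — plus a simulator
that generates panels with known genotypes.

The pipeline is deterministic: given a band table (observed or
simulated), a gel resolution and the filtering thresholds, fingerprints
and all downstream statistics are pure functions of the input. The only
stochastic component is the simulator, which is fully seeded.

## Repeat tracts

A motif is identified with its equivalence class under rotation and
reverse complement — a repeat read in another phase or on the other
strand is the same microsatellite — and reported as the lexicographically
smallest member (`canonical_motif("TG")` is `"AC"`). Units that are
powers of a shorter unit are invalid: the unit of `TGTG` is `TG`.

`find_repeats()` reports *maximal* tracts with at least `min_units`
perfect units. An interruption is one whole mismatched unit (the
unit-granular model matches the observed `AA`-for-`CA` unit substitutions
inside TG-rich alleles); at most `max_interrupted_units` are allowed per
tract, each flanked by two or more perfect units on both sides. Defaults:
dinucleotide search (`unit_lengths = 2`), `min_units = 5`,
`max_interrupted_units = 1`. The minimum of 5 is a package choice — the
source gels were found with long seed probes but the sequenced alleles go
down to 6 units, and no minimum is stated for calling a microsatellite —
so 5 captures every relevant allele with a one-unit margin.

Coordinates are 0-based, half-open, forward strand. Phase is normalised
by reporting the leftmost maximal extent, and rotated-phase reports of
the same run are collapsed. One consequence is worth stating honestly:
when a partial-unit extension exists at exactly one tract boundary (for
example `G(TG)5`, where the `GT` phase starts one base earlier), the
leftmost representative of a sequence and of its reverse complement
mirror to positions that differ by less than one unit length. No
deterministic representative can make the reverse-complement mapping
exact in that corner, because the two phase variants swap under reverse
complement. The tract *set* — motif, unit count, span up to sub-unit
phase — is strand-stable, and the property tests assert exactly that.

Inputs are validated strictly: characters outside `{A,C,G,T}` (including
`N`) are rejected rather than skipped, so tract arithmetic
(`end − start = unit length × (unit_count + interrupted_units)`) is exact.

## In-silico PCR

Primer binding uses the minimal substitution-only contract: a site is
any position, on either strand, where the primer matches with at most
`max_mismatches` substitutions *and* its 3'-terminal
`three_prime_exact_bases` match exactly (extension initiates at the
3' end, so terminal mismatches abolish amplification). No indels in the
primer alignment — this keeps the site search exact and checkable against
a brute-force oracle. Defaults `max_mismatches = 2`,
`three_prime_exact_bases = 3`, `max_product_bp = 2000` are package
choices: the source protocol specifies annealing conditions, not match
tolerances, and these are the customary minimal values for in-silico PCR.

Amplicons are formed from every plus-strand site and every minus-strand
site fully downstream of it, using either primer of the pair at either
end (self-pairing is degenerate but real behaviour; duplicate intervals
are collapsed). Product size includes both primer footprints, matching
how sizes are reported on gels. An empty result is the model of "no
amplification".

## Band patterns and fingerprints

Bands co-migrate when their sizes differ by *less than* `resolution_bp`;
the default of 2 bp encodes the empirical sensitivity of the gel system
(a 2 bp shift — one dinucleotide unit — is resolvable). Classes are formed
by single-linkage clustering, which is order-invariant and coarsens
monotonically as the resolution grows. The class representative is the
half-up-rounded mean of member sizes; where a sequenced size and a gel
estimate coexist in a fixture, the sequenced size is the one recorded
(218 bp for the band read "about 216 bp" on gel).

Pattern construction filters bands before clustering: bands flagged
`faint` or `smear`, and bands below `min_intensity = 0.25` relative
intensity, are excluded, because strain comparison is done on the
reproducible main bands — this filtering is what reconciles the published
pattern identities (the AEP and *H. oligactis* strains share one 218 bp
class despite smears and faint second bands). Filtering can never demote
an amplified locus to "no amplification": if every band is filtered, the
strongest filtered band is retained. An explicit `no_amplification`
pattern is an informative negative and is distinct from a locus missing
from a fingerprint (missing data — classifying a pair there is an error,
not level 4).

Pattern equality at a resolution is reflexive and symmetric but *not*
transitive (199 ≈ 198 and 199 ≈ 200, yet 198 ≠ 200); equivalence classes
are therefore formed by clustering, never by pairwise closure.

## Four-level discrimination

For each unordered strain pair at a locus: level 1, distinct patterns;
level 2, amplified in exactly one strain; level 3, identical patterns;
level 4, amplified in neither. Levels 1+2 are *positive discrimination*.
Although prose conventions group levels 2 and 3 as "partially
informative", the printed arithmetic counts positives as distinct +
one-sided, and the package follows the arithmetic. Two percentage bases
are in simultaneous use in the published statistics — over all pairs for
one locus, over positive pairs for another — so summaries always report
both, labelled, and callers choose.

The combined matrix takes the numerically smallest level per pair across
loci; a pair is "resolved" iff some locus scores 1 or 2. Identification
scores a query against references by the fraction of shared loci with
identical state and pattern (no partial band credit — the simplest
contract consistent with qualitative gel matching), ties broken
alphabetically.

## The synthetic panel

The generator emulates the mechanisms that shape real strain gels:

- *diploidy*: one or two alleles per genomic copy (homozygous vs
  heterozygous);
- *locus duplication*: a second genomic copy, so a diploid can show up to
  four bands ("twice two alleles");
- *primer-site loss*: three substitutions planted in the 3' half of each
  primer site abolish amplification in selected strains;
- *fixed flank indels*: e.g. the 16 bp deletion
  `TAGTCAAAGTAGTACA` carried by one sub-group's upstream flank;
- *stutter*: each amplified molecule independently loses or gains one
  whole repeat unit with probabilities `p_minus`, `p_plus`
  (defaults 0.1 and 0.05 — slippage shortens more often than it extends;
  multi-unit slips are out of scope); per-amplicon molecule fractions
  below 0.05 — the detection-limit stand-in — are dropped, fractions are
  pooled by size across amplicons and normalised so the modal band has
  intensity 1 (gels are qualitative, so intensity is relative);
- *mosaicism*: with a configurable rate, one extra allele two units away
  appears at intensity ≤ 0.2, flagged `faint`.

The shipped `paper_like_panel.yaml` encodes the nine wild-type strains at
the three loci with the *published repeat counts* as allele values
(e.g. 6, 13 and 17 TG units across the two duplicated copies in Hm-105;
11 vs 13 AT units separating the Basel strains; 16 and 22 in AEP2).
Flank filler is synthesised deterministically from a `flank_seed`
recorded in the file — repeat-free, with the bases adjacent to the
microsatellite forced outside the motif alphabet — so templates are a
pure function of the config and the planted tract is exactly the ground
truth. Flank lengths were chosen so that the amplicon sizes land on the
published sizes where the published data are internally consistent under
a shared-flank model (218 bp for the AEP/*H. oligactis* TG locus;
104/118 bp at ms-DMTF1), and per-strain flank indels reproduce the
published co-migration trio at ms-AIP (Hm-105 ≈ Basel1 ≈ reg-16 within
2 bp). Two published details cannot be carried over verbatim: the AEP2
ms-AIP sizes (204 and 212 bp for 16 and 22 repeats) are mutually
inconsistent under equal flanks, so the repeat counts were kept and the
sizes fall at 201/213; and the faint second Hm-105 ms-AIP product and
fourth Hm-105 TG band exist only in the transcribed fixture, not as
simulator alleles, since modelling them as true alleles would contradict
the published pair accounting. Neither affects any discrimination
statistic, which is the quantity the simulation is asked to reproduce.

With zero stutter and no mosaicism the pipeline output equals the ground
truth exactly (bit-level, given a seed). Under the default stutter the
satellite bands carry ≈ 12% and ≈ 6% relative intensity and are removed
by the 0.25 intensity filter, so modal-band genotype recovery is
effectively complete; recovery is monotone non-increasing in
`p_minus + p_plus`. One global seed drives everything; per strain-locus
sub-seeds are derived deterministically from it.

What the simulator does **not** emulate: quantitative PCR efficiency and
intensity calibration, multi-unit slippage, base-granular interruptions
arising during PCR, inter-locus competition in multiplex reactions, and
allele evolution across generations. Passing the recovery tests therefore
shows the pipeline's logic is sound under the stated noise model, not
that real gels of arbitrary quality will genotype perfectly.

## Fixtures and reconstruction choices

The band-table fixture transcribes the published nine-strain gels: sizes,
smear flags on the larger AEP products, faint flags on the second
*H. oligactis* and Hm-105 bands. One assignment required reconstruction:
the gels mark a faint band in Hm-105 at the AT locus without stating
which of the two sequenced products (199–200 vs 229–234 bp) it is. The
fixture assigns faintness to the 232 bp product because that is the only
assignment consistent with the published pair accounting at that locus
(12 distinct / 3 identical pairs among the co-amplified strains). The
strain panel membership is supplied separately
(`wildtype_strains.txt`), because a strain that never amplified anywhere
(Nicolet) has no band rows yet is a full panel member.

## Numerical and degenerate-input conventions

- Representative size: `floor(mean + 0.5)` (half always up), so
  clustering is platform-stable.
- Identification tie-break: alphabetical by strain name.
- Empty band table → `no_amplification`; empty sequence, non-DNA
  characters, non-primitive motifs, unequal aligned lengths, duplicate
  strain×locus×size rows, unknown flags → typed errors, never silent
  repair.
- All randomness is seeded; simulator outputs are byte-identical for a
  given seed.

## Problem sizes used by the tests

The oracle-equivalence suites compare `amplify` with a brute-force
all-offsets oracle on 200 random planted templates up to 2 kb, and
`find_repeats` with an exhaustive-substring oracle on 500 random
sequences up to 200 bp (complete in a few minutes on one core). The
recovery experiment uses the nine-strain panel, default stutter, 1000
molecules per amplicon and 20 replicate seeds — 420 strain×locus×allele
entries per run. These sizes were chosen so the full suite documents the
behaviour at realistic scale while remaining quick to run.

## Known limitations

- Primer alignment is substitution-only; indel-tolerant binding and
  thermodynamic annealing models are out of scope.
- Repeat units longer than 6 bp and seeded searches against large
  assemblies are out of scope.
- The four-level scheme is qualitative by design: no heterozygosity,
  allele-frequency or match-likelihood statistics.
- Gel-image processing is out of scope; the package starts from band
  tables.
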