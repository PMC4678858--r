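---
title: "Modeling competitive replication and adduct bypass assays"
author: "crabReap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling competitive replication and adduct bypass assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crabReap)
```

## The assay

A single O4-alkylthymidine (O4-alkyldT) adduct mispairs with guanine and
drives T&rarr;C transitions. To measure how such a lesion affects
replication in cells, a 12-mer oligo carrying the adduct
(5'-ATGGCGXGCTAT-3', X = O4-alkyldT) is ligated to a 10-mer
(5'-AGTGGAAGAC-3') and the resulting 22-mer is sealed into a
single-stranded shuttle-vector genome using two bridging scaffolds. The
lesion genome is transfected together with a lesion-free *competitor*
genome at a known molar ratio; after replication, the progeny is
PCR-amplified and read out by *restriction endonuclease and
post-labeling*:

1. a Type IIS enzyme (BbsI, GAAGAC(2/6)) or a frequent cutter (MluCI,
   ^AATT) makes the first cut, creating fresh 5'-phosphorylated ends;
2. shrimp alkaline phosphatase removes accessible 5'-phosphates, and T4
   polynucleotide kinase re-phosphorylates every free 5'-OH with
   [32P]-phosphate -- so exactly the termini created by the *first*
   digestion carry the label;
3. the second enzyme releases a short duplex
   d(p\*GGCGMGCTAT)/d(AATTATAGCN), where M is the base inserted opposite
   the lesion in vivo and N its complement.

Switching the digestion order therefore selects which strand's 10-mer is
visualized. The competitor genome releases a distinguishable 13-mer used
as an internal standard. crabReap implements every desk-computable piece
of this workflow: construct assembly, digestion and label bookkeeping,
gel-band quantification, fragment-ion prediction for LC-MS/MS
verification, and a synthetic-data generator that takes the place of the
wet steps.

## Quantities and estimators

**Bypass efficiency.** With each lane normalized to its competitor band,

$$\mathrm{BE}(\%) = \frac{I_\mathrm{lesion}/I_\mathrm{comp}}
{I_\mathrm{control}/I_\mathrm{comp}^{ctl}} \times 100
\;\Big/\; \frac{r_\mathrm{lesion}}{r_\mathrm{control}},$$

where the lesion and control signals sum *all* 10-mer product bands of
the lane and the trailing division corrects for the transfection mixing
ratios (the division convention is fixed here; the source protocol states
only that the molar ratio is taken into account). The ratio structure
makes the estimate invariant to uniform rescaling within a lane. Within a
replicate the ratio is computed per scheme and averaged; across
replicates we report arithmetic mean &plusmn; sample SD. A zero
competitor band makes the quantity undefined and is raised as an error,
never reported as 0.

**Mutation spectrum.** Each band contributes one linear constraint: its
share of the scheme's substitution-product signal equals the summed
frequency of its member outcomes. The lesion-strand scheme contributes
rows for the merged T/C band and the resolved A and G bands; the
complementary-strand scheme contributes one row per resolved N. The
spectrum $(f_T, f_C, f_A, f_G)$ is the least-squares solution constrained
to the probability simplex, solved exactly by enumerating the 15 support
sets of a 4-dimensional problem (no QP dependency). With consistent
tables the solution is exact; the T/C split is identified only by the
complementary-strand rows, so the lesion strand's co-migration cannot
bias it. Mutation frequency is $1 - f_T$.

**Frameshifts and deletions.** Hypothetical &minus;1/&minus;2 products
release 9-/8-nt fragments; bands at those lengths are reported as a
fraction of lane signal against a configurable detection threshold
(default 0.5%, since the source assay reports frameshifts only as "below
detection" without a number). Large deletions remove the recognition
sites entirely, so no diagnostic labeled fragment appears at all --
`isBypassDetectable()` returns `FALSE`, which the assay scores as lack of
bypass.

## Design choices where the protocol is silent

**Primer matching.** The printed forward primer matches the
scaffold-derived top strand with exactly one mismatch at its 5'-terminal
base. Since PCR tolerates 5'-end mismatches and the product carries the
primer sequence regardless, `extractAmplicon()` requires an exact match
except within the primer's 5'-terminal window (default 2 nt) and writes
the primer sequence into the amplicon. Each primer must still match
exactly once. Primer 5'-amino modifiers (the `Y` code) are stripped
before matching and the amplicon termini are marked `amino_blocked`,
which is why they are never labeled in step 2 above.

**Vector context.** Only the scaffold-defined flanks of the genome are
reconstructed; the reverse-primer site lies beyond them in vector
sequence the printed oligos do not determine. `defaultVectorContext()`
supplies a short synthetic stand-in ending in the reverse-complement of
the printed reverse primer -- enough for amplicon extraction, and clearly
labeled synthetic.

**Competitor fixture.** The printed 25-mer competitor insert does not by
itself carry the restriction context that yields its 13-mer product (that
context comes from a vector construction outside this package's inputs).
`competitorAmplicon()` is therefore a configurable synthetic fixture: a
BbsI site and 2-nt spacer upstream of `GGCGATAAGCTAT` (the 25-mer's 3'
13 nt) followed by the MluCI site, so the BbsI-first scheme releases a
13-nt labeled top fragment and the MluCI-first scheme a 13-nt bottom
fragment, reproducing the internal-standard band without guessing the
true vector sequence.

**Enzyme geometry** is shipped as an editable table
(`extdata/enzymes.tsv`) with REBASE definitions -- EcoRI G^AATTC, MluCI
^AATT, BbsI GAAGAC(2/6) -- expressed as between-base offsets from the
recognition start (coordinates are 0-based, half-open, top-strand frame
throughout). Reproducing the printed 10-mers end-to-end is the check that
these definitions are right.

**Masses.** Standard monoisotopic DNA residue masses; the neutral
baseline is a 5'-OH/3'-OH molecule, each terminal phosphate adds HPO3
(79.96633 Da). The eight alkyl adducts shift the T residue by CnH2n
(14.01565 Da per CH2); the sec-butyl stereoisomers differ only in
registry metadata. A labeled phosphate is treated as 31P because MS only
ever sees dephosphorylated material. CID series: `w` and `a-B` by
default (sufficient to localize one internal substitution), `y` and `d`
on request; the `a-B` neutral is $M(\text{5' } i\text{-mer, 3'-OH}) -
\mathrm{H_2O} - \text{base}_i$.

**MS identification** scores each candidate by presence/absence of its
predicted ions within a ppm tolerance (default 20 ppm; the ion-trap
resolution is configurable, not asserted) plus a precursor match at
charge 3 -- no intensity weighting, mirroring manual assignment. Ties of
the top two candidates within 0.05 are flagged ambiguous.

## What the generator emulates -- and what it does not

`generateRun()` produces expected band intensities -- competitor
&prop; 1, lesion products &prop; $r_\mathrm{lesion}\,\theta\,p_M$,
control &prop; $r_\mathrm{control}$ -- merged by the co-migration rules
and multiplied by independent lognormal noise $e^{N(0,\sigma^2)}$ per
band ($\sigma$ = 0.1 by default; the wet data show only error bars, so
the noise model is a declared assumption). `generatePeaklist()` emits the
predicted precursor and full w/a&minus;B ladder with Gaussian ppm jitter
and optional decoys. Everything is seeded: one seed fixes every
downstream number.

The generator does *not* simulate polymerase kinetics, SOS regulation,
repair, gel smearing, background, or partial digestion. Passing tests
therefore demonstrate that the estimators invert the assay's arithmetic
and its band-assignment logic under the declared noise model -- not that
the wet assay is accurate; the published bypass/mutation percentages are
wet-lab measurements that desk simulation cannot reproduce.

Scenario presets (`scenarioPresets()`) encode the study design -- 2:1
lesion:competitor mixing for Me/Et/nPr/nBu, 5:1 for the poorly bypassed
branched iPr/iBu/sBu lesions (sBu &theta; &asymp; 0.05) -- with
plausible, fixed default parameters; they are study conditions, not
fitted values.

## Numerical and problem-size notes

- Simplex least squares is solved by exhaustive support enumeration
  (15 subsets), exact to machine precision; tiny negative components are
  clamped and renormalized. Ambiguous/degenerate systems fall back to the
  best feasible support.
- Scaffold bridging requires a minimum exact insert overlap of 4 nt (the
  printed scaffold2 overlap is exactly 5 nt); a mismatched scaffold fails
  assembly with the junction named.
- Property tests run 1000 random substrates for digestion conservation,
  200 seeded noisy runs (&sigma; = 0.1, n = 3) for parameter recovery at
  the canonical scenario (&theta; = 0.5, 80% T&rarr;C, 2:1 mixing), and
  100 seeded peak lists at 5 ppm jitter for MS round-trips; the whole
  suite runs in under a minute on one core.

## Worked example

```{r example}
res <- runPipeline(outDir = tempfile("crab"))
res$quantification$bypass
res$quantification$spectrum
```

The shipped default scenario is noise-free, so quantification returns
the configured ground truth exactly (50% bypass, 80% T&rarr;C); set
`sigma` in the configuration to explore noisy recovery.

## Known limitations

- The competitor amplicon and the vector context beyond scaffold reach
  are synthetic fixtures, not the true vector sequence.
- Gel mobility is a declarative rule table; new species fall back to
  pure length classes unless rules are added.
- No isotope envelopes, chromatography, or intensity models on the MS
  side; identification is presence/absence only.
- The lognormal band-noise model is an assumption; real gel noise may be
  heavier-tailed or correlated within a lane.
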