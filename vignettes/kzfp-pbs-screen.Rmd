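---
title: "Screening KZFPs that target retroviral primer-binding sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening KZFPs that target retroviral primer-binding sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kzfpscreen)
```

## The biological problem

Endogenous retroviruses (ERVs) replicate through reverse transcription
primed by a host tRNA that anneals to an 18-nucleotide primer-binding site
(PBS) immediately downstream of the 5' long terminal repeat (LTR). Because
the PBS must stay complementary to the 3' end of a specific tRNA, it is one
of the most conserved parts of a retroviral genome, and its sequence names
the PBS type: PBS-Pro, PBS-Lys, and so on. KRAB zinc-finger proteins
(KZFPs) exploit this constraint: a KZFP whose C2H2 array recognises a PBS
sequence can silence every provirus of that family at once by recruiting
KAP1/TRIM28 and H3K9me3 machinery.

`kzfpscreen` implements the computational side of finding such proteins as
a reusable, testable pipeline with two arms:

* **Arm A (ChIP-based):** KZFPs with ChIP-seq peak sets are ranked by how
  many of their strong peaks fall on annotated PBS loci.
* **Arm B (no ChIP data):** the remaining KZFPs are screened by the
  temporal co-occurrence of their gene age with the invasion window of the
  PBS-containing ERV subfamily, then by the match between their predicted
  DNA-binding motif and the PBS; fingerprint similarity to declared
  reference binders is reported alongside.

Every stage can be exercised on synthetic data with known ground truth, so
the pipeline's behaviour is verifiable end to end without any downloads.

## PBS derivation, classification and scanning

A PBS consensus is the reverse complement of the 3'-terminal 18 nt of the
priming tRNA (`derive_pbs_from_trna()`). Classification of an 18-mer
(`classify_pbs()`) minimises Hamming mismatches over a catalog of types; N
counts as a mismatch, and ties are reported as ambiguous rather than
resolved silently. The bundled catalog (`default_pbs_catalog()`) carries a
PBS-Pro consensus whose first nine nucleotides are the conserved
`TGGGGGCTC` nine-mer, a PBS-Lys consensus matching the widely used
tRNA-Lys3 3' end, and three synthetic decoy types (Leu/Phe/Trp labels)
built to differ from PBS-Pro within the first nine nucleotides —
`pbs_distinctiveness()` quantifies this separation (Hamming distance at
least 4 over the first nine positions).

`scan_pbs()` reports every 18-mer window within `max_mismatch` (default 3)
of any catalog entry, on both strands. The confidence score is
`round(100 * (18 - mismatches) / 18)` plus a +10 positional bonus when the
hit starts within 20 bp downstream of an annotated 5'-LTR end. The formula
used by provirus-annotation software for its published PBS scores is not
public, so this score is a declared stand-in with one deliberate property:
*"score > 100"* — the conventional high-confidence filter — is achievable
only by an (almost) exact match sitting in the expected proviral position.
Counts of high-confidence loci in real genomes therefore depend on that
software's internals and are not comparable quantities for this package.

Windows with more than six Ns are skipped; when several types match one
window the minimal-mismatch type is kept with an alphabetical tie-break,
which keeps output deterministic.

## C2H2 detection, fingerprints and the recognition code

`find_c2h2()` matches the classical pattern `C-x(2,4)-C-x(12)-H-x(3,5)-H`
left to right with lazy quantifiers (earliest start, shortest stretch).
Only the C–C and H–H stretches vary; the spacer between the second
cysteine and the first histidine is fixed at 12 residues. That fixed
spacer is what makes the fingerprint well defined: the DNA-contacting
residues at recognition-helix positions −1, 2, 3 and 6 sit at offsets −7,
−5, −4 and −1 from the first histidine (helix position 7). A literal
reading of "positions −1, 2, 3 and 6 relative to the first histidine" as
sequence offsets from the histidine itself would contradict the canonical
Zif268 finger-1 fingerprint; the helix-numbering interpretation recovers
the textbook `RDER` from the RSDELTR helix, which is the validation we
anchor on.

`fingerprint_similarity()` aligns two ordered fingerprint lists with a
dynamic program whose unit is a whole finger: aligned fingers score the
number of positionally identical residues (0–4), gaps score 0, and fingers
are never reordered. Similarity is `100 * score / (4 * max(n_a, n_b))`, so
extra unmatched fingers dilute similarity — a deliberately conservative
denominator for a screening context where "similar" should mean "similar
along the whole array". How the published "<50%" fingerprint-similarity
comparisons were computed is not stated anywhere we could consult, so this
definition is declared rather than inferred, and the threshold is a
configuration knob (`fingerprint_sim_max`, default 50).

`predict_motif()` maps each fingerprint to a DNA triplet through a
recognition code and emits triplets in reverse finger order — the
C-terminal finger binds the 5'-most triplet. Both the consensus and its
reverse complement are retained, because a ChIP-derived motif may match
either strand of a prediction. The shipped code
(`default_recognition_code()`) is generated from four canonical base
contacts (Arg–G, Asn–A, Glu–C, Thr–T at helix positions −1, 3 and 6, Asp
held at position 2), covering all 64 triplets and therefore invertible,
plus the classical Zif268 `RDHT→TGG` alias. It is a small documented
table, not a reconstruction of any external prediction server; users can
load their own with `load_recognition_code()`. Unknown fingerprints map to
`NNN` and are flagged, and N positions are excluded from both numerator
and denominator of `motif_vs_pbs()` match fractions.

## Needle-style pairwise alignment

`global_align()` wraps Needleman–Wunsch alignment with affine gaps
(Biostrings' optimal implementation) and reports percentages the way
EMBOSS Needle prints them: identity and similarity over the full alignment
length *including* end-gap columns, similarity counting columns whose
substitution score is strictly positive. Defaults are BLOSUM62, gap open
10, gap extend 0.5, end gaps free — the Needle defaults. A gap of length L
costs `open + L * extend`. When both sequences have unaligned overhangs at
the same end under free end gaps, the overhangs are emitted as stacked
end-gap columns (same score; the percentage denominator may differ by a
few columns from a tool that forces overhang residues into aligned
columns). Traceback choices inside the DP engine are deterministic, so
results are reproducible bit for bit.

The DNA matrix is +5/match, −4/mismatch with N scoring 0 against
everything; BLOSUM62 is shipped unmodified (its X scores are all
non-positive), since modified matrices would break comparability with
standard Needle output.

## LTR dating and invasion profiles

The two LTRs of a provirus are identical at integration, so their
divergence clocks the insertion. `ltr_divergence()` aligns the pair (DNA
matrix, free end gaps) and takes the raw p-distance over columns where
both rows are non-gap and non-N; gap columns are excluded from both
numerator and denominator, and pairs with a gap fraction above 20% are
flagged low-confidence. The calibration is the linear rule *0.4%
divergence = 1 Myr* (`insertion_age()`); because the clock is stated as a
linear rule, the default distance is uncorrected, with Jukes–Cantor
correction behind a flag (at the divergences relevant here, ≤ a few
percent, the two agree closely).

`invasion_profile()` bins ages (default 5 Myr) and reports the peak
window: the maximal contiguous run of bins containing the modal bin whose
counts all reach 50% of the modal count. The 50% rule is this package's
declared definition — published invasion-peak figures give none.

## Gene ages and co-occurrence

`estimate_age()` implements ortholog-based dating: a gene's age is the
divergence time from the reference species to the most distant species
carrying an ortholog. Reliability is flagged `low` when fewer than half of
the species *younger* than the oldest ortholog also carry one (a patchy
distribution suggests losses or annotation gaps); the 50% patchiness
threshold is a declared proxy for the unspecified "reliability" marking of
published age tables and is configurable. `cooccurrence_screen()` keeps
genes whose age falls inside the invasion peak window widened by a
tolerance (default 10 Myr on each side — the width of two histogram bins,
declared here since no published tolerance exists), sorted by distance to
the window midpoint.

## Peak overlaps

Coordinates are 0-based half-open everywhere (BED native). `read_bed()`
is a small validating parser that reports malformed lines by number.
Overlap counting (`count_overlaps_report()`) uses an interval index
(GenomicRanges) and counts each peak once even when it spans several PBS
loci — rankings count *peaks*, the reading we adopt for published
top-binder counts — while also emitting the per-PBS count, since the
alternative reading is defensible. Strand is ignored (ChIP peaks are
unstranded). `filter_peaks()` is strictly greater-than, matching the
"score > 500" (GFP) and "> 300" (HA) strong-peak conventions;
`rank_binders()` breaks ties by mean peak score at overlaps, then name.

## The synthetic-data generator

`simulate_genome()` plants proviruses (5'LTR + PBS + internal + 3'LTR;
defaults 1 kb LTRs, 1.5 kb internal) in a random background genome
(default 100 kb, 10 ERVs). Both LTR copies are mutated independently at a
per-site probability chosen so that the *expected observed p-distance*
equals `age × 0.4%` exactly: the naive rate `age × 0.004 / 2` per copy
undershoots slightly because two independent hits at one site can
coincide, so the generator solves `1 − (1 − q)² − q²/3 = d` for `q`. PBS
mismatches are planted outside the conserved first nine nucleotides by
default, mirroring the observed conservation pattern of PBS-Pro. Default
insertion ages are drawn from a truncated Normal(30, 3) Myr, matching the
reported invasion window of the PBS-Pro ERV subfamily (~30 Myr ago).

`simulate_kzfp_panel()` builds proteins as a KRAB-like scaffold plus a
C2H2 array whose spacers carry chosen fingerprints; scaffold and linkers
contain no C or H, so the scanner finds exactly the constructed fingers.
The planted binder's fingerprints are obtained by inverting the
recognition code against the PBS (finger order reversed), making the
motif-prediction round trip exact by construction; decoys draw random
code-table fingerprints and are regenerated until their motif matches the
PBS below 0.5. `simulate_peaks()` centres binder peaks on 90% of PBS loci
(width 200–400 bp, scores 600–1000) and scatters equally many uniform
decoy peaks (scores 100–1000). `simulate_ortholog_table()` places
orthologs exactly in species within the planted age over an 11-species
divergence ladder (6–160 Myr, in the spirit of TimeTree medians), with
optional patchy dropouts to exercise the reliability flag. All generators
are pure functions of their parameters and seed.

### What the simulator does and does not emulate

It reproduces the *logical* structure of the real inputs — provirus
geometry, clock-calibrated LTR decay, PBS conservation, code-consistent
binder fingerprints, PBS-concentrated binder peaks, age-consistent
ortholog distributions. It does not emulate nucleotide composition bias,
nested or truncated ERVs, solo LTRs, indel evolution in LTRs, ChIP
background structure, finger spacers other than 12, or fingerprint/code
mismatches arising from non-canonical contacts. Tests passing on
synthetic data therefore demonstrate correctness of the computations and
the recoverability of planted signal under the stated noise model — not
performance on real genomes, where annotation quality and the external
recognition code dominate.

## Problem sizes and numerical choices

The test suite and the acceptance script run the screen at 20 KZFPs × 10
ERVs × 100 kb genome, sweep 20 seeds for end-to-end recovery, date 80
1-kb LTR pairs across ages {1, 5, 10, 30} Myr, and verify alignment scores
against exhaustive enumeration on hundreds of short pairs — sizes chosen
so the full suite completes in about two minutes on one core while leaving
each statistical check enough replication to be meaningful. Determinism:
all randomness flows from explicit seeds; scanning, ranking and screening
are deterministic given their inputs, with stated tie-breaks
(alphabetical type on equal mismatches, name on equal rank scores).

## Known limitations

* The recognition code is intentionally minimal; predictions for real
  KZFPs require loading a richer user-supplied table.
* The PBS confidence score is a stand-in; absolute score values are
  comparable only within this package.
* Fingerprint-similarity values depend on the declared alignment scheme
  and denominator; other reasonable definitions give different numbers.
* Ortholog-based ages are lower-bounded by annotation completeness and
  snap to the species divergence ladder; the estimator cannot resolve ages
  between adjacent ladder steps.
* Reproducing published pairwise-similarity percentages for specific
  protein pairs requires those exact sequences, which are not bundled.
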