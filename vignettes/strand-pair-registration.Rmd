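---
title: "Registration of paired beta-strands: model, statistics and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration of paired beta-strands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandpairs)
```

## The problem

Two adjacent strands of a beta-sheet are held together by a ladder of
backbone hydrogen bonds, but their ends rarely coincide: one strand
usually overhangs the other. Given DSSP secondary-structure assignments,
this package quantifies that registration. For a pair of strands of
lengths $SL_1$ and $SL_2$ (residues), the bridge-partner annotations
define a *common paired part* of length $PL$ — the residues of each
strand that have a bridge partner in the other — leaving *terminal
extensions* $Et_1 = SL_1 - PL$ and $Et_2 = SL_2 - PL$ and a whole span
$EL = PL + Et_1 + Et_2$. Two per-pair ratios summarise the geometry:

$$R = 100\,\frac{PL}{EL}, \qquad Rt_i = 100\,\frac{PL}{SL_i},\quad i = 1,2 .$$

$R$ is the fraction of the pairing's union that is actually paired;
$Rt_i$ is the fraction of each strand that is paired. Both are carried on
the 0–100 scale throughout. Since $EL \ge \max(SL_1, SL_2)$, always
$R \le \min(Rt_1, Rt_2)$, and all three equal 100 exactly when both
terminals align ($Et_1 = Et_2 = 0$).

Surveys of nonredundant structure sets show that strands strongly prefer
to align at least one pair of terminals and to maximise the common part;
nearly all pairs satisfy the *terminal-alignment rule*

$$R \ge 25\% \quad\text{and}\quad Rt_i \ge 40\%,\ i = 1,2,$$

with all thresholds inclusive. The rule is useful as a hard constraint in
strand-register prediction: candidate offsets violating it can be
discarded before scoring.

## From DSSP text to pairs

The package reads the classic fixed-column DSSP dialect — the variant
carrying BP1/BP2 bridge-partner indices and a sheet label — because the
bridge partners are what define pairing at residue resolution
(`parse_dssp()`, `read_dssp()`). Chain-level preprocessing
(`filter_chains()`) mirrors the survey conventions: chains with no
`'E'` residue are dropped (no beta-sheet to analyse), as are chains
containing residues DSSP could not map to a standard amino acid
(letter `X`); DSSP's lowercase letters for disulfide-bonded cysteines are
standard cysteines and are normalised to `C`, never rejected. A third
published criterion, removal of "uncertain or incorrect" entries, has no
operational definition; the parser enforces structural validity of the
residue table (strictly increasing indices, resolvable bridge partners)
and nothing more.

Strands are maximal runs of `'E'` split at chain breaks
(`extract_strands()`); isolated single bridges (state `'B'`) are not
strands, while single-residue `'E'` runs count. Two strands form a pair
when any residue of one names a residue of the other as bridge partner
(`enumerate_pairs()`). Orientation follows the partner progression along
the first strand — increasing is parallel, decreasing antiparallel; a
single-rung pair is decided by the case of the DSSP ladder letter
(lowercase = parallel), and if none is recorded the pair is classed with
the antiparallel majority under a warning.

A pair is flagged *bulged* when its bridged residues are non-contiguous
in either strand, the two strands bridge unequal residue counts, or the
partner progression is non-monotonic. Published practice excludes bulged
pairs from registration statistics, and that is the default here
(`include_bulged = FALSE` restores them on request; their `PL` is then
the smaller bridged-residue count). Cross-chain pairs are tagged
`interchain` and included by default, since the survey conventions do
not exclude them. When one strand bridges two others, each neighbour
yields its own pair; duplicate links from bifurcated ladders collapse
because `PL` counts distinct residues, not bonds.

## Dataset summaries

`pair_stats()` appends $R$, $Rt_1$, $Rt_2$ and the rule verdict to the
pair table. Four dataset-level views reproduce the standard summary
machinery:

* `length_difference_table()` — pairs cross-tabulated by
  $|SL_1 - SL_2|$ (rows 0–10 and ">10") against the four
  extension-existence cases. Two columns are structurally zero: with
  $Et_1 - Et_2 = SL_1 - SL_2$, equal-length pairs can never have exactly
  one extension, and unequal-length pairs always have at least one.
* `variable_summary()` — min/max/mean/sd of $SL_1, SL_2, PL, Et_1,
  Et_2, EL$. The sample ($n-1$) standard deviation is used; at survey
  scale the alternative differs negligibly, and a lone pair reports 0.
* `ratio_distribution()` — percent of pairs per right-closed bin
  $(lo, hi]$ of width 5 by default; exact 100s land in the top bin so
  every pair is counted once.
* `cumulative_curve()` — $CP(x) = 100\,|\{v \ge x\}|/n$ on a percent
  grid (default step 5), non-increasing with $CP(0) = 100$.

Display rounding is half-up at two decimals (`round_half_up()`), the
convention of printed summary tables; internal computation keeps full
precision. The shipped reference cross-table
(`reference_pair_table()`) carries the published counts and row
percentages of a 2009 culled nonredundant chain survey (19,214 pairs)
and is used for desk-scale arithmetic checks of the aggregation
contract; reproducing its dataset-level percentages from raw structures
would require the original culled chain list plus DSSP runs, which is
out of scope here.

## The synthetic generator

`sample_dataset()` + `render_dssp()` produce DSSP fixtures with known
ground truth, so every stage is testable without downloads. A
configuration is $(SL_1, SL_2, o, \text{orientation})$, where the offset
$o$ shifts strand2's pairing frame against strand1's first residue; for
antiparallel pairs the frame runs along strand2's reversed sequence, so a
single interval-overlap closed form covers both orientations:

$$PL = \min(SL_1,\, o + SL_2) - \max(0,\, o).$$

Default sampling parameters are fixed study conditions chosen from the
published tables, not tuning knobs:

* **Lengths.** Paired strands have strongly correlated lengths (the
  published cross-table has 29.5% of pairs equal-length, decaying by
  ~0.55 per extra residue of difference — far tighter than independent
  draws would give). Lengths are therefore drawn as a shared core plus
  independent Geometric($p = 0.46$) extensions,
  $SL_i = \text{core} + e_i$, with the core $1 +$ negative binomial
  sized so each marginal hits mean 4.99 and sd 2.82, truncated to
  $[1, 25]$. For iid geometric extensions
  $P(SL_1 = SL_2) = p/(2-p) = 0.30$ and the difference decays by
  $1 - p = 0.54$ per residue, matching the published decay.
* **Offsets.** With probability 0.83 (the published both-terminal
  alignment rate among equal-length pairs) the offset falls uniformly in
  the *containment range* — the offsets that pair the shorter strand
  completely, aligning at least one terminal. Otherwise an overhang of
  $k = 1 + \text{Geom}(0.5)$ rungs is applied to a random side. An
  overhang leaves $PL = \min(SL_1, SL_2) - k$, and the draw keeps at
  least two rungs wherever the lengths allow: a single-rung ladder is an
  isolated bridge, which DSSP labels `'B'`, so an isolated two-strand
  ladder with $PL = 1$ could never present as two `'E'` strands in real
  DSSP output. (`make_pair_config()` itself accepts any $PL \ge 1$ for
  oracle sweeps.)
* **Orientation.** 70% antiparallel, the typical excess of antiparallel
  pairing in globular folds; the surveys do not publish the mix.
* **Bulges.** Off by default (the summaries exclude them anyway); at
  rate $b$, an eligible pair ($PL \ge 3$) has one interior rung's bridge
  deleted, which the pipeline must re-flag as bulged.

Under these defaults the emergent population statistics land close to
the published ones without being fitted: mean $PL \approx 4.0$,
$Et_i \approx 0.96$, rule-pass fraction $\approx 91\%$, and cumulative
percentages at the rule thresholds of roughly 97/95/95 against the
published 96.97/94.26/95.98. One published inconsistency is worth
recording: the survey's summary table prints mean $SL_1 = 4.99$,
$PL = 4.86$ and $Et_1 = 1.15$ simultaneously, which no dataset can
satisfy under the identity $Et_1 = SL_1 - PL$; the generator anchors the
$SL$ marginals, the difference decay and the alignment probability, and
lets the $PL/Et/EL$ means follow from the geometry.

What the generator does *not* emulate: multi-strand sheets (each
configuration is an isolated two-strand ladder, so sheet-graph features
like bifurcations arise only in hand-built test fixtures), hydrogen-bond
energetics, sequence propensities, and any coupling between offset and
length beyond the containment constraint. Passing tests therefore
validate the bookkeeping — parsing, pairing, registration arithmetic,
summaries — under controlled truth, not the biological claims about real
sheets.

Rendering writes each configuration as two `'E'` runs separated by
four-residue coil linkers (so runs never merge), wires BP1 both ways,
and cycles sheet and ladder letters. Classic DSSP columns hold bridge
partners in four digits, so `render_dssp()` splits large datasets into
multiple files, each below 10,000 residues. Amino-acid letters are drawn
uniformly from the 20 standard residues under a seed derived from the
dataset seed; sequence content is irrelevant to every implemented
statistic. All sampling restores the caller's RNG state, and identical
seeds give byte-identical output. `emit_dssp()` writes residues at their
stored indices and emits a break line at every skipped index, exactly as
DSSP numbers breaks, so parse–emit round trips are field-identical.

## Numerical and design notes

* Percent values live on 0–100 everywhere; no 0–1 scale appears in any
  interface.
* Rule thresholds are inclusive ($\ge$); boundary behaviour is probed in
  the tests at $\pm\varepsilon$ around each face.
* Strand1 of a pair is the strand earlier along the chain (for
  cross-chain pairs, earlier in file order). DSSP input carries no PDB
  SHEET numbering, so N-terminal order is the deterministic stand-in.
* Histograms error on bin widths that do not divide 100 rather than
  silently rebinning.
* Empty inputs: filtering an empty set succeeds; `variable_summary()`
  refuses ("no pairs"); the cross-table returns all-zero counts.
* Problem sizes in the shipped tests — an exhaustive offset sweep over
  all length pairs up to 12, a 1,000-pair end-to-end recovery run, a
  100,000-pair calibration sample — were chosen to exercise every code
  path at desk scale; the whole suite runs in well under a minute.

## Validation layout

The test suite asserts, per module: parser column positions against an
independently written formatter; emit–parse round trips on generator
output; the chain filters and their idempotence; strand segmentation
against a brute-force run oracle; pair counts on hand-built ladders and
a 10-strand, 3-sheet topology; registration against the closed form on
random and exhaustive sweeps; the ratio identities, structural zeros,
histogram/cumulative consistency; and end-to-end truth recovery with
zero mismatches. `scripts/acceptance.R` re-runs the pipeline from
scratch under a caller-supplied seed and writes the headline quantities
as JSON.
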