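---
title: "famtrend: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famtrend: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famtrend)
```

## The problem

Consensus design replaces residues of a working protein (the *parent*) by
the most common residue at each position of its family alignment. When the
redesigned protein (the *mutant*) loses function, every position where it
was moved onto the consensus is a suspect. `famtrend` operationalizes the
mining workflow that narrows the suspect list: diff parent against mutant,
keep the substitution columns where the mutant agrees with a strongly
conserved family consensus, annotate position pairs that are symmetric
about the sequence midpoint, and — when a structure is available — measure
how close the remaining candidates sit to the active site.

This vignette documents the models, the tunable parameters, the synthetic
data world, and the numerical decisions. It intentionally states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves recompute.

## Data model

An `aligned_family` holds `n` equal-length rows over the alphabet of the
20 standard one-letter residue codes, `X` (unknown) and `-` (gap). Two
kinds of `-` are distinguished *positionally*: maximal leading/trailing
gap runs are **terminal filler** (alignment padding, drawn gray in trend
images), everything else is an **internal gap** (drawn white). The source
alignment format does not distinguish them, so a purely positional rule is
the only reproducible one; an all-gap row is attributed entirely to the
leading run by convention.

`X` is treated conservatively everywhere: it belongs to no classification
scheme, and it **never matches any residue, itself included**, in any
similarity or consensus computation. One consequence worth knowing: plain
edit distance between two strings containing `X` at the same position is
positive, so the identity-of-indiscernibles axiom holds only on `X`-free
strings (the acceptance checks use `X`-free alphabets). Another: the
reference-match profile is reported as undefined (`NA`) at columns where
the reference carries `X`, exactly as at reference gaps — otherwise its
"defined values lie in (0, 1]" contract would break.

## Residue classification schemes

Four partitions of the 20 residues drive coloring and the weighted edit
distance. The literature names the scheme families but not exact
memberships, so the package fixes standard textbook groupings:

* `chemical`: aliphatic GAVLIP / aromatic FYW / sulfur CM / hydroxyl ST /
  basic KRH / acidic+amide DENQ.
* `polarity`: nonpolar GAVLIPFMW / polar-uncharged STCYNQ / polar-charged
  DEKRH.
* `charge`: positive KRH / negative DE / neutral (rest). Histidine is
  counted positive by convention; it is only partially protonated at
  physiological pH, and nothing downstream depends on the choice.
* `solvent_contact`: hydrophobic/buried = positive Kyte–Doolittle
  hydropathy (AVLIMFC) vs hydrophilic/exposed (rest) — a reproducible
  proxy for "side-chain contact with polar solvent".

Colors are fixed from the Okabe–Ito colorblind-safe palette and recorded
in the legend TSV written next to every raster. Three colors are invariant
across schemes: gap white `(255,255,255)`, terminal filler gray
`(190,190,190)`, unclassified black `(0,0,0)`.

`fragment_frequency` is *not* a partition: it colors each trend-image cell
by the frequency of that cell's own residue within its column (among
non-gap entries), binned into 5 sequential blues with edges at
0.2/0.4/0.6/0.8. The closed-right binning puts frequency 0.5 in bin 3 and
frequency 1 in the top bin.

## Similarity weights

All string distances operate on **degapped** sequences — the alignment is
a display and selection artifact, not part of the metric. The seven
weights:

1. *Edit distance*: Levenshtein with unit costs (C++ kernel; the test
   oracle is an independent pure-R dynamic program).
2. *Weighted edit distance*: substitution costs 0 (identical), 0.5
   (different residues, same class of the chosen partition scheme;
   default `polarity`), 1 (otherwise, including any `X`); indels cost 1.
   The published description names the weight but not the cost model;
   class-based discounting is this package's choice, consistent with its
   own residue classifications, and is configurable by scheme. The
   weighted distance never exceeds the plain one.
3. *Common residues (positional)*: columns where both rows carry the
   identical non-`X` residue; gap–gap columns never match.
4. *Common residues (compositional)*: multiset intersection of the two
   degapped compositions. Percentages divide by the shorter degapped
   length (symmetric, bounded by 100, zero when empty).
5. *Shared n-grams*: distinct contiguous length-`n` substrings present in
   both degapped sequences (default `n = 3`). Distinct-set counting is
   used because occurrence-pairing is ill-defined for repeats.
6. *Fragment frequency*: fraction of family rows with a
   character-identical aligned substring over a column window (default:
   the full width, since the original tool leaves the no-paddle case
   unspecified). Needs no reference sequence.
7. *Selected-column edit distance*: project both rows onto a chosen column
   set, degap each projection independently, then edit distance.

`sort_family()` orders ascending for the three distance weights (the
reference row weighs 0 and ranks first) and descending for the rest, with
ties broken by input row order so rendering is bit-reproducible.

## Consensus, conservation, candidates

Per-column frequencies are computed over non-gap entries by default (a
gap-inclusive mode exists by flag) because consensus-design mutations are
residue-to-residue. The consensus residue is the per-column mode with
alphabetical tie-break; "almost fully conserved" is a configurable
threshold defaulting to 0.9. `conserved_columns()` additionally requires
at least half the rows to be non-gap, so filler-heavy termini cannot
masquerade as conserved columns. The reference-match profile includes the
reference itself in its denominator.

`consensus_candidates()` keeps exactly the columns where parent and mutant
both carry residues and differ (indel columns are counted by
`diff_runs()` but are not candidates — the workflow targets substitutions
toward consensus), and ranks by descending consensus frequency then
column. Symmetric pairs are computed in the **parent's degapped residue
numbering**, not alignment columns: "equal offset from either end" is a
property of the protein, and alignment padding would break the arithmetic
`i + j = L + 1`. The exact center position of an odd-length protein never
pairs with itself. Pair members are annotated in the report, never
dropped: the inference that symmetric conserved pairs are benign is domain
judgment, not algorithm.

## Trend raster

One pixel block per cell, `row_scale x col_scale` (default 1×1, the
original abstraction's scale). Cell color depends only on the cell's
character, the scheme, the row's filler mask and the paddle windows, which
is verified by a permutation-equivariance test. At most two paddle windows
may be overlaid — mirroring the two fragment paddles of the interactive
tool, which proved necessary to inspect both members of a symmetric pair
simultaneously — and the overlay darkens by a factor 0.7 rather than
recoloring, keeping class hues readable. PNG encoding is deterministic;
the acceptance suite asserts byte-identical files across repeated renders.

## Structure mapping

`map_columns_to_structure()` uses a semiglobal Needleman–Wunsch (match +1,
mismatch −1, gap −2, terminal gaps free) between the degapped family row
and the chain sequence extracted from PDB `ATOM` records (heavy atoms
only; first altloc; insertion codes kept in the residue key). Free
terminal gaps accommodate truncated constructs; mismatched aligned
positions are mapped but flagged, covering point mutations between the
sequence record and the deposited structure. Below 30% alignment identity
the mapping refuses (likely the wrong chain); the floor is a safety
default and is overridable. Note a consequence of the scoring: for truly
unrelated sequences the optimal semiglobal alignment is empty, so the
refusal triggers via 0% identity rather than via a forced bad alignment.

`site_proximity()` is the exact minimum over all heavy-atom pairs of the
Euclidean distance — no neighbor-list approximation is warranted at
protein scale — and the active-site residue set is always a user input,
since no canonical set ships with a family alignment.

## The synthetic world

`generate_family()` states the world the tests live in: `n = 200` rows of
length `L = 250` (the scale of a triosephosphate-isomerase-like family
alignment), i.i.d. per-column substitution noise at rate 0.05 (uniform
over the 19 other residues), a uniformly drawn planted consensus, and
planted candidates constructed exactly like a consensus redesign: the
mutant *is* the consensus at planted positions, the parent is reverted to
a different residue there. Symmetric plants occupy `(k, L + 1 - k)`. All
randomness flows from one seed through `withr::with_seed`, so identical
seeds give byte-identical FASTA output.

At rate 0.05 and `n = 200`, each non-consensus residue appears in a
column with expected count ≈ 0.5 versus ≈ 190 for the consensus residue,
so exact consensus recovery and perfect candidate precision/recall are
properties of the stated world, not tuned outcomes; the acceptance suite
checks them across 20 seeds. What the generator deliberately does *not*
emulate: phylogenetic correlation between rows, column-dependent
conservation levels, and indels (the generated alignment is gap-free;
gap/filler behavior is exercised by hand-built alignments instead). A
green recovery test therefore establishes correctness of the machinery on
i.i.d. noise, not robustness to tree-structured redundancy — real
families need the redundancy-aware eye the threshold parameter gives the
analyst.

## Numerical and interface conventions

* Alignment columns are 1-based inclusive in every user-facing output;
  internal code may be 0-based.
* All ties anywhere (sorting, consensus, modal residues) break
  deterministically (input order / alphabetical).
* TSV outputs carry a `# famtrend <version> | key=value ...` header line;
  every CLI run logs its parameters to stderr with timestamps.
* CLI exit codes: 0 success, 1 data error, 2 usage error.
* The full-pairs exhaustive diff check is limited to alignment length 4
  (6561 joint column states per length) and complemented by seeded random
  pairs up to length 12; the joint space at length 12 (~10^11 pairs) is
  not enumerable.

## Known limitations

Edit distances are quadratic-time exact dynamic programs — fine for
protein-length strings, unsuitable for genomic scales. The PDB reader
parses `ATOM` records of single-model files only (no mmCIF, no model
selection). The fragment-frequency sorting weight uses the full alignment
width when no window is given, which makes it nearly constant across rows
of very diverse families; narrow the window for discrimination. No
sequence-weighting scheme corrects for family redundancy, and no
entropy-based conservation score is provided — the modal-frequency
threshold is the only conservation notion.
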