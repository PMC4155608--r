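# famtrend

Mining protein families for the mutations that matter — without a GUI.

When a protein is mutated toward its family consensus ("consensus design")
and the redesign loses function, the interesting question is *which* of the
many substitutions broke it. `famtrend` provides the computational backbone
for that investigation on a protein-family multiple sequence alignment
(MSA):

- **Trend images** — a pixel-per-residue raster of the whole family (one
  pixel row per sequence, one pixel column per alignment position), colored
  by side-chain chemistry, polarity, charge, solvent contact, or per-column
  residue frequency. Internal alignment gaps render white, terminal filler
  gray, unclassified residues black.
- **Similarity sorting** — seven weights rank every family member against a
  chosen reference: Levenshtein edit distance `d(a,b)`, a class-weighted
  edit distance (substitutions within a physicochemical class cost 0.5
  instead of 1), counts/percentages of common residues with and without
  regard to position, shared distinct *n*-grams, fragment frequency over a
  column window, and edit distance restricted to selected columns.
- **Family statistics** — per-column residue distributions, the consensus
  sequence (per-column modal residue), conservation above a threshold, and
  the per-column fraction of the family agreeing with a reference.
- **Mutation mining** — maximal runs of difference between a parent and a
  mutant row; candidate columns where the mutant departs from the parent
  *but agrees with the family consensus*; and terminus-symmetric pairs of
  mutated positions `i + j = L + 1`, which field experience flags as
  conserved features rather than causes of functional loss.
- **Structure mapping** — semiglobal alignment of a family row onto a PDB
  chain, and minimum heavy-atom distances from candidate residues to a
  user-specified site (e.g. the active site), with a selection-string
  export for external 3D viewers.
- **Synthetic fixtures** — a seeded generator that plants a consensus,
  substitution noise, candidate positions, and symmetric pairs, so the
  whole pipeline is testable offline with known ground truth.

## Worked example

```r
library(famtrend)

# A 200-sequence family of 250-residue proteins, 5% substitution noise,
# three planted candidate positions and one symmetric pair at offset 22.
fx <- generate_family(n = 200, L = 250, sub_rate = 0.05,
                      candidates = c(10, 60, 125), sym_offsets = 22,
                      seed = 1)

cand <- consensus_candidates(fx$family, fx$parent$seq, fx$mutant$seq,
                             threshold = 0.9)
head(cand[, c("column", "parent_res", "mutant_res",
              "consensus_res", "consensus_freq", "highly_conserved")])
#>   column parent_res mutant_res consensus_res consensus_freq highly_conserved
#> 1     10          S          L             L          0.980             TRUE
#> 2    125          R          E             E          0.955             TRUE
#> 3     22          F          L             L          0.945             TRUE
#> 4    229          M          R             R          0.945             TRUE
#> 5     60          F          T             T          0.930             TRUE

symmetric_pairs(cand, nchar(fx$parent$seq))
#>   pos_i pos_j offset
#> 1    22   229     22
```

Every candidate column is a position where the mutant was moved onto the
family consensus (`consensus_freq` is the fraction of non-gap family
entries carrying that residue); positions 22 and 229 sit at the same
offset from either end of the 250-residue protein (22 + 229 = 251), so
they are annotated as a symmetric pair. Render the family sorted by
weighted edit distance from the first sequence:

```r
sr <- sort_family(fx$family, "seq0001", metric_spec("weighted_edit"))
write_raster(render(fx$family, sr, scheme = "polarity",
                    paddles = list(c(20, 25), c(227, 232))),
             "trend.png")   # + trend_legend.tsv, trend_order.tsv
```

## Command line

```sh
Rscript -e 'quit(status = famtrend::cli_dispatch())' \
  fixtures --n 200 --length 250 --rate 0.05 --seed 1 --out fx/
Rscript -e 'quit(status = famtrend::cli_dispatch())' \
  candidates --alignment fx/family.fasta --ref fx/parent.fasta \
  --alt fx/mutant.fasta --threshold 0.9 --out out/
```

(or use the installed `cli/famtrend` launcher script). Subcommands: `sort`,
`render`, `consensus`, `distribution`, `diff`, `candidates`, `symmetric`,
`map`, `near-site`, `fixtures`. Exit status 0 = success, 1 = data error,
2 = usage error.

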