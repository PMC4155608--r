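test_that("diff runs are maximal contiguous blocks with typed counts", {
  d <- diff_runs("ACDEFG", "ACNEFG")
  expect_equal(d$n_runs, 1L)
  expect_equal(d$runs$start, 3L)
  expect_equal(d$runs$end, 3L)
  expect_equal(d$n_diff_cols, 1L)

  d2 <- diff_runs("ACDEFG", "AXDYFG")
  expect_equal(d2$n_runs, 2L)
  expect_equal(d2$runs$start, c(2L, 4L))
  expect_equal(d2$runs$end, c(2L, 4L))

  expect_equal(diff_runs("ACDE", "ACDE")$n_runs, 0L)
  expect_error(diff_runs("AC", "ACD"), "length")

  # created (gap in ref) and deleted (gap in alt) columns; gap-gap inert
  d3 <- diff_runs("A--CD-", "AKW-D-")
  expect_equal(d3$n_runs, 1L)
  expect_equal(d3$runs$start, 2L)
  expect_equal(d3$runs$end, 4L)
  expect_equal(d3$runs$n_ins, 2L)   # ref gap, alt residue
  expect_equal(d3$runs$n_del, 1L)   # ref residue, alt gap
  expect_equal(d3$runs$n_sub, 0L)
})

test_that("swapping ref and alt preserves runs, swaps created/deleted", {
  set.seed(31)
  for (rep in 1:30) {
    fam <- rand_family(2, 20, gap_prob = 0.25)
    a <- fam$rows[1]; b <- fam$rows[2]
    d1 <- diff_runs(a, b); d2 <- diff_runs(b, a)
    expect_equal(d1$runs[, c("start", "end")], d2$runs[, c("start", "end")])
    expect_equal(d1$runs$n_ins, d2$runs$n_del)
    expect_equal(d1$runs$n_sub, d2$runs$n_sub)
    expect_equal(d1$n_diff_cols, d2$n_diff_cols)
    # run lengths sum to the straight per-column difference count
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    expect_equal(sum(d1$runs$end - d1$runs$start + 1), sum(ca != cb))
  }
})

test_that("consensus candidates flag consensus-restoring substitutions", {
  # family of 20: column 3 is D in 19 rows, K in one
  rows <- c(rep("AKDWE", 19), "AKKWE")
  fam <- aligned_family(sprintf("s%02d", 1:20), rows)
  parent <- "AKKWE"   # parent carries K at column 3
  mutant <- "AKDWE"   # mutant restores the consensus D
  cand <- consensus_candidates(fam, parent, mutant, threshold = 0.9)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$column, 3L)
  expect_equal(cand$parent_res, "K")
  expect_equal(cand$mutant_res, "D")
  expect_equal(cand$consensus_res, "D")
  expect_equal(cand$consensus_freq, 0.95)
  expect_true(cand$mutant_matches_consensus)
  expect_false(cand$parent_matches_consensus)
  expect_true(cand$highly_conserved)
})

test_that("candidates skip equal and indel columns; flags track consensus", {
  rows <- rep("AKDWE", 10)
  fam <- aligned_family(sprintf("s%02d", 1:10), rows)
  # column 1 equal; column 3 parent-mutant differ, mutant off-consensus;
  # column 5 indel in mutant -> skipped
  cand <- consensus_candidates(fam, "AKKWE", "AKYW-")
  expect_equal(cand$column, 3L)
  expect_false(cand$mutant_matches_consensus)
  expect_false(cand$parent_matches_consensus)
  expect_error(consensus_candidates(fam, "nope_zz", "AKYWE"), "neither")

  # parent ids resolve from the family too
  fam2 <- aligned_family(c("p", "m", "o1", "o2"),
                         c("AKDE", "AADE", "AADE", "AADE"))
  cand2 <- consensus_candidates(fam2, "p", "m")
  expect_equal(cand2$column, 2L)
  expect_true(cand2$mutant_matches_consensus)
})

test_that("candidate ranking is by descending frequency then column", {
  rows <- c(rep("KADE", 8), "KGDE", "WGDE")
  fam <- aligned_family(sprintf("s%02d", 1:10), rows)
  # col1: K 0.9; col2: A 0.8 -> parent differs from both at cols 1,2
  cand <- consensus_candidates(fam, "RWDE", "KADE")
  expect_equal(cand$column, c(1L, 2L))
  expect_true(cand$consensus_freq[1] >= cand$consensus_freq[2])
})

test_that("symmetric pairs satisfy i + j = L + 1", {
  p <- symmetric_pairs(data.frame(parent_pos = c(22, 219)), 240)
  expect_equal(nrow(p), 1L)
  expect_equal(p$pos_i, 22L)
  expect_equal(p$pos_j, 219L)
  expect_equal(p$offset, 22L)

  expect_equal(nrow(symmetric_pairs(data.frame(parent_pos = integer(0)),
                                    240)), 0L)
  expect_equal(nrow(symmetric_pairs(data.frame(parent_pos = c(10, 100)),
                                    240)), 0L)
  # the exact center never pairs with itself (odd L)
  expect_equal(nrow(symmetric_pairs(data.frame(parent_pos = 120), 239)), 0L)
  # every reported pair satisfies the arithmetic exactly
  set.seed(13)
  pos <- sample(1:300, 40)
  pr <- symmetric_pairs(data.frame(parent_pos = pos), 300)
  if (nrow(pr)) expect_true(all(pr$pos_i + pr$pos_j == 301))
})

test_that("candidate reports annotate partners without dropping rows", {
  cand <- data.frame(column = c(5, 10, 22), parent_pos = c(5, 10, 22),
                     parent_res = c("K", "A", "E"),
                     mutant_res = c("D", "G", "Q"),
                     consensus_res = c("D", "G", "Q"),
                     consensus_freq = c(0.99, 0.80, 0.95),
                     parent_matches_consensus = FALSE,
                     mutant_matches_consensus = TRUE,
                     highly_conserved = c(TRUE, FALSE, TRUE))
  pairs <- symmetric_pairs(cand, 26)   # 5 + 22 = 27 = L + 1
  expect_equal(nrow(pairs), 1L)
  rep <- candidate_report(cand, pairs)
  expect_equal(nrow(rep), 3L)
  expect_equal(sum(!is.na(rep$symmetric_partner)), 2L)
  expect_equal(rep$symmetric_partner[rep$parent_pos == 5], 22L)
  expect_equal(rep$symmetric_partner[rep$parent_pos == 22], 5L)

  empty <- candidate_report(cand[0, ], pairs[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true("symmetric_partner" %in% names(empty))
})
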