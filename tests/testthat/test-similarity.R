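test_that("edit distance matches the classic examples and degaps first", {
  expect_equal(edit_distance("AAAA", "AAAA"), 0L)
  expect_equal(edit_distance("KITTEN", "SITTING"), 3L)
  expect_equal(edit_distance("ACD", ""), 3L)
  expect_equal(edit_distance("A-C-D", "ACD"), 0L)   # gaps are display only
})

test_that("weighted edit distance discounts within-class substitutions", {
  expect_equal(weighted_edit_distance("ACDE", "ACDE"), 0)
  expect_equal(weighted_edit_distance("L", "I", "polarity"), 0.5)
  expect_equal(weighted_edit_distance("K", "D", "charge"), 1.0)
  expect_equal(weighted_edit_distance("K", "R", "charge"), 0.5)
  expect_error(weighted_edit_distance("A", "C", "fragment_frequency"),
               "partition")
})

test_that("X never matches, even itself", {
  expect_equal(edit_distance("X", "X"), 1L)
  expect_equal(weighted_edit_distance("AXA", "AXA", "polarity"), 1)
  expect_equal(common_residues("XX", "XX")$count, 0L)
  expect_equal(ngram_common("AXC", "AXC", 2), 0L)
})

test_that("weighted distance is bounded by plain distance and symmetric", {
  set.seed(11)
  for (rep in 1:50) {
    a <- paste(sample(famtrend:::AA20, sample(0:12, 1), TRUE), collapse = "")
    b <- paste(sample(famtrend:::AA20, sample(0:12, 1), TRUE), collapse = "")
    for (sch in c("polarity", "charge", "chemical", "solvent_contact")) {
      w <- weighted_edit_distance(a, b, sch)
      expect_lte(w, edit_distance(a, b))
      expect_equal(w, weighted_edit_distance(b, a, sch))
    }
  }
})

test_that("common residues: positional vs compositional", {
  r <- common_residues("A-CD", "A-CE", positional = TRUE)
  expect_equal(r$count, 2L)                   # columns 1 and 3; gap-gap no
  expect_equal(common_residues("AC", "CA", TRUE)$count, 0L)
  expect_equal(common_residues("AC", "CA", FALSE)$count, 2L)
  r7 <- common_residues("AKCDEFG", "AKCDEFG", TRUE)
  expect_equal(r7$count, 7L)
  expect_equal(r7$percentage, 100)
  expect_error(common_residues("AC", "ACD"), "length")
  # percentage denominator is the shorter degapped sequence
  r <- common_residues("AC--", "ACDE", TRUE)
  expect_equal(r$percentage, 100)
  expect_equal(common_residues("--", "--")$percentage, 0)
})

test_that("positional count never exceeds compositional count (property)", {
  set.seed(5)
  for (rep in 1:60) {
    fam <- rand_family(2, 25, gap_prob = 0.2)
    p <- common_residues(fam$rows[1], fam$rows[2], TRUE)$count
    c <- common_residues(fam$rows[1], fam$rows[2], FALSE)$count
    expect_lte(p, c)
  }
})

test_that("shared n-grams are counted as distinct substrings", {
  expect_equal(ngram_common("ACDE", "GCDE", 2), 2L)   # CD, DE
  expect_equal(ngram_common("AAAA", "AAAA", 2), 1L)   # only AA
  expect_equal(ngram_common("AAAA", "CCCC", 2), 0L)
  expect_equal(ngram_common("AC", "AC", 5), 0L)       # shorter than n
  expect_error(ngram_common("AC", "AC", 0), "n must be")
  # self-commonality equals the distinct n-gram count
  set.seed(3)
  for (rep in 1:20) {
    a <- paste(sample(c("A", "C", "G"), 15, TRUE), collapse = "")
    n <- sample(1:4, 1)
    grams <- unique(substring(a, 1:(15 - n + 1), n:15))
    expect_equal(ngram_common(a, a, n), length(grams))
  }
})

test_that("selected-column edit distance projects then degaps", {
  expect_equal(selected_edit_distance("AKCD", "AYCD", 2), 1L)
  expect_equal(selected_edit_distance("AKCD", "AYCD", c(1, 3, 4)), 0L)
  expect_equal(selected_edit_distance("AKCD", "AYWD", 1:4),
               edit_distance("AKCD", "AYWD"))
  expect_equal(selected_edit_distance("A-CD", "AEC-", c(2, 4)),
               edit_distance("D", "E"))
  expect_error(selected_edit_distance("AC", "AC", integer(0)), "empty")
  expect_error(selected_edit_distance("AC", "AC", 5), "lie in")
})

test_that("fragment frequency weight counts identical window substrings", {
  fam <- aligned_family(sprintf("s%d", 1:4),
                        c("AAACD", "AAACE", "AAACD", "AAWCD"))
  expect_equal(fragment_frequency_weight(fam, 1, c(1, 3)), 0.75)
  expect_equal(fragment_frequency_weight(fam, 2, c(1, 5)), 0.25)
  expect_equal(fragment_frequency_weight(fam, 1, c(1, 5)), 0.5)
  for (i in 1:4)
    expect_equal(fragment_frequency_weight(fam, i, c(4, 4)), 1.0)
  expect_error(fragment_frequency_weight(fam, 1, c(3, 1)), "window")
  expect_error(fragment_frequency_weight(fam, 1, c(0, 2)), "window")
})

test_that("sort_family ranks by weight with stable ties", {
  fam <- aligned_family(c("r", "far", "near"),
                        c("AAAA", "CCDD", "AAAC"))
  sr <- sort_family(fam, "r", "edit")
  expect_equal(unname(sr$weights), c(0, 4, 1))
  expect_equal(sr$order, c(1L, 3L, 2L))
  expect_equal(names(sr$weights)[sr$order[1]], "r")   # reference first

  # ties keep input order
  fam2 <- aligned_family(c("r", "t1", "t2"), c("AAAA", "AAAC", "AAAG"))
  sr2 <- sort_family(fam2, "r", "edit")
  expect_equal(sr2$order, c(1L, 2L, 3L))

  # similarity metrics sort descending
  sr3 <- sort_family(fam, "r", "common_positional")
  expect_equal(sr3$order[1], 1L)
  expect_error(sort_family(fam, "nope", "edit"), "unknown sequence id")
  expect_error(metric_spec("bogus"), "unknown metric")
})

test_that("sort weights are invariant under family row permutation", {
  set.seed(23)
  fam <- rand_family(8, 18, gap_prob = 0.1)
  perm <- sample(8)
  fam_p <- aligned_family(fam$ids[perm], fam$rows[perm])
  for (m in c("edit", "weighted_edit", "common_positional", "ngram_common")) {
    w1 <- sort_family(fam, "s001", m)$weights
    w2 <- sort_family(fam_p, "s001", m)$weights
    expect_equal(w2[names(w1)], w1, label = m)
  }
  # fragment frequency depends on the family, not a reference sequence
  w1 <- sort_family(fam, "s001", metric_spec("fragment_frequency"))$weights
  w2 <- sort_family(fam_p, "s002", metric_spec("fragment_frequency"))$weights
  expect_equal(w2[names(w1)], w1)
})
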