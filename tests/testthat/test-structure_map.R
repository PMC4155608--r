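# Toy chain builder: one CA atom per residue at the given coordinates.
toy_chain <- function(codes, keys = seq_along(codes), coords = NULL) {
  coords <- coords %||% lapply(seq_along(codes), function(i)
    rbind(c(i, 0, 0)))
  structure(list(chain = "A", keys = as.character(keys), codes = codes,
                 coords = coords),
            class = "structure_chain")
}

test_that("identical sequences map one-to-one", {
  chain <- toy_chain(strsplit("AKCDEFG", "")[[1]])
  m <- map_columns_to_structure("AKCDEFG", chain)
  expect_equal(nrow(m$map), 7L)
  expect_equal(m$map$column, 1:7)
  expect_equal(m$map$key, as.character(1:7))
  expect_true(all(m$map$match))
  expect_equal(length(m$unmapped_columns), 0L)
  expect_equal(length(m$unmapped_keys), 0L)
  expect_equal(m$identity, 1)
})

test_that("gaps in the family row shift columns; missing residues unmatch", {
  chain <- toy_chain(strsplit("AKCDEFG", "")[[1]])
  # aligned row with leading filler and an internal gap
  m <- map_columns_to_structure("--AKC-DEFG", chain)
  expect_equal(m$map$column, c(3, 4, 5, 7, 8, 9, 10))
  expect_true(all(m$map$match))

  # chain missing two interior residues (D, E absent)
  chain2 <- toy_chain(strsplit("AKCFG", "")[[1]], keys = c(1, 2, 3, 6, 7))
  m2 <- map_columns_to_structure("AKCDEFG", chain2)
  expect_equal(sort(m2$unmapped_columns), c(4, 5))
  expect_equal(nrow(m2$map), 5L)
  expect_true(all(m2$map$match))
  # mapping is order-preserving
  expect_true(all(diff(m2$map$column) > 0))
  expect_true(all(diff(as.integer(m2$map$key)) > 0))
})

test_that("mapped codes equal the row residues wherever flagged as match", {
  set.seed(8)
  for (rep in 1:10) {
    seq <- paste(sample(famtrend:::AA20, 30, TRUE), collapse = "")
    # drop a random interior chunk from the structure
    drop <- sort(sample(5:25, 4))
    keep <- setdiff(1:30, drop)
    chain <- toy_chain(strsplit(seq, "")[[1]][keep], keys = keep)
    m <- map_columns_to_structure(seq, chain)
    row_chars <- strsplit(seq, "")[[1]]
    expect_true(all(m$map$code[m$map$match] ==
                      row_chars[m$map$column[m$map$match]]))
  }
})

test_that("unrelated sequences are refused below the identity floor", {
  chain <- toy_chain(strsplit("KKKKKKKKKK", "")[[1]])
  expect_error(map_columns_to_structure("DDDDDDDDDD", chain), "identity")

  # a point mutation is still mapped, flagged as mismatch
  chain2 <- toy_chain(strsplit("KKKDKKKKKK", "")[[1]])
  m <- map_columns_to_structure("KKKKKKKKKK", chain2)
  expect_equal(nrow(m$map), 10L)
  expect_equal(sum(!m$map$match), 1L)
  expect_equal(m$identity, 0.9)
  # the floor is overridable upward too
  expect_error(map_columns_to_structure("KKKKKKKKKK", chain2,
                                        min_identity = 0.95), "identity")
})

test_that("site proximity is a min over heavy-atom pairs", {
  chain <- toy_chain(c("A", "K"), keys = c(10, 20),
                     coords = list(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))))
  p <- site_proximity("20", "10", chain, cutoff = 6)
  expect_equal(p$distance, 5)          # 3-4-5 triangle
  expect_true(p$within)
  expect_false(site_proximity("20", "10", chain, cutoff = 4)$within)
  # membership short-circuits to zero
  expect_equal(site_proximity("10", c("10", "20"), chain)$distance, 0)
  expect_error(site_proximity("99", "10", chain), "99")
  expect_error(site_proximity("20", "10", chain, cutoff = 0), "positive")
  # symmetric under swapping singleton candidate and site
  expect_equal(site_proximity("20", "10", chain)$distance,
               site_proximity("10", "20", chain)$distance)
})

test_that("distances match a brute-force all-pairs oracle on toy chains", {
  set.seed(14)
  for (rep in 1:10) {
    n_res <- 5
    coords <- lapply(1:n_res, function(i)
      matrix(runif(3 * sample(1:4, 1), -10, 10), ncol = 3))
    chain <- toy_chain(sample(famtrend:::AA20, n_res), coords = coords)
    cand <- sample(chain$keys, 2)
    site <- setdiff(chain$keys, cand)[1:2]
    p <- site_proximity(cand, site, chain, cutoff = 8)
    for (k in seq_along(cand)) {
      a <- coords[[match(cand[k], chain$keys)]]
      best <- Inf
      for (s in site) {
        b <- coords[[match(s, chain$keys)]]
        for (i in seq_len(nrow(a)))
          for (j in seq_len(nrow(b)))
            best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
      }
      expect_equal(p$distance[k], best, tolerance = 1e-12)
      expect_equal(p$within[k], best <= 8)
    }
  }
})

test_that("selection strings are sorted and keep insertion codes", {
  expect_equal(selection_string(c(138, 107), "A"),
               "chain A and resi 107+138")
  expect_equal(selection_string("42", "B"), "chain B and resi 42")
  expect_equal(selection_string(c("100B", "100A", "99"), "A"),
               "chain A and resi 99+100A+100B")
  expect_error(selection_string(character(0), "A"), "empty")
})
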