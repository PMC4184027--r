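test_that("a homopolymer text sets exactly one occurrence bit", {
  idx <- build_qgroup_index(encode_sequence("AAAA"), q = 2)
  expect_identical(idx$I[1], 1L)                # bit 0 of word 0: q-gram AA
  expect_true(all(idx$I[-1] == 0L))
  expect_setequal(idx$O, 0:2)                   # three AA starts
  ip <- indexpair(idx, 0)
  expect_identical(unname(ip[2] - ip[1]), 3L)
})

test_that("distinct q-gram and position counts match a naive enumeration", {
  t <- encode_sequence("ACGTACGT")
  idx <- build_qgroup_index(t, q = 2)
  expect_identical(sum(bits_popcount <- qgroupmap:::bits_popcount_cpp(idx$I)), 4L)
  expect_identical(length(idx$S_prime) - 1L, 4L) # AC, CG, GT, TA
  expect_identical(length(idx$O), 7L)
})

test_that("group_and_bit implements i = floor(g/w), j = g mod w", {
  expect_identical(group_and_bit(0, 32), list(i = 0, j = 0))
  expect_identical(group_and_bit(33, 32), list(i = 1, j = 1))
  gb <- group_and_bit(4^16 - 1, 32)
  expect_identical(gb$i, 134217727)
  expect_identical(gb$j, 31)
})

test_that("grouprank counts set bits strictly below j", {
  expect_identical(grouprank(1L, 0), 0L)
  expect_identical(grouprank(strtoi("1011", base = 2), 3), 2L)
  full <- -1L # all 32 bits set
  for (j in c(0, 1, 13, 31)) expect_identical(grouprank(full, j), as.integer(j))
})

test_that("indexpair returns absent for q-grams not in the text", {
  idx <- build_qgroup_index(encode_sequence("AAAA"), q = 2)
  expect_null(indexpair(idx, 15))   # TT never occurs
  expect_identical(lookup_positions(idx, 15), integer(0))
  expect_error(indexpair(idx, 16), "range")
})

test_that("lookups set-equal a naive scan on randomized texts", {
  set.seed(11)
  for (rep in 1:40) {
    q <- sample(2:8, 1)
    n <- sample(q:300, 1)
    dna <- rand_dna(n)
    t <- encode_sequence(dna)
    idx <- build_qgroup_index(t, q = q)
    truth <- oracle_qgram_scan(dna, q)
    for (gram in names(truth)) {
      g <- encode_qgram(encode_sequence(gram), 0, q)
      expect_setequal(lookup_positions(idx, g), truth[[gram]])
    }
    # a few absent q-grams
    for (g in sample(0:(4^q - 1), 5)) {
      gram <- codes_to_str((g %/% 4^((q - 1):0)) %% 4)
      if (is.null(truth[[gram]])) expect_null(indexpair(idx, g))
    }
  }
})

test_that("q = 16 lookups agree with the naive scan", {
  set.seed(12)
  dna <- rand_dna(3000)
  t <- encode_sequence(dna)
  idx <- build_qgroup_index(t, q = 16)
  truth <- oracle_qgram_scan(dna, 16)
  sel <- sample(names(truth), 50)
  for (gram in sel) {
    g <- encode_qgram(encode_sequence(gram), 0, 16)
    expect_setequal(lookup_positions(idx, g), truth[[gram]])
  }
  expect_null(indexpair(idx, 0)) # AAAA... a 16-mer absent whp
})

test_that("small group widths keep lookup semantics", {
  set.seed(13)
  dna <- rand_dna(200)
  truth <- oracle_qgram_scan(dna, 4)
  for (w in c(4L, 8L, 16L, 32L)) {
    idx <- build_qgroup_index(encode_sequence(dna), q = 4, w = w)
    for (gram in names(truth)) {
      g <- encode_qgram(encode_sequence(gram), 0, 4)
      expect_setequal(lookup_positions(idx, g), truth[[gram]])
    }
  }
})

test_that("half-sampled S reproduces full-index lookups", {
  set.seed(14)
  dna <- rand_dna(500)
  full <- build_qgroup_index(encode_sequence(dna), q = 5)
  half <- build_qgroup_index(encode_sequence(dna), q = 5, half_sample = TRUE)
  expect_lt(length(half$S), length(full$S))
  for (g in 0:(4^5 - 1)) {
    expect_setequal(lookup_positions(half, g), lookup_positions(full, g))
  }
})

test_that("structural invariants hold on random builds", {
  set.seed(15)
  for (rep in 1:10) {
    q <- sample(2:8, 1)
    t <- encode_sequence(rand_dna(sample(q:500, 1)))
    idx <- build_qgroup_index(t, q = q)
    pc <- qgroupmap:::bits_popcount_cpp(idx$I)
    expect_identical(sum(pc), length(idx$S_prime) - 1L)
    expect_identical(diff(idx$S), pc)              # S cumulative over popcounts
    expect_identical(idx$S[1], 0L)
    expect_true(!is.unsorted(idx$S_prime))
    expect_identical(idx$S_prime[length(idx$S_prime)], length(idx$O))
    expect_setequal(idx$O, 0:(t$length - q))       # permutation of all starts
    expect_lte(qgroupmap:::index_words(idx),
               worst_case_words(q, 32, t$length) + 2) # sentinel slack
    # rebuilding is bit-identical
    expect_identical(idx, build_qgroup_index(t, q = q))
  }
})

test_that("the q/word-size compatibility limits are enforced", {
  t <- encode_sequence("ACGTACGT")
  expect_error(build_qgroup_index(t, q = 17), "q must be")
  expect_error(build_qgroup_index(t, q = 4, w = 64), "w must be")
  expect_error(build_qgroup_index(encode_sequence("ACG"), q = 4), "shorter")
})

test_that("worst-case size formula matches hand arithmetic", {
  expect_identical(worst_case_words(16, 32, 1e8), 468435456)
  expect_identical(worst_case_words(4, 32, 0), 2 * ceiling(4^4 / 32))
  expect_identical(worst_case_words(8, 64, 1000),
                   2 * ceiling(4^8 / 64) + 1000 + 1000)
})

test_that("size ratio is piecewise in K with the documented landmarks", {
  expect_equal(size_ratio(1), 1.03125)
  expect_equal(size_ratio(16 / 15), 1)
  expect_equal(size_ratio(1e9), 1 / 16, tolerance = 1e-6)
  expect_equal(size_ratio(0.5), (0.5 / 16 + 0.5 + 1) / 1.5)
  expect_error(size_ratio(0), "positive")
  # generalised word size: break-even at K = h/(h-1)
  expect_equal(size_ratio(32 / 31, w = 64), 1)
})

test_that("size ratio agrees with the worst-case word count", {
  Tlen <- 1e6
  for (q in c(8, 10, 12)) {
    K <- 4^q / Tlen
    measured <- worst_case_words(q, 32, Tlen) / (4^q + Tlen)
    expect_equal(size_ratio(K), measured, tolerance = 0.01)
  }
})

test_that("naive position map handles the documented corner cases", {
  m <- naive_qgram_positions(encode_sequence("AAAA"), 2)
  expect_identical(m, list(`0` = 0:2))
  m2 <- naive_qgram_positions(encode_sequence("ACGT"), 4)
  expect_identical(m2, list(`27` = 0L))
  expect_length(naive_qgram_positions(encode_sequence("ACG"), 4), 0)
})
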