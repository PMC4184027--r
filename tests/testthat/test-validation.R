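test_that("an exact substring scores distance zero", {
  set.seed(41)
  win <- rand_codes(60)
  read <- win[11:40]
  res <- banded_myers_distance(read, win)
  expect_identical(res$k, 0L)
  expect_identical(res$end, 40L)
})

test_that("one substitution costs one (4x4 DP oracle)", {
  read <- encode_sequence("ACGT")$codes
  win <- encode_sequence("AGGT")$codes
  res <- banded_myers_distance(read, win)
  expect_identical(res$k, 1L)
  expect_identical(res$k, oracle_semiglobal_min(read, win))
})

test_that("bit-parallel scores equal the DP oracle on random edited pairs", {
  set.seed(42)
  for (rep in 1:300) {
    m <- sample(20:90, 1) # spans one and two 64-bit blocks
    win <- rand_codes(m + 20)
    read <- apply_random_edits(win[6:(5 + m)], sample(0:8, 1))
    prof <- qgroupmap:::myers_profile_cpp(read, win)
    expect_identical(prof, oracle_semiglobal_profile(read, win))
  }
})

test_that("reads longer than two words are scored correctly", {
  set.seed(43)
  win <- rand_codes(220)
  read <- apply_random_edits(win[11:190], 5) # |r| ~ 180 -> 3 blocks
  res <- banded_myers_distance(read, win)
  expect_identical(res$k, oracle_semiglobal_min(read, win))
})

test_that("the backward pass locates the alignment start", {
  set.seed(44)
  win <- rand_codes(50)
  read <- win[8:27] # exact match at offset 7, |r| = 20
  res <- banded_myers_distance(read, win)
  expect_identical(locate_start(read, win, res$k, res$end), 7L)
  # an extra non-matching head base costs 1; among the tied explanations
  # (insert the head vs substitute it against the previous reference base)
  # the smaller ref_start wins
  head_base <- setdiff(0:3, c(win[7], win[8]))[1]
  read2 <- c(head_base, win[8:27])
  res2 <- banded_myers_distance(read2, win)
  st2 <- locate_start(read2, win, res2$k, res2$end)
  expect_identical(res2$k, 1L)
  expect_identical(st2, 6L)
  # forward and backward distances agree on random cases
  for (rep in 1:50) {
    w <- rand_codes(60)
    r <- apply_random_edits(w[11:40], sample(0:4, 1))
    fwd <- banded_myers_distance(r, w)
    st <- locate_start(r, w, fwd$k, fwd$end)
    expect_gte(st, 0)
    expect_lt(st, fwd$end)
    # re-deriving the distance over the located span gives k again
    seg <- w[(st + 1):fwd$end]
    expect_identical(qgroupmap:::edit_traceback_cpp(r, seg)$k, fwd$k)
  }
})

make_toy_setup <- function(genome_str, reads, q = 8) {
  ref <- build_reference_index(c(chr1 = genome_str), q = q,
                               mask_absolute_cap = Inf,
                               mask_frequency_cap = Inf)
  batch <- make_read_batches(paste0("r", seq_along(reads)), reads, q = q,
                             buffer_size = 100)[[1]]
  list(ref = ref, batch = batch)
}

test_that("hits below the identity threshold are discarded", {
  set.seed(45)
  genome_str <- rand_dna(2000)
  start <- 300
  read_codes <- encode_sequence(substr(genome_str, start + 1, start + 20))$codes
  ps <- sample(20, 5) # 5 substitutions in 20 bp -> s = 75
  for (p in ps) read_codes[p] <- sample(setdiff(0:3, read_codes[p]), 1)
  st <- make_toy_setup(genome_str, codes_to_str(read_codes))
  cand <- data.table::data.table(read_id = 1L, strand = "+", chrom = "chr1",
                                 diagonal = start)
  dropped <- validate_hits(cand, st$batch, st$ref, identity_threshold = 80)
  expect_identical(nrow(dropped), 0L)
  kept <- validate_hits(cand, st$batch, st$ref, identity_threshold = 60)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$k, 5L)
  expect_equal(kept$s, 75)
})

test_that("four substitutions in 100 bp score s = 96", {
  set.seed(46)
  genome_str <- rand_dna(3000)
  start <- 1000
  read_codes <- encode_sequence(substr(genome_str, start + 1, start + 100))$codes
  # keep the read ends intact so the optimal span is unambiguous
  for (p in sample(10:90, 4)) {
    read_codes[p] <- sample(setdiff(0:3, read_codes[p]), 1)
  }
  st <- make_toy_setup(genome_str, codes_to_str(read_codes))
  cand <- data.table::data.table(read_id = 1L, strand = "+", chrom = "chr1",
                                 diagonal = start)
  v <- validate_hits(cand, st$batch, st$ref, identity_threshold = 60)
  expect_identical(v$k, 4L)
  expect_equal(v$s, 96)
  expect_identical(v$ref_start, start)
  expect_identical(v$ref_end, start + 100L)
})

test_that("duplicate candidates collapse to one validated hit", {
  set.seed(47)
  genome_str <- rand_dna(1000)
  read <- substr(genome_str, 201, 250)
  st <- make_toy_setup(genome_str, read)
  cand <- data.table::data.table(read_id = 1L, strand = "+", chrom = "chr1",
                                 diagonal = c(198L, 200L, 202L))
  v <- validate_hits(cand, st$batch, st$ref, identity_threshold = 80)
  expect_identical(nrow(v), 1L)
  expect_identical(v$ref_start, 200L)
  expect_identical(v$k, 0L)
})

test_that("lowering the threshold never removes a hit (monotonicity)", {
  set.seed(48)
  genome_str <- rand_dna(5000)
  reads <- vapply(1:10, function(i) {
    s <- sample(4900, 1)
    codes_to_str(apply_random_edits(
      encode_sequence(substr(genome_str, s, s + 49))$codes, sample(0:8, 1)))
  }, "")
  st <- make_toy_setup(genome_str, reads)
  idx <- build_batch_index(st$batch, 8)
  ch <- st$ref$chromosomes$chr1
  raw <- generate_hits(idx, st$batch, ch$P_g, ch$P_pos, q = 8)
  raw[, chrom := "chr1"]
  cand <- dedup_candidates(raw)
  v80 <- validate_hits(cand, st$batch, st$ref, identity_threshold = 80)
  v60 <- validate_hits(cand, st$batch, st$ref, identity_threshold = 60)
  key <- function(v) paste(v$read_id, v$chrom, v$ref_start, v$ref_end)
  expect_true(all(key(v80) %in% key(v60)))
  expect_true(all(v60$s >= 60))
  expect_true(all(v80$s >= 80))
  expect_true(all(v60$s == 100 * (v60$read_len - v60$k) / v60$read_len))
})

test_that("windows clipped at contig edges still validate overhanging hits", {
  set.seed(49)
  genome_str <- rand_dna(500)
  read <- substr(genome_str, 1, 40) # maps to position 0
  st <- make_toy_setup(genome_str, read)
  cand <- data.table::data.table(read_id = 1L, strand = "+", chrom = "chr1",
                                 diagonal = 0L)
  v <- validate_hits(cand, st$batch, st$ref)
  expect_identical(v$ref_start, 0L)
  expect_identical(v$k, 0L)
})
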