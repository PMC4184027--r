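test_that("reads are padded into fixed slots and batched by buffer size", {
  set.seed(31)
  seqs <- c(rand_dna(100), rand_dna(100), rand_dna(80))
  b <- make_read_batches(paste0("r", 1:3), seqs, q = 16, buffer_size = 10)
  expect_length(b, 1)
  batch <- b[[1]]
  expect_identical(batch$slot_length, 100L)
  expect_identical(batch$concat$length, 300L)
  expect_identical(unname(batch$concat$skipped_runs[1, ]), c(280L, 300L))
  # batching: 5 reads with buffer 2 -> 2, 2, 1
  b5 <- make_read_batches(paste0("r", 1:5),
                          vapply(1:5, function(i) rand_dna(30), ""),
                          q = 16, buffer_size = 2)
  expect_identical(vapply(b5, `[[`, 0L, "count"), c(2L, 2L, 1L))
})

test_that("reads shorter than q are skipped with a warning", {
  expect_warning(
    b <- make_read_batches(c("a", "b"), c("ACGTACGTACGTACGTACGT", "ACG"),
                           q = 16, buffer_size = 10),
    "1 read\\(s\\) shorter")
  expect_identical(b[[1]]$count, 1L)
  expect_identical(attr(b, "skipped"), 1L)
})

test_that("the batch index never contains a q-gram spanning two slots", {
  set.seed(32)
  q <- 6
  seqs <- vapply(c(40, 35, 40), rand_dna, "")
  b <- make_read_batches(paste0("r", 1:3), seqs, q = q, buffer_size = 10)[[1]]
  idx <- build_batch_index(b, q = q)
  slot <- b$slot_length
  offs <- idx$O %% slot
  rids <- idx$O %/% slot
  expect_true(all(offs <= b$read_lengths[rids + 1] - q))
  # and it contains exactly the union of per-read scans
  expected <- unlist(lapply(1:3, function(i) {
    (i - 1) * slot + 0:(nchar(seqs[i]) - q)
  }))
  expect_setequal(idx$O, expected)
})

test_that("a read matching a unique locus yields one deduplicated hit", {
  set.seed(33)
  genome_str <- rand_dna(5000)
  read <- substr(genome_str, 501, 600) # 0-based start 500
  ref <- build_reference_index(c(chr1 = genome_str), q = 16,
                               mask_absolute_cap = Inf,
                               mask_frequency_cap = Inf)
  b <- make_read_batches("r1", read, q = 16, buffer_size = 10)[[1]]
  idx <- build_batch_index(b, q = 16)
  ch <- ref$chromosomes$chr1
  raw <- generate_hits(idx, b, ch$P_g, ch$P_pos, q = 16)
  expect_identical(nrow(raw), 85L) # 100 - 16 + 1 q-gram matches
  expect_true(all(raw$diagonal == 500L))
  raw[, chrom := "chr1"]
  cand <- dedup_candidates(raw)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$diagonal, 500L)
  expect_identical(cand$support, 85L)
})

test_that("a read absent from the reference yields zero hits", {
  set.seed(34)
  genome_str <- rand_dna(100000)
  read <- rand_dna(100)
  truth <- oracle_qgram_scan(genome_str, 16)
  read_grams <- substring(read, 1:85, 16:100)
  expect_false(any(read_grams %in% names(truth))) # oracle: no shared 16-gram
  ref <- build_reference_index(c(chr1 = genome_str), q = 16,
                               mask_absolute_cap = Inf,
                               mask_frequency_cap = Inf)
  b <- make_read_batches("r1", read, q = 16, buffer_size = 10)[[1]]
  idx <- build_batch_index(b, q = 16)
  ch <- ref$chromosomes$chr1
  raw <- generate_hits(idx, b, ch$P_g, ch$P_pos, q = 16)
  expect_identical(nrow(raw), 0L)
})

test_that("an empty pair list yields an empty hit list", {
  b <- make_read_batches("r1", "ACGTACGTACGTACGTACGT", q = 16,
                         buffer_size = 10)[[1]]
  idx <- build_batch_index(b, q = 16)
  raw <- generate_hits(idx, b, numeric(0), integer(0), q = 16)
  expect_identical(nrow(raw), 0L)
})

test_that("raw hits equal the naive double loop over P and occurrences", {
  set.seed(35)
  q <- 4
  genome_str <- rand_dna(300)
  seqs <- vapply(rep(30, 5), rand_dna, "")
  ref <- build_reference_index(c(chr1 = genome_str), q = q,
                               mask_absolute_cap = Inf,
                               mask_frequency_cap = Inf)
  b <- make_read_batches(paste0("r", 1:5), seqs, q = q, buffer_size = 10)[[1]]
  idx <- build_batch_index(b, q = q)
  ch <- ref$chromosomes$chr1
  raw <- generate_hits(idx, b, ch$P_g, ch$P_pos, q = q)
  # oracle: scan every reference q-gram against per-read string scans
  expected <- list()
  for (t in seq_along(ch$P_pos)) {
    p <- ch$P_pos[t]
    gram <- substr(genome_str, p + 1, p + q)
    for (ri in 1:5) {
      occ <- oracle_qgram_scan(seqs[ri], q)[[gram]]
      for (o in occ) {
        expected[[length(expected) + 1]] <- c(ri, p - o)
      }
    }
  }
  exp_dt <- data.table::as.data.table(do.call(rbind, expected))
  data.table::setnames(exp_dt, c("read_id", "diagonal"))
  got <- data.table::copy(raw)[, list(read_id, diagonal)]
  data.table::setorder(exp_dt, read_id, diagonal)
  data.table::setorder(got, read_id, diagonal)
  expect_equal(as.data.frame(got), as.data.frame(exp_dt),
               ignore_attr = TRUE)
  # two-pass compaction: one output row per counted occurrence
  expect_identical(nrow(raw), nrow(exp_dt))
})

test_that("pigeonhole: few enough substitutions always leave a seed", {
  # e < (n+1)/q - 1 with n = 40, q = 8: up to 4 substitutions guaranteed
  set.seed(36)
  q <- 8
  genome_str <- rand_dna(20000)
  ref <- build_reference_index(c(chr1 = genome_str), q = q,
                               mask_absolute_cap = Inf,
                               mask_frequency_cap = Inf)
  ch <- ref$chromosomes$chr1
  for (rep in 1:25) {
    start <- sample(20000 - 40, 1) - 1
    read_codes <- encode_sequence(substr(genome_str, start + 1, start + 40))$codes
    ps <- sample(40, 4)
    for (p in ps) read_codes[p] <- sample(setdiff(0:3, read_codes[p]), 1)
    b <- make_read_batches("r", codes_to_str(read_codes), q = q,
                           buffer_size = 10)[[1]]
    idx <- build_batch_index(b, q = q)
    raw <- generate_hits(idx, b, ch$P_g, ch$P_pos, q = q)
    raw[, chrom := "chr1"]
    cand <- dedup_candidates(raw)
    expect_true(any(abs(cand$diagonal - start) <= 3))
  }
})

test_that("mismatched q between index and stream is a configuration error", {
  b <- make_read_batches("r1", "ACGTACGTACGTACGTACGT", q = 8,
                         buffer_size = 10)[[1]]
  idx <- build_batch_index(b, q = 8)
  expect_error(generate_hits(idx, b, numeric(0), integer(0), q = 16),
               "q mismatch")
})

test_that("candidate deduplication merges nearby diagonals and clamps negatives", {
  hits <- data.table::data.table(
    read_id = c(1L, 1L, 1L, 1L, 1L, 2L),
    strand = "+",
    chrom = "chr1",
    diagonal = c(100L, 100L, 101L, 150L, -2L, 100L))
  cand <- dedup_candidates(hits, delta = 3)
  c1 <- cand[read_id == 1L]
  expect_identical(sort(c1$diagonal), c(0L, 100L, 150L))
  expect_identical(c1[diagonal == 100L, support], 3L) # 100,100,101 merged
  expect_identical(cand[read_id == 2L, diagonal], 100L)
})
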