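# Independent oracles: plain dynamic programming and exhaustive scans,
# deliberately sharing no code with the package's C++ paths.

BASES <- c("A", "C", "G", "T")

rand_codes <- function(n) sample(0:3, n, replace = TRUE)

codes_to_str <- function(codes) paste(BASES[codes + 1], collapse = "")

rand_dna <- function(n) codes_to_str(rand_codes(n))

# Semi-global DP profile: for each window prefix end j, the minimal
# unit-cost distance of the whole read vs any window substring ending at j
# (read global, window start free). Column recurrence vectorised with the
# cummin trick for the within-column dependency.
oracle_semiglobal_profile <- function(read, window) {
  m <- length(read)
  col <- 0:m
  prof <- integer(length(window))
  steps <- 0:m
  for (j in seq_along(window)) {
    tent <- pmin(col[1:m] + (read != window[j]), col[2:(m + 1)] + 1L)
    col <- cummin(c(0L, tent) - steps) + steps
    prof[j] <- col[m + 1]
  }
  prof
}

oracle_semiglobal_min <- function(read, window) {
  if (length(window) == 0) return(length(read))
  min(length(read), min(oracle_semiglobal_profile(read, window)))
}

# Global unit-cost edit distance through an independent route (adist).
oracle_global <- function(codes_a, codes_b) {
  drop(utils::adist(codes_to_str(codes_a), codes_to_str(codes_b)))
}

# Apply n random edits (substitutions and, optionally, 1-base indels) to a
# code vector.
apply_random_edits <- function(codes, n_edits, indels = TRUE) {
  for (e in seq_len(n_edits)) {
    kind <- if (indels) sample(3, 1) else 1L
    if (kind == 1L && length(codes) > 0) { # substitution
      p <- sample(length(codes), 1)
      codes[p] <- sample(setdiff(0:3, codes[p]), 1)
    } else if (kind == 2L) { # insertion
      p <- sample(length(codes) + 1, 1)
      codes <- append(codes, sample(0:3, 1), after = p - 1)
    } else if (length(codes) > 1) { # deletion
      p <- sample(length(codes), 1)
      codes <- codes[-p]
    }
  }
  codes
}

# Exhaustive q-gram occurrence scan on a plain string (no encoding layer).
oracle_qgram_scan <- function(dna, q) {
  n <- nchar(dna)
  if (n < q) return(list())
  grams <- substring(dna, 1:(n - q + 1), q:n)
  split(0:(n - q), grams)
}

# Read-consuming length of a CIGAR string.
cigar_query_length <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDSH=X]", cigar)[[1]]
  if (ops[1] == -1) return(0L)
  pieces <- regmatches(cigar, gregexpr("[0-9]+[MIDSH=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]", "", pieces))
  type <- sub("[0-9]+", "", pieces)
  sum(lens[type %in% c("M", "I", "S", "=", "X")])
}

cigar_ref_length <- function(cigar) {
  pieces <- regmatches(cigar, gregexpr("[0-9]+[MIDSH=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]", "", pieces))
  type <- sub("[0-9]+", "", pieces)
  sum(lens[type %in% c("M", "D", "=", "X")])
}
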