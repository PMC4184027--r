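# 2-bit DNA encoding with IUPAC handling.
#
# All coordinates attached to encoded sequences (n_mask, skipped_runs, and
# every position derived from them downstream) are 0-based; conversion to
# 1-based happens only when SAM records are written.

.iupac_sets <- list(
  A = 0L, C = 1L, G = 2L, T = 3L, U = 3L,
  R = c(0L, 2L), Y = c(1L, 3L), S = c(1L, 2L), W = c(0L, 3L),
  K = c(2L, 3L), M = c(0L, 1L),
  B = c(1L, 2L, 3L), D = c(0L, 2L, 3L), H = c(0L, 1L, 3L), V = c(0L, 1L, 2L),
  N = c(0L, 1L, 2L, 3L)
)

# byte -> code lookup: 0..3 for ACGT/U, negative index into .iupac_sets for
# ambiguity letters, NA for anything else
.make_lut <- function() {
  lut <- rep(NA_integer_, 256)
  nm <- names(.iupac_sets)
  for (i in seq_along(nm)) {
    v <- .iupac_sets[[i]]
    code <- if (length(v) == 1L) v else -i
    for (ch in c(nm[i], tolower(nm[i]))) {
      lut[utf8ToInt(ch) + 1L] <- code
    }
  }
  lut
}
.encode_lut <- .make_lut()

#' Encode a DNA string as 2-bit symbols
#'
#' Bases are packed as A=0, C=1, G=2, T=3. Ambiguous IUPAC letters are
#' replaced uniformly at random among their compatible bases (deterministic
#' for a given `seed`) and the affected positions recorded in `n_mask`.
#' Maximal runs of `N` of length at least `n_run_threshold` are additionally
#' recorded as `skipped_runs`: q-grams overlapping such a run are never
#' indexed, while isolated ambiguity codes keep their random replacement.
#'
#' @param raw a DNA string (IUPAC letters, case-insensitive).
#' @param seed integer seed driving the random replacement of ambiguous
#'   bases.
#' @param n_run_threshold minimum length of an `N` run to be excluded from
#'   indexing.
#' @return an object of class `encoded_seq` with fields `codes` (integer
#'   vector in 0..3), `length`, `n_mask` (0-based positions of replaced
#'   bases) and `skipped_runs` (two-column matrix of 0-based half-open
#'   intervals).
#' @export
encode_sequence <- function(raw, seed = 0L, n_run_threshold = 10L) {
  stopifnot(is.character(raw), length(raw) == 1L)
  bytes <- as.integer(charToRaw(raw))
  codes <- .encode_lut[bytes + 1L]
  bad <- which(is.na(codes))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d (not an IUPAC code)",
                 substr(raw, bad[1], bad[1]), bad[1]))
  }
  amb <- which(codes < 0L)
  if (length(amb)) {
    cls <- -codes[amb]
    codes[amb] <- with_seed(seed, {
      out <- integer(length(amb))
      for (ci in sort(unique(cls))) {
        idx <- which(cls == ci)
        out[idx] <- sample(.iupac_sets[[ci]], length(idx), replace = TRUE)
      }
      out
    })
  }
  # maximal runs of the letter N (not other ambiguity codes)
  is_n <- bytes == utf8ToInt("N") | bytes == utf8ToInt("n")
  runs <- matrix(integer(0), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  if (any(is_n)) {
    r <- rle(is_n)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= n_run_threshold
    if (any(keep)) {
      runs <- cbind(start = starts[keep] - 1L, end = ends[keep])
    }
  }
  structure(
    list(codes = as.integer(codes), length = length(codes),
         n_mask = amb - 1L, skipped_runs = runs),
    class = "encoded_seq"
  )
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat(sprintf("<encoded_seq> length %d, %d replaced ambiguous base(s), %d skipped run(s)\n",
              x$length, length(x$n_mask), nrow(x$skipped_runs)))
  invisible(x)
}

#' Decode a 2-bit encoded sequence back to letters
#'
#' Positions listed in `n_mask` carry the random replacement base, not the
#' original ambiguity code.
#' @param x an `encoded_seq`.
#' @return a character string over ACGT.
#' @export
decode_sequence <- function(x) {
  if (x$length == 0L) return("")
  paste(c("A", "C", "G", "T")[x$codes + 1L], collapse = "")
}

#' Reverse complement of an encoded sequence
#'
#' In 2-bit space complementation is `code -> 3 - code`; the function is an
#' involution. `n_mask` and `skipped_runs` are mirrored accordingly.
#' @param x an `encoded_seq`.
#' @return the reverse-complemented `encoded_seq`.
#' @export
reverse_complement <- function(x) {
  L <- x$length
  runs <- x$skipped_runs
  if (nrow(runs)) {
    runs <- cbind(start = L - runs[, "end"], end = L - runs[, "start"])
    runs <- runs[order(runs[, "start"]), , drop = FALSE]
  }
  structure(
    list(codes = rev(3L - x$codes), length = L,
         n_mask = if (length(x$n_mask)) sort(L - 1L - x$n_mask) else integer(0),
         skipped_runs = runs),
    class = "encoded_seq"
  )
}

#' Encode one q-gram window as an integer
#'
#' The window starting at 0-based `offset` is read most-significant base
#' first, so the numeric order of codes equals the lexicographic order of
#' q-grams. Codes can exceed `.Machine$integer.max` (q = 16 spans `[0,
#' 4^16)`), hence the return type is double.
#'
#' @param x an `encoded_seq`.
#' @param offset 0-based start of the window.
#' @param q window length; `offset + q` must not exceed the sequence length.
#' @return the code in `[0, 4^q)`, or `NA` when the window overlaps a
#'   skipped run (unindexable).
#' @export
encode_qgram <- function(x, offset, q) {
  if (offset < 0 || offset + q > x$length) {
    stop("q-gram window out of sequence bounds")
  }
  runs <- x$skipped_runs
  if (nrow(runs) && any(runs[, "start"] < offset + q & runs[, "end"] > offset)) {
    return(NA_real_)
  }
  sum(x$codes[(offset + 1L):(offset + q)] * 4^((q - 1):0))
}

# All rolling q-gram codes of a sequence as a double vector of length
# len - q + 1; NA where the window overlaps a skipped run.
qgram_codes <- function(x, q) {
  npos <- x$length - q + 1L
  if (npos <= 0L) return(numeric(0))
  g <- numeric(npos)
  for (kk in 0:(q - 1L)) {
    g <- g + x$codes[(1L + kk):(npos + kk)] * 4^(q - 1L - kk)
  }
  g[!valid_qgram_starts(x, q)] <- NA_real_
  g
}

# Logical mask over 0-based starts 0..(len-q): TRUE where the window does
# not overlap any skipped run.
valid_qgram_starts <- function(x, q) {
  npos <- x$length - q + 1L
  if (npos <= 0L) return(logical(0))
  ok <- rep(TRUE, npos)
  runs <- x$skipped_runs
  if (nrow(runs)) {
    for (r in seq_len(nrow(runs))) {
      from <- max(0L, runs[r, "start"] - q + 1L)
      to <- min(npos - 1L, runs[r, "end"] - 1L)
      if (from <= to) ok[(from + 1L):(to + 1L)] <- FALSE
    }
  }
  ok
}
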