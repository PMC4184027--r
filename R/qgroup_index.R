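# The q-group index: a succinct, rank-based variant of the q-gram index.
#
# The classical index stores an address table of 4^q integers. Here the
# address table is replaced by (1) an occurrence bit-vector I with one bit
# per possible q-gram, grouped into w-bit words, (2) a cumulative-popcount
# array S indexing into (3) a compacted offset array S' with one entry per
# *occurring* q-gram, and (4) the position array O. Lookup stays constant
# time per retrieved position (one popcount does the within-group rank),
# while memory drops up to w/2-fold when 4^q >> |T|.

#' Build a q-group index
#'
#' Constructs the four arrays (I, S, S', O) over a 2-bit encoded text in
#' four vectorised passes: set occurrence bits, cumulative popcount, count
#' occurrences per distinct q-gram with a second cumulative sum, then
#' scatter positions into their intervals of O.
#'
#' @param text an [encode_sequence()] result.
#' @param q q-gram length; `2*q` bits must fit a 32-bit word (`q <= 16`).
#' @param w group width in bits (at most 32, default 32): each word of I
#'   covers `w` consecutive q-gram codes.
#' @param half_sample store only every second entry of S; the missing
#'   entries are reconstructed at query time with one extra popcount.
#' @param valid optional logical mask over q-gram start positions
#'   overriding the mask derived from `text`'s skipped runs (used for
#'   concatenated read batches whose slot padding must never be indexed).
#' @return an object of class `qgroup_index` with the four arrays plus
#'   `q`, `w`, `indexed_length` and bookkeeping fields. Positions in `O`
#'   are 0-based; the order inside one q-gram's interval is unspecified
#'   (set semantics).
#' @export
build_qgroup_index <- function(text, q, w = 32L, half_sample = FALSE,
                               valid = NULL) {
  stopifnot(inherits(text, "encoded_seq"))
  q <- as.integer(q)
  w <- as.integer(w)
  if (q < 1L || 2L * q > 32L) {
    stop("q must be in 1..16: the 2q-bit q-gram code has to fit one 32-bit word")
  }
  if (w < 1L || w > 32L) stop("group width w must be in 1..32")
  if (text$length < q) stop("text shorter than q")
  if (is.null(valid)) valid <- valid_qgram_starts(text, q)
  arrays <- qgi_build_cpp(text$codes, valid, q, w, half_sample)
  structure(
    c(arrays,
      list(q = q, w = w, half_sampled = half_sample,
           indexed_length = text$length,
           n_indexable = sum(valid))),
    class = "qgroup_index"
  )
}

#' @export
print.qgroup_index <- function(x, ...) {
  cat(sprintf(
    "<qgroup_index> q=%d w=%d%s | %d distinct q-grams, %d positions, text length %d\n",
    x$q, x$w, if (x$half_sampled) " (half-sampled S)" else "",
    length(x$S_prime) - 1L, length(x$O), x$indexed_length))
  invisible(x)
}

#' Group and bit of a q-gram code
#'
#' The q-gram with code `g` lives in group `i = floor(g/w)` at bit
#' `j = g mod w` of word `I[i]`.
#' @param g q-gram code (double, `0 <= g < 4^q`).
#' @param w group width in bits.
#' @return list with components `i` and `j`.
#' @export
group_and_bit <- function(g, w = 32L) {
  i <- floor(g / w)
  list(i = i, j = g - w * i)
}

#' Rank of a set bit inside one group word
#'
#' Counts the 1-bits strictly below bit `j`: `popcount(I[i] & (2^j - 1))`.
#' The caller is expected to have checked that bit `j` itself is set.
#' @param I_word a group word (R integer, reinterpreted as unsigned).
#' @param j bit index in `0..w-1`.
#' @return the within-group rank j'.
#' @export
grouprank <- function(I_word, j) {
  mask <- if (j == 0) 0L else as.integer(2^j - 1)
  bits_popcount_cpp(bitwAnd(as.integer(I_word), mask))[1]
}

#' Interval of O holding the occurrences of a q-gram
#'
#' Computes `(i, j)` from `g`, tests bit `j` of `I[i]`, ranks it to `j'`
#' and returns `k_start = S'[S[i] + j']`, `k_end = S'[S[i] + j' + 1]`.
#' @param index a `qgroup_index`.
#' @param g q-gram code.
#' @return integer vector `c(k_start, k_end)` (0-based half-open into `O`),
#'   or `NULL` when `g` does not occur in the indexed text.
#' @export
indexpair <- function(index, g) {
  if (g < 0 || g >= 4^index$q) stop("q-gram code out of range")
  kk <- qgi_indexpair_cpp(index$I, index$S, index$S_prime,
                          index$half_sampled, index$w, g)
  if (kk[1] < 0L) return(NULL)
  c(k_start = kk[1], k_end = kk[2])
}

#' All occurrence positions of a q-gram
#'
#' @param index a `qgroup_index`.
#' @param g q-gram code.
#' @return integer vector of 0-based positions (possibly empty), in
#'   unspecified order.
#' @export
lookup_positions <- function(index, g) {
  kk <- indexpair(index, g)
  if (is.null(kk)) return(integer(0))
  if (kk[1] == kk[2]) return(integer(0))
  index$O[(kk[1] + 1L):kk[2]]
}

#' Worst-case size of the q-group index in words
#'
#' I and S take `ceil(4^q/w)` words each, S' one word per occurring q-gram
#' (at most `min(4^q, |T|)`), and O one word per text position.
#' @param q q-gram length.
#' @param w word size in bits (32 or 64).
#' @param text_length number of indexed positions |T|.
#' @return the word count `2*ceil(4^q/w) + min(4^q, |T|) + |T|`.
#' @export
worst_case_words <- function(q, w = 32, text_length) {
  stopifnot(q >= 1, w %in% c(32, 64), text_length >= 0)
  2 * ceiling(4^q / w) + min(4^q, text_length) + text_length
}

#' Worst-case size ratio of q-group index vs classical q-gram index
#'
#' In terms of `K = 4^q / |T|` (possible q-grams per text position) and with
#' h = w/2, the ratio is `(K/h + K + 1) / (K + 1)` for `K <= 1` (every
#' q-gram may occur, S' costs K|T|) and `(2 + K/h) / (1 + K)` for `K > 1`
#' (S' capped at |T|). For w = 32 the ratio is 1.03125 at K = 1, crosses
#' 1 at K = 16/15 and tends to 1/16 as K grows.
#' @param K ratio `4^q / |T|`, positive.
#' @param w word size in bits.
#' @return the size ratio.
#' @export
size_ratio <- function(K, w = 32) {
  if (any(K <= 0)) stop("K must be positive")
  h <- w / 2
  ifelse(K <= 1, (K / h + K + 1) / (K + 1), (2 + K / h) / (1 + K))
}

#' Exhaustive q-gram position map (test oracle)
#'
#' Brute-force scan equivalent of the classical address/position table:
#' ground truth that `indexpair`/`lookup_positions` are checked against.
#' @param text an `encoded_seq`.
#' @param q q-gram length.
#' @return named list mapping q-gram code (as produced by scanning, keys
#'   are decimal strings) to the sorted 0-based occurrence positions.
#' @export
naive_qgram_positions <- function(text, q) {
  g <- qgram_codes(text, q)
  keep <- !is.na(g)
  if (!any(keep)) return(structure(list(), names = character(0)))
  pos <- which(keep) - 1L
  out <- split(pos, qgram_key(g[keep]))
  lapply(out, sort)
}

# Total words held by a built index (I + S + S' + O).
index_words <- function(index) {
  length(index$I) + length(index$S) + length(index$S_prime) + length(index$O)
}
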