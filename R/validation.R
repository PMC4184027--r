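# Validation: bit-parallel semi-global edit distance around each candidate
# diagonal, backward pass for the alignment start, percent-identity filter.
#
# The computation follows Myers' bit-parallel recurrence, blocked across
# 64-bit words for reads longer than one word. The diagonal band is
# realised through the extent of the reference window handed to the
# scorer: a window reaching pad bases beyond each end of the diagonal
# placement admits no alignment path whose diagonal excursion exceeds pad,
# so scoring full columns of that window *is* the band-restricted optimum.

#' Banded semi-global edit distance
#'
#' Minimal unit-cost (Levenshtein) distance of the read against any
#' substring of the reference window (read global, window local), computed
#' with the bit-parallel column recurrence in O(|window| * ceil(|r|/64)).
#'
#' @param read an `encoded_seq` or integer code vector.
#' @param ref_window an `encoded_seq` or integer code vector; its extent
#'   defines the diagonal band (see [validate_hits()]).
#' @return list with `k` (distance) and `end` (smallest 0-based half-open
#'   window end position attaining it; 0 when the empty prefix is optimal).
#' @export
banded_myers_distance <- function(read, ref_window) {
  r <- if (inherits(read, "encoded_seq")) read$codes else as.integer(read)
  w <- if (inherits(ref_window, "encoded_seq")) ref_window$codes else as.integer(ref_window)
  myers_semiglobal_cpp(r, w)
}

#' Locate the alignment start by a backward pass
#'
#' Runs the same bit-parallel computation on the reversed read against the
#' reversed window prefix ending at `end_pos`. Among backward end
#' positions attaining the forward distance `k`, the largest is taken, so
#' ties resolve toward the smallest `ref_start`.
#'
#' @param read,ref_window as in [banded_myers_distance()].
#' @param k forward-pass distance.
#' @param end_pos forward-pass half-open end position.
#' @return 0-based alignment start within the window.
#' @export
locate_start <- function(read, ref_window, k, end_pos) {
  r <- if (inherits(read, "encoded_seq")) read$codes else as.integer(read)
  w <- if (inherits(ref_window, "encoded_seq")) ref_window$codes else as.integer(ref_window)
  if (end_pos == 0L) return(0L)
  prof <- myers_profile_cpp(rev(r), rev(w[seq_len(end_pos)]))
  kmin <- min(prof)
  if (kmin != k) {
    stop(sprintf("backward pass distance %d != forward distance %d", kmin, k))
  }
  end_pos - max(which(prof == kmin))
}

#' Validate candidate hits
#'
#' Expands each candidate diagonal to the window
#' `[diagonal - pad, diagonal + |r| + pad)` (pad = `band_width / 2`,
#' clipped to the chromosome), scores it, and keeps hits whose percent
#' identity `s = 100 * (|r| - k) / |r|` reaches the threshold. Identical
#' validated loci arising from distinct candidates are collapsed.
#'
#' @param candidates data.table with columns `read_id`, `strand`, `chrom`,
#'   `diagonal` (forward 0-based putative read start).
#' @param batch the `read_batch` the candidates refer to.
#' @param ref the `ref_index`.
#' @param identity_threshold minimal percent identity, in (0, 100];
#'   default 80.
#' @param band_width diagonal band in columns (default 32); the window
#'   pads `band_width / 2` on each side.
#' @return data.table of validated hits: `read_id`, `strand`, `chrom`,
#'   `ref_start`, `ref_end` (0-based half-open on the forward reference),
#'   `k`, `read_len`, `s`.
#' @export
validate_hits <- function(candidates, batch, ref, identity_threshold = 80,
                          band_width = 32L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 100)
  pad <- band_width %/% 2L
  n <- nrow(candidates)
  out <- vector("list", n)
  # oriented read codes are cached per (read, strand)
  rc_cache <- new.env(parent = emptyenv())
  oriented <- function(rid, strand) {
    if (strand == "+") return(batch$reads[[rid]]$codes)
    key <- as.character(rid)
    v <- rc_cache[[key]]
    if (is.null(v)) {
      v <- reverse_complement(batch$reads[[rid]])$codes
      rc_cache[[key]] <- v
    }
    v
  }
  for (t in seq_len(n)) {
    rid <- candidates$read_id[t]
    strand <- candidates$strand[t]
    chrom <- candidates$chrom[t]
    diag <- candidates$diagonal[t]
    rcodes <- oriented(rid, strand)
    L <- length(rcodes)
    ch <- ref$chromosomes[[chrom]]
    win_start <- max(0L, diag - pad)
    win_end <- min(ch$seq$length, diag + L + pad)
    if (win_end <= win_start) next
    window <- ch$seq$codes[(win_start + 1L):win_end]
    res <- myers_semiglobal_cpp(rcodes, window)
    k <- res$k
    s <- 100 * (L - k) / L
    if (s < identity_threshold || res$end == 0L) next
    start_in_win <- locate_start(rcodes, window, k, res$end)
    out[[t]] <- data.table::data.table(
      read_id = rid, strand = strand, chrom = chrom,
      ref_start = win_start + start_in_win,
      ref_end = win_start + res$end,
      k = k, read_len = L, s = s)
  }
  out <- data.table::rbindlist(out)
  if (nrow(out) == 0L) {
    return(data.table::data.table(
      read_id = integer(0), strand = character(0), chrom = character(0),
      ref_start = integer(0), ref_end = integer(0), k = integer(0),
      read_len = integer(0), s = numeric(0)))
  }
  # post-validation dedup: one hit per validated locus, best k wins
  data.table::setorderv(out, c("read_id", "chrom", "strand", "ref_start", "k"))
  out <- out[, utils::head(.SD, 1L),
             by = c("read_id", "chrom", "strand", "ref_start")]
  data.table::setcolorder(out, c("read_id", "strand", "chrom", "ref_start",
                                 "ref_end", "k", "read_len", "s"))
  out[]
}
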