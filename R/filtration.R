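# Filtration: index the read batch, stream the reference's pair list P
# against it, emit candidate (read, strand, diagonal) triples.
#
# The economy of the design is that the q-group index is built over the
# concatenated reads of a batch (built once per batch) while the reference
# is streamed, chromosome by chromosome, forward then reverse-complemented.

#' Collect reads into fixed-slot batches
#'
#' Reads are padded into slots of `slot_length = max(read length)` within a
#' batch, so the in-batch position `o` of a q-gram occurrence recovers the
#' read as `o %/% slot_length` and the in-read offset as `o %% slot_length`.
#' Slot padding is never indexable, and no q-gram window can span two
#' reads. Reads shorter than `q` are skipped with a warning and counted in
#' the `skipped` attribute of the result.
#'
#' @param names,seqs,quals parallel vectors describing the reads; `seqs`
#'   are DNA strings.
#' @param q q-gram length the batch index will use.
#' @param buffer_size maximum reads per batch.
#' @param seed seed for ambiguous-base replacement.
#' @param mate optional integer vector (1/2) marking mate membership for
#'   paired input.
#' @param n_run_threshold see [encode_sequence()].
#' @return list of `read_batch` objects.
#' @export
make_read_batches <- function(names, seqs, quals = NULL, q = 16L,
                              buffer_size = 10000L, seed = 0L, mate = NULL,
                              n_run_threshold = 10L) {
  stopifnot(length(names) == length(seqs))
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (is.null(mate)) mate <- rep(0L, length(seqs))
  too_short <- nchar(seqs) < q
  if (any(too_short)) {
    warning(sprintf("%d read(s) shorter than q=%d skipped", sum(too_short), q))
  }
  keep <- which(!too_short)
  n_skipped <- sum(too_short)
  starts <- seq(1L, length.out = ceiling(length(keep) / buffer_size),
                by = buffer_size)
  batches <- lapply(starts, function(s) {
    idx <- keep[s:min(s + buffer_size - 1L, length(keep))]
    enc <- lapply(seq_along(idx), function(ii) {
      encode_sequence(seqs[idx[ii]],
                      seed = (seed + idx[ii]) %% .Machine$integer.max,
                      n_run_threshold = n_run_threshold)
    })
    lens <- vapply(enc, `[[`, 0L, "length")
    slot <- max(lens)
    count <- length(idx)
    concat_codes <- integer(count * slot)
    valid <- logical(count * slot - q + 1L)
    runs <- NULL
    for (ii in seq_len(count)) {
      base <- (ii - 1L) * slot
      concat_codes[base + seq_len(lens[ii])] <- enc[[ii]]$codes
      if (lens[ii] >= q) {
        ok <- valid_qgram_starts(enc[[ii]], q) # honours in-read N runs
        valid[base + which(ok)] <- TRUE
      }
      if (lens[ii] < slot) {
        runs <- rbind(runs, c(base + lens[ii], base + slot))
      }
    }
    if (is.null(runs)) {
      runs <- matrix(integer(0), ncol = 2)
    }
    colnames(runs) <- c("start", "end")
    concat <- structure(
      list(codes = concat_codes, length = length(concat_codes),
           n_mask = integer(0), skipped_runs = runs),
      class = "encoded_seq")
    structure(
      list(names = names[idx], reads = enc, quals = quals[idx],
           mate = mate[idx], global_index = idx, count = count,
           slot_length = slot, concat = concat, valid = valid,
           read_lengths = lens),
      class = "read_batch")
  })
  attr(batches, "skipped") <- n_skipped
  batches
}

#' Build the q-group index of a read batch
#' @param batch a `read_batch`.
#' @param q,w,half_sample see [build_qgroup_index()].
#' @return a `qgroup_index` over the concatenated slots.
#' @export
build_batch_index <- function(batch, q, w = 32L, half_sample = FALSE) {
  idx <- build_qgroup_index(batch$concat, q, w, half_sample,
                            valid = batch$valid)
  idx$slot_length <- batch$slot_length
  idx
}

#' Stream one chromosome's pair list against a batch index
#'
#' Implements the count / exclusive-prefix-sum / scatter scheme: for every
#' pair (g, p) of the reference stream and every occurrence o of g in the
#' batch index, a raw hit with `read_id = o %/% slot_length` and diagonal
#' `p - o %% slot_length` is written. The minus strand is handled by
#' streaming the reverse-complemented chromosome and mapping diagonals back
#' to forward coordinates (`chrom_len - diagonal - read_len`).
#'
#' @param batch_index the index built by [build_batch_index()].
#' @param batch the corresponding `read_batch`.
#' @param P_g,P_pos the reference stream (codes and 0-based positions).
#' @param q q-gram length of the stream; must match the index.
#' @param strand `"+"` or `"-"` label attached to the hits.
#' @param chrom_len chromosome length, needed to transform minus-strand
#'   diagonals.
#' @return data.table of raw (pre-deduplication) hits with columns
#'   `read_id` (1-based into the batch), `strand`, `diagonal`.
#' @export
generate_hits <- function(batch_index, batch, P_g, P_pos, q,
                          strand = "+", chrom_len = NULL) {
  if (batch_index$q != q) {
    stop(sprintf("q mismatch: batch index has q=%d, reference stream q=%d",
                 batch_index$q, q))
  }
  raw <- qgi_stream_cpp(batch_index$I, batch_index$S, batch_index$S_prime,
                        batch_index$O, batch_index$half_sampled,
                        batch_index$w, P_g, P_pos, batch$slot_length)
  dt <- data.table::data.table(read_id = raw$read_id + 1L,
                               diagonal = raw$diagonal)
  if (strand == "-") {
    if (is.null(chrom_len)) stop("chrom_len required for minus-strand hits")
    dt[, diagonal := chrom_len - diagonal - batch$read_lengths[read_id]]
  }
  dt[, strand := strand]
  dt[]
}

#' Collapse candidate diagonals
#'
#' Exact duplicates of (read, strand, diagonal) are merged, then diagonals
#' of one read/strand lying within `delta` of each other are chained into
#' one cluster represented by its best-supported diagonal (most raw
#' q-gram hits, ties to the smaller diagonal). Diagonals that would start
#' before the contig are clamped to 0; the validation window absorbs the
#' overhang.
#'
#' @param hits raw hits from [generate_hits()] (a `chrom` column may be
#'   present and is honoured).
#' @param delta diagonal merge distance (default 3).
#' @return deduplicated candidates with a `support` column.
#' @export
dedup_candidates <- function(hits, delta = 3L) {
  if (nrow(hits) == 0L) {
    out <- data.table::copy(hits)
    out[, `:=`(support = integer(0))]
    return(out[])
  }
  by_cols <- intersect(c("read_id", "strand", "chrom", "diagonal"),
                       names(hits))
  dt <- hits[, list(mult = .N), by = by_cols]
  dt[diagonal < 0L, diagonal := 0L]
  dt <- dt[, list(mult = sum(mult)),
           by = setdiff(by_cols, "diagonal") |> c("diagonal")]
  grp <- setdiff(by_cols, "diagonal")
  data.table::setorderv(dt, c(grp, "diagonal"))
  dt[, cluster := cumsum(c(1L, diff(diagonal) > delta)), by = grp]
  out <- dt[, {
    best <- which.max(mult)
    list(diagonal = diagonal[best], support = sum(mult))
  }, by = c(grp, "cluster")]
  out[, cluster := NULL]
  out[]
}
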