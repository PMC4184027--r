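# The mapping pipeline: batch reads, index the batch, stream each
# chromosome forward and reverse-complemented, validate candidates,
# postprocess into SAM records.

#' Mapping run configuration
#'
#' Bundles every tunable of the pipeline with its default. The defaults
#' are q = 16 (a 2-bit 16-mer fills one 32-bit word), identity threshold
#' 80, best-stratum reporting, likelihood decay lambda = 1 with constant
#' C = 1 and mapping-quality cap 60.
#'
#' @param q q-gram length (1..16).
#' @param w group width of the q-group index in bits.
#' @param identity_threshold minimal percent identity of a reported hit,
#'   in (0, 100].
#' @param mode `"best-stratum"` or `"all"`.
#' @param lambda,likelihood_const likelihood model parameters.
#' @param mapq_cap maximum reported mapping quality.
#' @param buffer_size reads per batch.
#' @param mask_absolute_cap,mask_frequency_cap frequent-q-gram masking (see
#'   [build_reference_index()]); only consulted when the reference is
#'   built by this call.
#' @param insert_min,insert_max proper-pair template length limits.
#' @param delta diagonal merge distance during candidate deduplication.
#' @param band_width validation band (window pad = band_width / 2).
#' @param alignment_style `"semi-global"` or `"local"` traceback.
#' @param seed master seed; all randomness (ambiguous-base replacement)
#'   derives from it.
#' @param n_run_threshold minimum N-run length excluded from indexing.
#' @param half_sample store only every second entry of the batch index's
#'   S array.
#' @return a `run_config` list.
#' @export
run_config <- function(q = 16L, w = 32L, identity_threshold = 80,
                       mode = c("best-stratum", "all"), lambda = 1,
                       likelihood_const = 1, mapq_cap = 60L,
                       buffer_size = 10000L, mask_absolute_cap = 1000,
                       mask_frequency_cap = 1e-4, insert_min = 0L,
                       insert_max = 1000L, delta = 3L, band_width = 32L,
                       alignment_style = c("semi-global", "local"),
                       seed = 0L, n_run_threshold = 10L,
                       half_sample = FALSE) {
  mode <- match.arg(mode)
  alignment_style <- match.arg(alignment_style)
  stopifnot(q >= 1, q <= 16, w >= 1, w <= 32,
            identity_threshold > 0, identity_threshold <= 100,
            lambda > 0, likelihood_const > 0, mapq_cap >= 0,
            buffer_size >= 1, insert_min >= 0, insert_max >= insert_min,
            delta >= 0, band_width >= 2, band_width <= 64)
  structure(list(
    q = as.integer(q), w = as.integer(w),
    identity_threshold = identity_threshold, mode = mode,
    lambda = lambda, likelihood_const = likelihood_const,
    mapq_cap = as.integer(mapq_cap), buffer_size = as.integer(buffer_size),
    mask_absolute_cap = mask_absolute_cap,
    mask_frequency_cap = mask_frequency_cap,
    insert_min = as.integer(insert_min), insert_max = as.integer(insert_max),
    delta = as.integer(delta), band_width = as.integer(band_width),
    alignment_style = alignment_style, seed = as.integer(seed),
    n_run_threshold = as.integer(n_run_threshold),
    half_sample = isTRUE(half_sample)), class = "run_config")
}

config_string <- function(config) {
  paste(vapply(names(config), function(n) {
    sprintf("--%s=%s", n, as.character(config[[n]]))
  }, character(1)), collapse = " ")
}

# The reverse-complement stream of one chromosome: encoded rc sequence and
# its masked, sorted pair list.
.rc_stream <- function(ch, q, mask_absolute_cap, mask_frequency_cap) {
  rc <- reverse_complement(ch$seq)
  c(list(seq = rc), build_P(rc, q, mask_absolute_cap, mask_frequency_cap))
}

#' Map reads against a reference index
#'
#' Runs the full filtration / validation / postprocessing pipeline and
#' returns (and optionally writes) SAM text. Given a fixed seed, inputs
#' and configuration the output is byte-identical across runs.
#'
#' @param ref a `ref_index` (see [build_reference_index()]).
#' @param reads FASTQ path, or a list with components `names`, `seqs` and
#'   optionally `quals`.
#' @param reads2 second FASTQ path / list for paired-end input, or NULL.
#' @param config a [run_config()].
#' @param output optional path; when given the SAM text is written there.
#' @return invisibly, a list with `sam` (character vector of SAM lines)
#'   and `stats` (per-batch candidate/validated/reported counts).
#' @export
map_reads <- function(ref, reads, reads2 = NULL, config = run_config(),
                      output = NULL) {
  stopifnot(inherits(ref, "ref_index"))
  if (config$q != ref$q) {
    stop(sprintf("configured q=%d does not match reference index q=%d",
                 config$q, ref$q))
  }
  rd1 <- if (is.character(reads)) read_fastq(reads) else reads
  if (is.null(rd1$quals)) rd1$quals <- strrep("I", nchar(rd1$seqs))
  paired <- !is.null(reads2)
  if (paired) {
    rd2 <- if (is.character(reads2)) read_fastq(reads2) else reads2
    if (is.null(rd2$quals)) rd2$quals <- strrep("I", nchar(rd2$seqs))
    if (length(rd1$seqs) != length(rd2$seqs)) {
      stop("paired FASTQ inputs differ in read count")
    }
    n <- length(rd1$seqs)
    ord <- rep(seq_len(n), each = 2L)
    pick <- rep(c(1L, 2L), n)
    nm <- ifelse(pick == 1L, rd1$names[ord], rd2$names[ord])
    sq <- ifelse(pick == 1L, rd1$seqs[ord], rd2$seqs[ord])
    ql <- ifelse(pick == 1L, rd1$quals[ord], rd2$quals[ord])
    mate <- pick
    buffer <- 2L * ceiling(config$buffer_size / 2L) # whole pairs per batch
  } else {
    nm <- rd1$names
    sq <- rd1$seqs
    ql <- rd1$quals
    mate <- rep(0L, length(sq))
    buffer <- config$buffer_size
  }
  batches <- make_read_batches(nm, sq, ql, q = config$q,
                               buffer_size = buffer, seed = config$seed,
                               mate = mate,
                               n_run_threshold = config$n_run_threshold)

  chrom_names <- names(ref$chromosomes)
  rc_streams <- lapply(ref$chromosomes, .rc_stream, q = config$q,
                       mask_absolute_cap = ref$params$mask_absolute_cap,
                       mask_frequency_cap = ref$params$mask_frequency_cap)

  sam_body <- character(0)
  stats <- list()
  for (bi in seq_along(batches)) {
    batch <- batches[[bi]]
    bidx <- build_batch_index(batch, config$q, config$w, config$half_sample)
    hit_parts <- list()
    for (cn in chrom_names) {
      ch <- ref$chromosomes[[cn]]
      if (length(ch$P_pos)) {
        h <- generate_hits(bidx, batch, ch$P_g, ch$P_pos, config$q,
                           strand = "+")
        if (nrow(h)) {
          h[, chrom := cn]
          hit_parts[[length(hit_parts) + 1L]] <- h
        }
      }
      rcs <- rc_streams[[cn]]
      if (length(rcs$P_pos)) {
        h <- generate_hits(bidx, batch, rcs$P_g, rcs$P_pos, config$q,
                           strand = "-", chrom_len = ch$seq$length)
        if (nrow(h)) {
          h[, chrom := cn]
          hit_parts[[length(hit_parts) + 1L]] <- h
        }
      }
    }
    raw_hits <- data.table::rbindlist(hit_parts)
    if (nrow(raw_hits) == 0L) {
      raw_hits <- data.table::data.table(read_id = integer(0),
                                         diagonal = integer(0),
                                         strand = character(0),
                                         chrom = character(0))
    }
    cands <- dedup_candidates(raw_hits, delta = config$delta)
    validated <- validate_hits(cands, batch, ref,
                               identity_threshold = config$identity_threshold,
                               band_width = config$band_width)
    recs <- postprocess_batch(validated, batch, ref, config, paired)
    sam_body <- c(sam_body, recs)
    reported <- if (length(recs)) {
      fl <- as.integer(data.table::tstrsplit(recs, "\t", keep = 2L)[[1]])
      sum(bitwAnd(fl, 4L) == 0L)
    } else 0L
    stats[[bi]] <- list(batch = bi, reads = batch$count,
                        candidates = nrow(cands),
                        validated = nrow(validated),
                        reported = reported)
  }
  sam <- c(sam_header(ref, config_string(config)), sam_body)
  if (!is.null(output)) writeLines(sam, output)
  invisible(list(sam = sam, stats = stats))
}

# --- SAM record assembly -----------------------------------------------------

.sam_line <- function(qname, flag, rname, pos1, mapq, cigar, rnext, pnext1,
                      tlen, seq, qual, tags = character(0)) {
  paste(c(qname, flag, rname, pos1, mapq, cigar, rnext, pnext1, tlen, seq,
          qual, tags), collapse = "\t")
}

.oriented_seq_qual <- function(batch, rid, strand) {
  enc <- batch$reads[[rid]]
  qual <- batch$quals[rid]
  if (strand == "+") {
    list(seq = decode_sequence(enc), qual = qual)
  } else {
    list(seq = decode_sequence(reverse_complement(enc)),
         qual = paste(rev(strsplit(qual, "")[[1]]), collapse = ""))
  }
}

.hit_record <- function(batch, ref, config, rid, hit, mapq, rank, primary,
                        flag_extra = 0L, rnext = "*", pnext1 = 0L, tlen = 0L) {
  sq <- .oriented_seq_qual(batch, rid, hit$strand)
  rcodes <- if (hit$strand == "+") {
    batch$reads[[rid]]$codes
  } else {
    reverse_complement(batch$reads[[rid]])$codes
  }
  ch <- ref$chromosomes[[hit$chrom]]
  tb <- traceback_alignment(rcodes, ch$seq$codes, hit$ref_start, hit$ref_end,
                            style = config$alignment_style)
  flag <- flag_extra
  if (hit$strand == "-") flag <- flag + 16L
  if (!primary) flag <- flag + 256L
  .sam_line(batch$names[rid], flag, hit$chrom, tb$ref_start + 1L, mapq,
            tb$cigar, rnext, pnext1, tlen, sq$seq, sq$qual,
            c(sprintf("NM:i:%d", tb$nm),
              sprintf("AS:i:%d", as.integer(round(hit$s))),
              sprintf("XR:i:%d", rank)))
}

.unmapped_record <- function(batch, rid, flag_extra = 0L) {
  sq <- list(seq = decode_sequence(batch$reads[[rid]]), qual = batch$quals[rid])
  .sam_line(batch$names[rid], 4L + flag_extra, "*", 0L, 0L, "*", "*", 0L, 0L,
            sq$seq, sq$qual)
}

# Records for one batch. Single-end: strata + per-read posterior. Paired:
# mates are paired into units (proper pairs ranked by summed identity,
# leftover single placements after all pairs) and the posterior is taken
# over a fragment's units.
postprocess_batch <- function(validated, batch, ref, config, paired) {
  chrom_order <- stats::setNames(seq_along(ref$chromosomes),
                                 names(ref$chromosomes))
  recs <- character(0)
  if (!paired) {
    for (rid in seq_len(batch$count)) {
      hits <- validated[read_id == rid]
      if (nrow(hits) == 0L) {
        recs <- c(recs, .unmapped_record(batch, rid))
        next
      }
      mq <- mapping_quality(hits$s, config$lambda, config$likelihood_const,
                            config$mapq_cap)
      hits[, mapq := mq$mapq]
      rep_hits <- build_strata(hits, mode = config$mode)
      data.table::setorderv(
        rep_hits[, J := chrom_order[chrom]],
        c("stratum_rank", "J", "ref_start"))
      for (t in seq_len(nrow(rep_hits))) {
        recs <- c(recs, .hit_record(batch, ref, config, rid, rep_hits[t],
                                    rep_hits$mapq[t], rep_hits$stratum_rank[t],
                                    primary = (t == 1L)))
      }
    }
    return(recs)
  }
  # paired: reads come interleaved (mate 1, mate 2, ...)
  n_frag <- batch$count %/% 2L
  for (fi in seq_len(n_frag)) {
    rid1 <- 2L * fi - 1L
    rid2 <- 2L * fi
    h1 <- validated[read_id == rid1]
    h2 <- validated[read_id == rid2]
    pm <- pair_mates(h1, h2, config$insert_min, config$insert_max)
    units <- list()
    if (nrow(pm$pairs)) {
      for (t in seq_len(nrow(pm$pairs))) {
        a <- pm$pairs$i1[t]
        b <- pm$pairs$i2[t]
        units[[length(units) + 1L]] <- list(
          type = "pair", i1 = a, i2 = b,
          score_num = pm$pairs$score_num[t],
          s_total = h1$s[a] + h2$s[b],
          err_pct = (100 - h1$s[a]) + (100 - h2$s[b]),
          left = min(h1$ref_start[a], h2$ref_start[b]),
          chromJ = chrom_order[h1$chrom[a]], tlen = pm$pairs$tlen[t])
      }
    }
    for (a in which(!pm$used1)) {
      units[[length(units) + 1L]] <- list(
        type = "single1", i1 = a, i2 = NA_integer_,
        score_num = NA_real_, s_total = h1$s[a],
        err_pct = (100 - h1$s[a]) + 100,
        left = h1$ref_start[a], chromJ = chrom_order[h1$chrom[a]],
        tlen = 0L)
    }
    for (b in which(!pm$used2)) {
      units[[length(units) + 1L]] <- list(
        type = "single2", i1 = NA_integer_, i2 = b,
        score_num = NA_real_, s_total = h2$s[b],
        err_pct = 100 + (100 - h2$s[b]),
        left = h2$ref_start[b], chromJ = chrom_order[h2$chrom[b]],
        tlen = 0L)
    }
    if (length(units) == 0L) {
      recs <- c(recs,
                .unmapped_record(batch, rid1, flag_extra = 1L + 8L + 64L),
                .unmapped_record(batch, rid2, flag_extra = 1L + 8L + 128L))
      next
    }
    ud <- data.table::rbindlist(lapply(units, function(u) {
      data.table::data.table(type = u$type, score_num = u$score_num,
                             s_total = u$s_total, left = u$left,
                             chromJ = u$chromJ)
    }))
    # proper pairs first (summed identity, exact integer key), then
    # leftover single placements by their own identity
    is_pair <- ud$type == "pair"
    key <- ifelse(is_pair, 1e6 + ud$score_num, ud$s_total)
    ord <- order(-is_pair, -key, ud$chromJ, ud$left)
    units <- units[ord]
    key <- key[ord]
    rank <- cumsum(c(TRUE, diff(key) != 0))
    # posterior over the fragment's units; a lone mate placement counts the
    # missing mate as fully erroneous, so proper pairs dominate
    err_pct <- vapply(units, `[[`, 0, "err_pct")
    lik <- config$likelihood_const * exp(-config$lambda * err_pct)
    post <- lik / sum(lik)
    q_raw <- -10 * log10(1 - post)
    mqv <- as.integer(ifelse(is.infinite(q_raw), config$mapq_cap,
                             pmin(floor(q_raw), config$mapq_cap)))
    if (sum(rank == 1L) >= 2L) mqv[rank == 1L] <- 0L
    mq <- list(mapq = mqv, posterior = post)
    keep <- if (config$mode == "best-stratum") which(rank == 1L) else
      seq_along(units)
    mate1_mapped <- any(vapply(units[keep], function(u) !is.na(u$i1), TRUE))
    mate2_mapped <- any(vapply(units[keep], function(u) !is.na(u$i2), TRUE))
    first_unit <- TRUE
    for (t in keep) {
      u <- units[[t]]
      primary <- first_unit
      first_unit <- FALSE
      if (u$type == "pair") {
        a <- u$i1
        b <- u$i2
        hit1 <- h1[a]
        hit2 <- h2[b]
        tl1 <- if (hit1$ref_start <= hit2$ref_start) u$tlen else -u$tlen
        base1 <- 1L + 2L + 64L + (if (hit2$strand == "-") 32L else 0L)
        base2 <- 1L + 2L + 128L + (if (hit1$strand == "-") 32L else 0L)
        recs <- c(recs,
          .hit_record(batch, ref, config, rid1, hit1, mq$mapq[t], rank[t],
                      primary, flag_extra = base1, rnext = "=",
                      pnext1 = hit2$ref_start + 1L, tlen = tl1),
          .hit_record(batch, ref, config, rid2, hit2, mq$mapq[t], rank[t],
                      primary, flag_extra = base2, rnext = "=",
                      pnext1 = hit1$ref_start + 1L, tlen = -tl1))
      } else if (u$type == "single1") {
        flag <- 1L + 64L + (if (!mate2_mapped) 8L else 0L)
        recs <- c(recs, .hit_record(batch, ref, config, rid1, h1[u$i1],
                                    mq$mapq[t], rank[t], primary,
                                    flag_extra = flag))
      } else {
        flag <- 1L + 128L + (if (!mate1_mapped) 8L else 0L)
        recs <- c(recs, .hit_record(batch, ref, config, rid2, h2[u$i2],
                                    mq$mapq[t], rank[t], primary,
                                    flag_extra = flag))
      }
    }
    if (!mate1_mapped) {
      recs <- c(recs, .unmapped_record(batch, rid1, flag_extra = 1L + 64L))
    }
    if (!mate2_mapped) {
      recs <- c(recs, .unmapped_record(batch, rid2, flag_extra = 1L + 128L))
    }
  }
  recs
}
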