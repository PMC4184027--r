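# Truth-based fixture generation and evaluation: uniform random genomes,
# reads with planted substitutions and short indels, and
# sensitivity/recall/precision against the recorded origins.

#' Simulate a uniform random genome
#'
#' Bases are drawn i.i.d. uniformly from ACGT; deterministic per seed. A
#' repeat-injection option copies one segment to extra loci to exercise
#' ambiguous-hit behaviour (mapping quality 0) on demand.
#'
#' @param length genome length (>= 1).
#' @param seed RNG seed.
#' @param name sequence name.
#' @param repeat_segment optional list `list(start, width, times)`
#'   (0-based start): the segment is copied to `times` random non-adjacent
#'   loci.
#' @return named character vector of length 1 (the sequence).
#' @export
simulate_genome <- function(length, seed = 1L, name = "chr1",
                            repeat_segment = NULL) {
  if (length < 1) stop("genome length must be >= 1")
  bases <- c("A", "C", "G", "T")
  seqc <- with_seed(seed, {
    x <- sample(bases, length, replace = TRUE)
    if (!is.null(repeat_segment)) {
      rs <- repeat_segment
      seg <- x[(rs$start + 1):(rs$start + rs$width)]
      tgt <- sample(seq_len(length - rs$width), rs$times)
      for (t in tgt) x[t:(t + rs$width - 1L)] <- seg
    }
    paste(x, collapse = "")
  })
  stats::setNames(seqc, name)
}

#' Simulate reads with planted edits
#'
#' Reads are sampled uniformly over valid positions and strands of the
#' genome. Each read carries `sample(0:max_subs, 1)` substitutions (always
#' to a different base, at distinct positions) and `sample(0:max_indels,
#' 1)` indels of length `1..indel_max_len`; the window extracted from the
#' genome is lengthened/shortened so the final read length is exact. In
#' paired mode forward-reverse pairs are drawn with Normal insert size.
#' Origins and planted edit counts are recorded as the truth table.
#'
#' @param genome named character vector (one or more chromosomes).
#' @param n_reads number of reads (fragments in paired mode).
#' @param read_len read length.
#' @param max_subs,max_indels per-read maxima of planted substitutions and
#'   indels.
#' @param indel_max_len maximal length of one planted indel.
#' @param paired generate mate pairs.
#' @param insert_mean,insert_sd Normal template length for paired mode.
#' @param seed RNG seed.
#' @return list with `names`, `seqs`, `quals` (and `names2`, `seqs2`,
#'   `quals2` in paired mode) plus `truth`, a data.table with one row per
#'   read: `qname`, `mate` (0 = single-end), `chrom`, `strand`, `start`
#'   (0-based forward start of the origin window), `window_len`,
#'   `k_planted` (substitutions + inserted + deleted bases).
#' @export
simulate_reads <- function(genome, n_reads, read_len = 100L, max_subs = 0L,
                           max_indels = 0L, indel_max_len = 3L,
                           paired = FALSE, insert_mean = 300, insert_sd = 30,
                           seed = 1L) {
  chroms <- names(genome)
  lens <- nchar(genome)
  if (any(lens < read_len)) stop("read_len exceeds a chromosome length")
  with_seed(seed, {
    if (!paired) {
      out <- .sim_single(genome, chroms, lens, n_reads, read_len, max_subs,
                         max_indels, indel_max_len, prefix = "read")
      out$truth[, mate := 0L]
      return(out)
    }
    .sim_paired(genome, chroms, lens, n_reads, read_len, max_subs,
                max_indels, indel_max_len, insert_mean, insert_sd)
  })
}

# one oriented read with planted edits; origin is `window` (oriented)
.plant_edits <- function(window_bases, read_len, n_subs, ins_ops, del_ops) {
  bases <- c("A", "C", "G", "T")
  x <- window_bases
  # deletions then insertions (positions drawn on the current vector)
  for (d in del_ops) {
    p <- sample(length(x) - d + 1L, 1L)
    x <- x[-(p:(p + d - 1L))]
  }
  for (d in ins_ops) {
    p <- sample(length(x) + 1L, 1L)
    x <- append(x, sample(bases, d, replace = TRUE), after = p - 1L)
  }
  stopifnot(length(x) == read_len)
  if (n_subs > 0L) {
    ps <- sample(read_len, n_subs)
    for (p in ps) x[p] <- sample(setdiff(bases, x[p]), 1L)
  }
  paste(x, collapse = "")
}

.draw_edit_plan <- function(max_subs, max_indels, indel_max_len, read_len) {
  n_subs <- sample(0:max_subs, 1L)
  n_ind <- sample(0:max_indels, 1L)
  ins_ops <- integer(0)
  del_ops <- integer(0)
  if (n_ind > 0L) {
    for (i in seq_len(n_ind)) {
      d <- sample(indel_max_len, 1L)
      if (runif(1) < 0.5) ins_ops <- c(ins_ops, d) else del_ops <- c(del_ops, d)
    }
  }
  window_len <- read_len + sum(del_ops) - sum(ins_ops)
  list(n_subs = n_subs, ins_ops = ins_ops, del_ops = del_ops,
       window_len = window_len, k = n_subs + sum(ins_ops) + sum(del_ops))
}

.sim_single <- function(genome, chroms, lens, n_reads, read_len, max_subs,
                        max_indels, indel_max_len, prefix) {
  seqs <- character(n_reads)
  truth <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    repeat {
      plan <- .draw_edit_plan(max_subs, max_indels, indel_max_len, read_len)
      if (plan$window_len >= 1L && plan$window_len <= min(lens)) break
    }
    ci <- sample(length(chroms), 1L, prob = lens)
    start <- sample(lens[ci] - plan$window_len + 1L, 1L) - 1L
    strand <- sample(c("+", "-"), 1L)
    win <- strsplit(substr(genome[[ci]], start + 1L,
                           start + plan$window_len), "")[[1]]
    if (strand == "-") win <- rev(c(T = "A", G = "C", C = "G", A = "T")[win])
    seqs[i] <- .plant_edits(win, read_len, plan$n_subs, plan$ins_ops,
                            plan$del_ops)
    truth[[i]] <- data.table::data.table(
      qname = sprintf("%s%06d", prefix, i), chrom = chroms[ci],
      strand = strand, start = start, window_len = plan$window_len,
      k_planted = plan$k)
  }
  list(names = sprintf("%s%06d", prefix, seq_len(n_reads)), seqs = seqs,
       quals = strrep("I", rep(read_len, n_reads)),
       truth = data.table::rbindlist(truth))
}

.sim_paired <- function(genome, chroms, lens, n_frags, read_len, max_subs,
                        max_indels, indel_max_len, insert_mean, insert_sd) {
  comp <- c(T = "A", G = "C", C = "G", A = "T")
  seqs1 <- character(n_frags)
  seqs2 <- character(n_frags)
  truth <- vector("list", 2L * n_frags)
  for (i in seq_len(n_frags)) {
    repeat {
      insert <- round(rnorm(1, insert_mean, insert_sd))
      if (insert >= read_len + 2L * indel_max_len &&
          insert <= min(lens)) break
    }
    ci <- sample(length(chroms), 1L, prob = lens)
    fstart <- sample(lens[ci] - insert + 1L, 1L) - 1L
    fwd_first <- runif(1) < 0.5 # which mate sits on the plus strand
    for (m in 1:2) {
      repeat {
        plan <- .draw_edit_plan(max_subs, max_indels, indel_max_len, read_len)
        if (plan$window_len >= 1L && plan$window_len <= insert) break
      }
      plus <- (m == 1L) == fwd_first
      start <- if (plus) fstart else fstart + insert - plan$window_len
      win <- strsplit(substr(genome[[ci]], start + 1L,
                             start + plan$window_len), "")[[1]]
      if (!plus) win <- rev(comp[win])
      sq <- .plant_edits(win, read_len, plan$n_subs, plan$ins_ops,
                         plan$del_ops)
      if (m == 1L) seqs1[i] <- sq else seqs2[i] <- sq
      truth[[2L * (i - 1L) + m]] <- data.table::data.table(
        qname = sprintf("frag%06d", i), mate = m, chrom = chroms[ci],
        strand = if (plus) "+" else "-", start = start,
        window_len = plan$window_len, k_planted = plan$k)
    }
  }
  nm <- sprintf("frag%06d", seq_len(n_frags))
  list(names = nm, seqs = seqs1, quals = strrep("I", rep(read_len, n_frags)),
       names2 = nm, seqs2 = seqs2,
       quals2 = strrep("I", rep(read_len, n_frags)),
       truth = data.table::rbindlist(truth))
}

#' Write / read a truth table
#'
#' Tab-separated sidecar with columns qname, mate, chrom, strand, start
#' (0-based), window_len, k_planted.
#' @param truth data.table from [simulate_reads()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  data.table::fread(path, sep = "\t",
                    colClasses = list(character = c("qname", "chrom", "strand")))
}

#' Evaluate mapping output against simulation truth
#'
#' A reported hit is correct when it matches the origin's chromosome and
#' strand and its (0-based) start lies within `tolerance_bp` of the true
#' start. Sensitivity is the fraction of reads whose true origin appears
#' among *any* reported hit (secondary included); recall the fraction
#' whose primary alignment is correct; precision the fraction of correct
#' reads among reads with exactly one reported hit.
#'
#' @param sam SAM path or character vector of SAM lines.
#' @param truth truth table from [simulate_reads()].
#' @param tolerance_bp positional tolerance (default 5).
#' @return list with `sensitivity`, `recall`, `precision`, `n_reads`.
#' @export
evaluate_mapping <- function(sam, truth, tolerance_bp = 5L) {
  aln <- parse_sam(sam)
  truth <- data.table::as.data.table(truth)
  if (!"mate" %in% names(truth)) truth[, mate := 0L]
  aln[, mate := ifelse(first_mate, 1L, ifelse(second_mate, 2L, 0L))]
  unknown <- setdiff(unique(aln$qname), unique(truth$qname))
  if (length(unknown)) {
    stop(sprintf("SAM contains %d read name(s) absent from the truth table (e.g. '%s')",
                 length(unknown), unknown[1]))
  }
  mapped <- aln[unmapped == FALSE]
  if (nrow(mapped)) {
    mapped[truth, on = c("qname", "mate"),
           correct := rname == i.chrom &
             ifelse(reverse, "-", "+") == i.strand &
             abs(pos - 1L - i.start) <= tolerance_bp]
    mapped[is.na(correct), correct := FALSE]
  } else {
    mapped[, correct := logical(0)]
  }
  per_read <- mapped[, list(any_ok = any(correct),
                            primary_ok = any(correct & !secondary),
                            n_hits = .N),
                     by = c("qname", "mate")]
  full <- per_read[truth[, c("qname", "mate")], on = c("qname", "mate")]
  full[is.na(any_ok), `:=`(any_ok = FALSE, primary_ok = FALSE, n_hits = 0L)]
  unamb <- full[n_hits == 1L]
  list(sensitivity = mean(full$any_ok),
       recall = mean(full$primary_ok),
       precision = if (nrow(unamb)) mean(unamb$any_ok) else NA_real_,
       n_reads = nrow(full))
}
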