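# Postprocessing: strata, mapping quality, mate pairing, traceback, SAM.

# Exact stratum scores. All hits of one read share |r|, so single-end
# strata compare by the integer k. Paired scores s1 + s2 with possibly
# different mate lengths are compared as exact rationals
# ((L1-k1)L2 + (L2-k2)L1) / (L1 L2) via integer cross-multiplication,
# never by float equality.
.pair_score_num <- function(k1, L1, k2, L2) {
  (L1 - k1) * L2 + (L2 - k2) * L1
}

#' Group a read's validated hits into percent-identity strata
#'
#' Hits sharing one exact percent identity form a stratum; strata are
#' ranked by identity, best first. In `best-stratum` mode only rank-1 hits
#' survive; `all` mode keeps every stratum.
#'
#' @param hits validated hits of *one* read (data.table from
#'   [validate_hits()]).
#' @param mode `"all"` or `"best-stratum"`.
#' @return the hits with a `stratum_rank` column (1 = best), filtered
#'   according to `mode`, ordered by rank then chromosome then position.
#' @export
build_strata <- function(hits, mode = c("best-stratum", "all")) {
  mode <- match.arg(mode)
  dt <- data.table::copy(hits)
  # same read => same |r|; identity order is the reverse of k order
  dt[, stratum_rank := match(k, sort(unique(k)))]
  if (mode == "best-stratum") dt <- dt[stratum_rank == 1L]
  data.table::setorderv(dt, c("stratum_rank", "chrom", "ref_start"))
  dt[]
}

#' Bayesian PHRED-scaled mapping qualities for one read's hits
#'
#' The sampling likelihood of a hit with percent identity s is
#' approximated as `C * exp(-lambda * (100 - s))`; the posterior of each
#' hit is its likelihood normalised over all validated hits of the read
#' (hits discarded at validation are treated as zero likelihood). The
#' reported quality is `min(floor(-10 * log10(1 - posterior)), cap)`, with
#' the cap applying when the posterior is 1, and is forced to 0 for every
#' hit tied at the best percent identity when two or more such hits exist.
#'
#' @param s percent identities of all validated hits of one read (or the
#'   summed identities of paired units).
#' @param lambda decay rate of the likelihood (default 1).
#' @param likelihood_const the constant C (default 1; it cancels in the
#'   posterior but is kept configurable).
#' @param cap maximum reported quality (default 60).
#' @param best_possible the identity value of a perfect hit (100
#'   single-end, 200 for summed pairs); only used for sanity checks.
#' @return list with `mapq` (integer vector) and `posterior`.
#' @export
mapping_quality <- function(s, lambda = 1, likelihood_const = 1, cap = 60L,
                            best_possible = 100) {
  stopifnot(length(s) >= 1L)
  lik <- likelihood_const * exp(-lambda * (best_possible - s))
  post <- lik / sum(lik)
  q_raw <- -10 * log10(1 - post)
  mq <- ifelse(is.infinite(q_raw), cap, pmin(floor(q_raw), cap))
  smax <- max(s)
  if (sum(s == smax) >= 2L) mq[s == smax] <- 0
  list(mapq = as.integer(mq), posterior = post)
}

#' Pair mate hits into proper pairs and singletons
#'
#' A proper pair requires the same chromosome, opposite strands in
#' forward-reverse orientation (the plus-strand mate starts no later than
#' the minus-strand mate) and an implied template length within
#' `[insert_min, insert_max]`. Pairings are chosen greedily by summed
#' percent identity (exact rational comparison), ties by leftmost
#' coordinate; each hit joins at most one reported pair.
#'
#' @param hits1,hits2 validated hits of the two mates of one fragment.
#' @param insert_min,insert_max template length limits.
#' @return list with `pairs` (data.table of index pairs `i1`, `i2` into
#'   `hits1`/`hits2` plus `tlen` and `score_num`) and logical vectors
#'   `used1`, `used2`.
#' @export
pair_mates <- function(hits1, hits2, insert_min = 0L, insert_max = 1000L) {
  empty <- data.table::data.table(i1 = integer(0), i2 = integer(0),
                                  tlen = integer(0), score_num = numeric(0))
  if (nrow(hits1) == 0L || nrow(hits2) == 0L) {
    return(list(pairs = empty, used1 = rep(FALSE, nrow(hits1)),
                used2 = rep(FALSE, nrow(hits2))))
  }
  cand <- data.table::CJ(i1 = seq_len(nrow(hits1)), i2 = seq_len(nrow(hits2)))
  h1 <- hits1[cand$i1]
  h2 <- hits2[cand$i2]
  same_chrom <- h1$chrom == h2$chrom
  fr <- (h1$strand == "+" & h2$strand == "-" & h1$ref_start <= h2$ref_start) |
        (h2$strand == "+" & h1$strand == "-" & h2$ref_start <= h1$ref_start)
  left <- pmin(h1$ref_start, h2$ref_start)
  right <- pmax(h1$ref_end, h2$ref_end)
  tlen <- right - left
  ok <- same_chrom & fr & tlen >= insert_min & tlen <= insert_max
  cand <- cand[ok]
  if (nrow(cand) == 0L) {
    return(list(pairs = empty, used1 = rep(FALSE, nrow(hits1)),
                used2 = rep(FALSE, nrow(hits2))))
  }
  cand[, `:=`(tlen = tlen[ok], left = left[ok],
              score_num = .pair_score_num(hits1$k[i1], hits1$read_len[i1],
                                          hits2$k[i2], hits2$read_len[i2]))]
  data.table::setorderv(cand, c("score_num", "left"), order = c(-1L, 1L))
  used1 <- rep(FALSE, nrow(hits1))
  used2 <- rep(FALSE, nrow(hits2))
  keep <- logical(nrow(cand))
  for (t in seq_len(nrow(cand))) {
    a <- cand$i1[t]
    b <- cand$i2[t]
    if (!used1[a] && !used2[b]) {
      used1[a] <- TRUE
      used2[b] <- TRUE
      keep[t] <- TRUE
    }
  }
  list(pairs = cand[keep, list(i1, i2, tlen, score_num)],
       used1 = used1, used2 = used2)
}

#' Unit-cost alignment traceback for a validated hit
#'
#' Recomputes the alignment path over the located reference segment and
#' renders a CIGAR. `semi-global` keeps the read end to end (edit count
#' equals k); `local` additionally soft-clips read ends whose retention
#' would lower a simple +1/-2 match/edit score, excluding clipped bases
#' from NM.
#'
#' @param read_codes oriented read codes (already reverse-complemented for
#'   minus-strand hits).
#' @param chrom_codes the chromosome's code vector.
#' @param ref_start,ref_end 0-based half-open alignment span.
#' @param style `"semi-global"` or `"local"`.
#' @return list with `cigar`, `nm` (edit count, clips excluded),
#'   `ref_start` (possibly advanced by local clipping), `ref_end`.
#' @export
traceback_alignment <- function(read_codes, chrom_codes, ref_start, ref_end,
                                style = c("semi-global", "local")) {
  style <- match.arg(style)
  seg <- if (ref_end > ref_start) {
    chrom_codes[(ref_start + 1L):ref_end]
  } else integer(0)
  tb <- edit_traceback_cpp(as.integer(read_codes), seg)
  ops <- tb$ops # 0 match, 1 mismatch, 2 insertion, 3 deletion
  clip_left <- 0L
  clip_right <- 0L
  if (style == "local" && length(ops)) {
    sc <- ifelse(ops == 0L, 1, -2)
    best <- 0
    best_i <- 1L
    best_j <- 0L # empty window allowed -> full clip guard below
    run <- 0
    run_start <- 1L
    for (t in seq_along(ops)) {
      if (run <= 0) {
        run <- 0
        run_start <- t
      }
      run <- run + sc[t]
      if (run > best) {
        best <- run
        best_i <- run_start
        best_j <- t
      }
    }
    if (best > 0 && (best_i > 1L || best_j < length(ops))) {
      pre <- if (best_i > 1L) ops[seq_len(best_i - 1L)] else integer(0)
      post <- if (best_j < length(ops)) ops[(best_j + 1L):length(ops)] else integer(0)
      clip_left <- sum(pre %in% c(0L, 1L, 2L))
      clip_right <- sum(post %in% c(0L, 1L, 2L))
      ref_start <- ref_start + sum(pre %in% c(0L, 1L, 3L))
      ref_end <- ref_end - sum(post %in% c(0L, 1L, 3L))
      ops <- ops[best_i:best_j]
    }
  }
  sym <- c("M", "M", "I", "D")[ops + 1L]
  r <- rle(sym)
  cig <- paste0(r$lengths, r$values, collapse = "")
  if (clip_left > 0L) cig <- paste0(clip_left, "S", cig)
  if (clip_right > 0L) cig <- paste0(cig, clip_right, "S")
  if (!nzchar(cig)) cig <- "*"
  list(cigar = cig, nm = sum(ops != 0L),
       ref_start = ref_start, ref_end = ref_end)
}
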