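# Precomputed reference stream: per chromosome, the sorted (q-gram,
# position) pairs P with frequent q-grams masked out, plus the encoded
# sequence itself. Everything downstream of FASTA parsing works per
# chromosome.

.refindex_format <- "qgroupmap.refindex"
.qgi_format <- "qgroupmap.qgroupindex"
.container_version <- 1L

#' Build a reference index
#'
#' Encodes each reference sequence, extracts all indexable q-gram start
#' positions, masks q-grams that are exceedingly frequent on that
#' chromosome and sorts the surviving (code, position) pairs by numeric
#' code, ties by position. A q-gram is masked when its per-chromosome
#' occurrence count exceeds `max(mask_absolute_cap,
#' ceil(mask_frequency_cap * chromosome_length))`; set both caps to `Inf`
#' to disable masking.
#'
#' @param fasta path to a FASTA file, or a named character vector of
#'   sequences.
#' @param q q-gram length (default 16: a 2-bit encoded 16-mer fills a
#'   32-bit word).
#' @param mask_absolute_cap,mask_frequency_cap masking thresholds, see
#'   above.
#' @param seed seed for the random replacement of ambiguous bases.
#' @param n_run_threshold minimum N-run length excluded from indexing.
#' @return an object of class `ref_index`.
#' @export
build_reference_index <- function(fasta, q = 16L, mask_absolute_cap = 1000,
                                  mask_frequency_cap = 1e-4, seed = 0L,
                                  n_run_threshold = 10L) {
  seqs <- read_fasta(fasta)
  if (length(seqs) == 0L) stop("reference FASTA contains no sequences")
  q <- as.integer(q)
  chromosomes <- vector("list", length(seqs))
  names(chromosomes) <- names(seqs)
  for (ci in seq_along(seqs)) {
    nm <- names(seqs)[ci]
    enc <- encode_sequence(seqs[[ci]],
                           seed = (seed + ci) %% .Machine$integer.max,
                           n_run_threshold = n_run_threshold)
    chromosomes[[ci]] <- c(
      list(name = nm, seq = enc),
      build_P(enc, q, mask_absolute_cap, mask_frequency_cap)
    )
    if (enc$length < q) {
      warning(sprintf("chromosome '%s' is shorter than q=%d: empty P", nm, q))
    }
  }
  structure(
    list(q = q,
         params = list(mask_absolute_cap = mask_absolute_cap,
                       mask_frequency_cap = mask_frequency_cap,
                       n_run_threshold = n_run_threshold),
         seed = as.integer(seed),
         chromosomes = chromosomes),
    class = "ref_index"
  )
}

# The masked, sorted pair list of one encoded chromosome. Returns list
# (P_g double, P_pos integer 0-based, masked_qgrams double).
build_P <- function(enc, q, mask_absolute_cap, mask_frequency_cap) {
  g <- qgram_codes(enc, q)
  keep <- !is.na(g)
  g <- g[keep]
  pos <- which(keep) - 1L
  masked <- numeric(0)
  threshold <- max(mask_absolute_cap, ceiling(mask_frequency_cap * enc$length))
  if (is.finite(threshold) && length(g)) {
    dt <- data.table::data.table(g = g)[, .N, by = g]
    masked <- sort(dt[N > threshold, g])
    if (length(masked)) {
      drop <- g %in% masked
      g <- g[!drop]
      pos <- pos[!drop]
    }
  }
  o <- order(g, pos)
  list(P_g = g[o], P_pos = pos[o], masked_qgrams = masked)
}

#' @export
print.ref_index <- function(x, ...) {
  cat(sprintf("<ref_index> q=%d, %d chromosome(s)\n", x$q,
              length(x$chromosomes)))
  for (ch in x$chromosomes) {
    cat(sprintf("  %s: length %d, |P|=%d, %d masked q-gram(s)\n",
                ch$name, ch$seq$length, length(ch$P_pos),
                length(ch$masked_qgrams)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Versioned single-file container: one JSON header line followed by raw
# little-endian array sections in the order announced by the header. Each
# section records its length and a simple additive checksum.

.chk <- function(x) {
  if (length(x) == 0) return(0)
  sum(as.numeric(x)) %% 2147483647
}

.write_section <- function(con, x, type) {
  switch(type,
    int32 = writeBin(as.integer(x), con, size = 4L, endian = "little"),
    dbl = writeBin(as.numeric(x), con, size = 8L, endian = "little"),
    byte = writeBin(as.raw(x), con))
  invisible(NULL)
}

.read_section <- function(con, n, type, chk) {
  out <- switch(type,
    int32 = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    dbl = readBin(con, "numeric", n = n, size = 8L, endian = "little"),
    byte = as.integer(readBin(con, "raw", n = n)))
  if (length(out) != n) stop("container truncated or corrupt")
  if (!isTRUE(all.equal(.chk(out), chk))) {
    stop("container checksum mismatch (file corrupt?)")
  }
  out
}

.write_container <- function(path, format, header_extra, sections) {
  header <- c(list(format = format, version = .container_version),
              header_extra,
              list(sections = lapply(sections, function(s) {
                list(name = s$name, type = s$type, n = length(s$data),
                     checksum = .chk(s$data))
              })))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(jsonlite::toJSON(header, auto_unbox = TRUE,
                                             digits = NA), "\n")), con)
  for (s in sections) .write_section(con, s$data, s$type)
  invisible(path)
}

.read_container <- function(path, format) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header: bytes up to the first newline
  buf <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 4096L)
    if (length(b) == 0L) stop("container truncated or corrupt")
    nl <- which(b == as.raw(10L))
    if (length(nl)) {
      buf <- c(buf, b[seq_len(nl[1] - 1L)])
      # rewind to just after the newline
      seek(con, length(buf) + 1L, origin = "start")
      break
    }
    buf <- c(buf, b)
    if (length(buf) > 1e7) stop("container header missing newline")
  }
  header <- jsonlite::fromJSON(rawToChar(buf), simplifyVector = FALSE)
  if (is.null(header$format) || header$format != format) {
    stop(sprintf("not a %s container", format))
  }
  if (header$version != .container_version) {
    stop(sprintf("unsupported container version %s (this build reads version %d)",
                 header$version, .container_version))
  }
  data <- lapply(header$sections, function(s) {
    .read_section(con, s$n, s$type, s$checksum)
  })
  names(data) <- vapply(header$sections, `[[`, "", "name")
  list(header = header, data = data)
}

#' Save a reference index to a container file
#'
#' The container is a single file: a JSON header line (format tag, version,
#' q, masking parameters, per-chromosome section table with lengths and
#' checksums) followed by raw little-endian arrays.
#' @param ref a `ref_index`.
#' @param path output path.
#' @export
save_reference_index <- function(ref, path) {
  sections <- list()
  meta <- list()
  for (ch in ref$chromosomes) {
    nm <- ch$name
    runs <- ch$seq$skipped_runs
    sections <- c(sections, list(
      list(name = paste0(nm, ":codes"), type = "byte", data = ch$seq$codes),
      list(name = paste0(nm, ":n_mask"), type = "int32", data = ch$seq$n_mask),
      list(name = paste0(nm, ":runs"), type = "int32", data = as.integer(t(runs))),
      list(name = paste0(nm, ":P_g"), type = "dbl", data = ch$P_g),
      list(name = paste0(nm, ":P_pos"), type = "int32", data = ch$P_pos),
      list(name = paste0(nm, ":masked"), type = "dbl", data = ch$masked_qgrams)))
    meta[[length(meta) + 1L]] <- list(name = nm, length = ch$seq$length)
  }
  .write_container(path, .refindex_format,
                   list(q = ref$q, seed = ref$seed, params = ref$params,
                        chromosomes = meta),
                   sections)
}

#' Load a reference index from a container file
#'
#' Inverse of [save_reference_index()]; fails loudly on format, version,
#' truncation or checksum problems.
#' @param path container path.
#' @return the `ref_index`.
#' @export
load_reference_index <- function(path) {
  cc <- .read_container(path, .refindex_format)
  h <- cc$header
  chromosomes <- list()
  for (m in h$chromosomes) {
    nm <- m$name
    runs_flat <- cc$data[[paste0(nm, ":runs")]]
    runs <- matrix(as.integer(runs_flat), ncol = 2, byrow = TRUE,
                   dimnames = list(NULL, c("start", "end")))
    enc <- structure(
      list(codes = as.integer(cc$data[[paste0(nm, ":codes")]]),
           length = m$length,
           n_mask = as.integer(cc$data[[paste0(nm, ":n_mask")]]),
           skipped_runs = runs),
      class = "encoded_seq")
    chromosomes[[nm]] <- list(
      name = nm, seq = enc,
      P_g = as.numeric(cc$data[[paste0(nm, ":P_g")]]),
      P_pos = as.integer(cc$data[[paste0(nm, ":P_pos")]]),
      masked_qgrams = as.numeric(cc$data[[paste0(nm, ":masked")]]))
  }
  structure(
    list(q = as.integer(h$q),
         params = lapply(h$params, function(p) {
           if (is.character(p) && p == "Inf") Inf else p
         }),
         seed = as.integer(h$seed),
         chromosomes = chromosomes),
    class = "ref_index"
  )
}

#' Save a q-group index to a container file
#'
#' Serialises the four arrays with the same container layout used for
#' reference indexes. Because the in-memory order of positions inside one
#' q-gram's interval of O is unspecified, each interval is sorted ascending
#' before writing so the on-disk artifact is canonical.
#' @param index a `qgroup_index`.
#' @param path output path.
#' @export
save_qgroup_index <- function(index, path) {
  O <- index$O
  sp <- index$S_prime
  if (length(sp) > 1L) {
    for (t in seq_len(length(sp) - 1L)) {
      if (sp[t + 1L] > sp[t] + 1L) {
        idx <- (sp[t] + 1L):sp[t + 1L]
        O[idx] <- sort(O[idx])
      }
    }
  }
  .write_container(path, .qgi_format,
                   list(q = index$q, w = index$w,
                        half_sampled = index$half_sampled,
                        indexed_length = index$indexed_length,
                        n_indexable = index$n_indexable),
                   list(list(name = "I", type = "int32", data = index$I),
                        list(name = "S", type = "int32", data = index$S),
                        list(name = "S_prime", type = "int32", data = index$S_prime),
                        list(name = "O", type = "int32", data = O)))
}

#' Load a q-group index from a container file
#' @param path container path.
#' @return the `qgroup_index`.
#' @export
load_qgroup_index <- function(path) {
  cc <- .read_container(path, .qgi_format)
  h <- cc$header
  structure(
    list(I = as.integer(cc$data$I), S = as.integer(cc$data$S),
         S_prime = as.integer(cc$data$S_prime), O = as.integer(cc$data$O),
         q = as.integer(h$q), w = as.integer(h$w),
         half_sampled = isTRUE(h$half_sampled),
         indexed_length = as.integer(h$indexed_length),
         n_indexable = as.integer(h$n_indexable)),
    class = "qgroup_index"
  )
}
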