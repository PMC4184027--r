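# Format plumbing: FASTA/FASTQ through Biostrings, SAM text written (and,
# for evaluation, re-read) by this package.

# Accepts a path or a named character vector; returns a named character
# vector of uppercase sequences.
read_fasta <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    return(stats::setNames(toupper(as.character(x)), names(x)))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    if (is.null(names(ss))) stop("FASTA records must be named")
    nm <- sub("\\s.*$", "", names(ss)) # SAM RNAME: first token only
    return(stats::setNames(toupper(as.character(ss)), nm))
  }
  if (is.character(x)) {
    if (length(x) == 0L) return(x)
    if (is.null(names(x)) || any(names(x) == "")) {
      stop("reference sequences must be named")
    }
    return(toupper(x))
  }
  stop("cannot interpret reference input")
}

# Returns list(names, seqs (character), quals (character)).
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(ss)$qualities)
  list(names = sub("\\s.*$", "", names(ss)),
       seqs = toupper(as.character(ss)),
       quals = quals)
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write reads to FASTQ (Sanger / Phred+33 qualities)
#' @param names,seqs,quals parallel character vectors.
#' @param path output path.
#' @export
write_fastq <- function(names, seqs, quals, path) {
  stopifnot(length(names) == length(seqs), length(seqs) == length(quals))
  lines <- character(4L * length(names))
  lines[seq(1L, by = 4L, length.out = length(names))] <- paste0("@", names)
  lines[seq(2L, by = 4L, length.out = length(names))] <- seqs
  lines[seq(3L, by = 4L, length.out = length(names))] <- "+"
  lines[seq(4L, by = 4L, length.out = length(names))] <- quals
  writeLines(lines, path)
  invisible(path)
}

# SAM header for a reference index.
sam_header <- function(ref, config_string) {
  c("@HD\tVN:1.6\tSO:unknown",
    vapply(ref$chromosomes, function(ch) {
      sprintf("@SQ\tSN:%s\tLN:%d", ch$name, ch$seq$length)
    }, character(1), USE.NAMES = FALSE),
    sprintf("@PG\tID:qgroupmap\tPN:qgroupmap\tVN:%s\tCL:%s",
            as.character(utils::packageVersion("qgroupmap")), config_string))
}

# Minimal parser for SAM text written by this package (or any mapper whose
# mandatory columns follow SAM 1.x). Returns a data.table of the mandatory
# fields with FLAG bits unpacked.
parse_sam <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.table::data.table(
      qname = character(0), flag = integer(0), rname = character(0),
      pos = integer(0), mapq = integer(0), cigar = character(0),
      unmapped = logical(0), reverse = logical(0), secondary = logical(0),
      first_mate = logical(0), second_mate = logical(0)))
  }
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:6)
  dt <- data.table::data.table(
    qname = f[[1]], flag = as.integer(f[[2]]), rname = f[[3]],
    pos = as.integer(f[[4]]), mapq = as.integer(f[[5]]), cigar = f[[6]])
  dt[, `:=`(unmapped = bitwAnd(flag, 4L) > 0L,
            reverse = bitwAnd(flag, 16L) > 0L,
            secondary = bitwAnd(flag, 256L) > 0L,
            first_mate = bitwAnd(flag, 64L) > 0L,
            second_mate = bitwAnd(flag, 128L) > 0L)]
  dt[]
}
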