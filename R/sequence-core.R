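#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   DNAString AAString reverseComplement translate getGeneticCode
#'   matchPattern letterFrequency subseq width
#' @importFrom S4Vectors mcols
NULL

# All genomic coordinates inside this package are 0-based, half-open
# [start, end).  Conversion to/from the 1-based inclusive GFF3 convention
# happens only in annotation-io.R.

#' Read a genome from a FASTA file
#'
#' Record ids are truncated at the first whitespace and used as replicon ids.
#' The alphabet is restricted to A, C, G, T, N (case-insensitive on read).
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per replicon.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  validate_genome(x)
  x
}

#' Write a genome to FASTA (60-column wrap)
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = 60L)
  invisible(path)
}

#' Coerce a character vector or DNAStringSet to a validated genome
#'
#' @param genome Named character vector of sequences or a `DNAStringSet`.
#' @return A validated `DNAStringSet`.
#' @export
as_genome <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == ""))
      stop("a character genome must have non-empty names (replicon ids)")
    if (length(genome) == 0L) stop("genome contains no replicons")
    sq <- toupper(genome)
    bad <- regexpr("[^ACGTN]", sq)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      stop(sprintf("invalid character '%s' at position %d of replicon '%s'",
                   substr(sq[i], bad[i], bad[i]), bad[i], names(genome)[i]))
    }
    genome <- Biostrings::DNAStringSet(sq)
  }
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or a named character vector")
  validate_genome(genome)
  genome
}

validate_genome <- function(genome) {
  if (length(genome) == 0L) stop("genome contains no replicons")
  if (any(Biostrings::width(genome) == 0L)) stop("empty sequence in genome")
  sq <- as.character(genome)
  bad <- regexpr("[^ACGTN]", sq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d of replicon '%s'",
                 substr(sq[i], bad[i], bad[i]), bad[i], names(genome)[i]))
  }
  invisible(genome)
}

#' Per-replicon metadata: length and GC content
#'
#' GC percent excludes N from both numerator and denominator.
#'
#' @param genome A `DNAStringSet` (or named character vector).
#' @return data.frame with columns `replicon_id`, `length`, `gc_percent`.
#' @export
replicon_info <- function(genome) {
  genome <- as_genome(genome)
  fr <- Biostrings::letterFrequency(genome, c("G", "C", "A", "T"))
  gc <- rowSums(fr[, c("G", "C"), drop = FALSE])
  at <- rowSums(fr[, c("A", "T"), drop = FALSE])
  data.frame(
    replicon_id = names(genome),
    length = Biostrings::width(genome),
    gc_percent = ifelse(gc + at > 0, 100 * gc / (gc + at), NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Reading-frame label of a genomic interval
#'
#' Frames are intrinsic to the strand-oriented reading: on '+' the frame is
#' `start %% 3`; on '-' it is `(L - end) %% 3`, where `L` is the replicon
#' length and `[start, end)` is 0-based half-open.  Two same-strand features
#' are in the same reading frame iff their frame labels are equal.
#'
#' @param start,end 0-based half-open interval.
#' @param strand "+" or "-".
#' @param seq_length Replicon length in nt.
#' @return Integer frame label in 0:2.
#' @export
frame_of <- function(start, end, strand, seq_length) {
  ifelse(strand == "+", start %% 3L, (seq_length - end) %% 3L)
}

#' Six-frame translation of a replicon
#'
#' Translates a nucleotide sequence in all six reading frames (3 offsets on
#' each strand) under a given genetic code.  Reverse-strand frames are
#' translated on the reverse complement.  Codons containing N translate to
#' 'X'; stop codons appear as '*'.  Plain codon lookup is used throughout
#' (no initiator-codon special-casing).
#'
#' @param seq A single sequence: `DNAString`, length-1 `DNAStringSet`, or
#'   character scalar.
#' @param table Genetic code id; defaults to "11" (bacterial/archaeal).
#' @return data.frame with one row per frame: `strand`, `frame` (0:2, equal
#'   to the frame label of every codon in that translation), `aa_seq`, plus
#'   attribute `seq_length`.
#' @export
translate_frames <- function(seq, table = "11") {
  dna <- single_dna(seq)
  L <- length(dna)
  code <- Biostrings::getGeneticCode(table)
  rc <- Biostrings::reverseComplement(dna)
  one <- function(x, off) {
    n <- (length(x) - off) %/% 3L
    if (n <= 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, off + 1L, off + 3L * n),
      genetic.code = code, if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  out <- data.frame(
    strand = rep(c("+", "-"), each = 3L),
    frame = rep(0:2, 2L),
    aa_seq = c(vapply(0:2, function(o) one(dna, o), ""),
               vapply(0:2, function(o) one(rc, o), "")),
    stringsAsFactors = FALSE
  )
  attr(out, "seq_length") <- L
  out
}

single_dna <- function(seq) {
  if (is.character(seq)) {
    stopifnot(length(seq) == 1L)
    if (nchar(seq) == 0L) stop("empty sequence")
    bad <- regexpr("[^ACGTN]", toupper(seq))
    if (bad > 0L)
      stop(sprintf("invalid character '%s' at position %d",
                   substr(toupper(seq), bad, bad), bad))
    return(Biostrings::DNAString(toupper(seq)))
  }
  if (methods::is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    return(seq[[1L]])
  }
  if (methods::is(seq, "DNAString")) {
    if (length(seq) == 0L) stop("empty sequence")
    return(seq)
  }
  stop("seq must be a DNAString, length-1 DNAStringSet, or character scalar")
}

# Genomic interval of the codon run [i1, i2] (1-based aa indices) in a frame.
aa_to_genomic <- function(i1, i2, strand, frame, seq_length) {
  if (strand == "+") {
    c(frame + 3L * (i1 - 1L), frame + 3L * i2)
  } else {
    c(seq_length - (frame + 3L * i2), seq_length - (frame + 3L * (i1 - 1L)))
  }
}

# aa index (1-based) of the codon whose 5'-most genomic position (on the
# coding strand) is at genomic coordinate g.
genomic_to_aa <- function(gstart, gend, strand, frame, seq_length) {
  if (strand == "+") (gstart - frame) %/% 3L + 1L
  else (seq_length - gend - frame) %/% 3L + 1L
}

#' Enumerate maximal open reading frames
#'
#' Finds all maximal stop-to-stop runs of sense codons in all six frames.
#' An ORF is the stop-free codon stretch itself: it excludes the bounding
#' stop codons (or is bounded by the sequence edge).  `has_start_codon` is
#' TRUE when the stretch contains an in-frame ATG, GTG or TTG (the
#' prokaryotic alternative starts).
#'
#' @param seq Sequence as in [translate_frames()], or a `DNAStringSet` of
#'   several replicons.
#' @param min_len_nt Minimum ORF length in nt (default 39, the shortest
#'   experimentally detected CDS).
#' @param table Genetic code id.
#' @return data.frame: `replicon_id`, `strand`, `frame`, `start`, `end`
#'   (0-based half-open), `length_nt`, `has_start_codon`, sorted by
#'   (replicon_id, start, end, strand).
#' @export
find_orfs <- function(seq, min_len_nt = 39L, table = "11") {
  if (min_len_nt < 3L) stop("min_len_nt must be >= 3")
  if (methods::is(seq, "DNAStringSet") && length(seq) > 1L) {
    out <- lapply(names(seq), function(id) {
      o <- find_orfs(seq[id], min_len_nt, table)
      o$replicon_id <- id
      o
    })
    out <- do.call(rbind, out)
    return(out[order(out$replicon_id, out$start, out$end, out$strand), ,
               drop = FALSE])
  }
  id <- if (methods::is(seq, "DNAStringSet")) names(seq)[1L] else NA_character_
  fr <- translate_frames(seq, table)
  L <- attr(fr, "seq_length")
  dna <- single_dna(seq)
  rcs <- as.character(Biostrings::reverseComplement(dna))
  fwd <- as.character(dna)
  rows <- list()
  for (r in seq_len(nrow(fr))) {
    aa <- fr$aa_seq[r]
    n <- nchar(aa)
    if (n == 0L) next
    stops <- aa_stop_positions(aa)
    runs <- stop_free_runs(stops, n)
    if (nrow(runs) == 0L) next
    keep <- (runs$i2 - runs$i1 + 1L) * 3L >= min_len_nt
    runs <- runs[keep, , drop = FALSE]
    if (nrow(runs) == 0L) next
    src <- if (fr$strand[r] == "+") fwd else rcs
    for (k in seq_len(nrow(runs))) {
      g <- aa_to_genomic(runs$i1[k], runs$i2[k], fr$strand[r], fr$frame[r], L)
      # start codons checked on the strand-local sequence
      loc1 <- fr$frame[r] + 3L * (runs$i1[k] - 1L) + 1L
      codons <- substring(src, seq(loc1, by = 3L,
                                   length.out = runs$i2[k] - runs$i1[k] + 1L),
                          seq(loc1 + 2L, by = 3L,
                              length.out = runs$i2[k] - runs$i1[k] + 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        replicon_id = id, strand = fr$strand[r], frame = fr$frame[r],
        start = g[1L], end = g[2L], length_nt = g[2L] - g[1L],
        has_start_codon = any(codons %in% c("ATG", "GTG", "TTG")),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L)
    return(data.frame(replicon_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      length_nt = integer(), has_start_codon = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$replicon_id, out$start, out$end, out$strand), , drop = FALSE]
}

aa_stop_positions <- function(aa) {
  p <- gregexpr("*", aa, fixed = TRUE)[[1L]]
  if (p[1L] == -1L) integer() else as.integer(p)
}

# Maximal stop-free aa index runs given stop positions in a string of length n.
stop_free_runs <- function(stops, n) {
  bounds <- c(0L, stops, n + 1L)
  i1 <- bounds[-length(bounds)] + 1L
  i2 <- bounds[-1L] - 1L
  keep <- i2 >= i1
  data.frame(i1 = i1[keep], i2 = i2[keep])
}
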