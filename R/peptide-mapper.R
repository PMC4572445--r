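# Peptide-to-genome mapping by exact, unique six-frame match.

#' Build a six-frame translation index for a genome
#'
#' Precomputes the six translated frames of every replicon once, so that
#' repeated peptide searches and reading-frame lookups are cheap.
#'
#' @param genome A `DNAStringSet` or named character vector.
#' @param table Genetic code id (default "11").
#' @return An object of class `six_frame_index`.
#' @export
six_frame_index <- function(genome, table = "11") {
  genome <- as_genome(genome)
  frames <- lapply(names(genome), function(id) {
    fr <- translate_frames(genome[id], table)
    fr$replicon_id <- id
    fr$seq_length <- attr(fr, "seq_length")
    fr
  })
  frames <- do.call(rbind, frames)
  structure(list(genome = genome, info = replicon_info(genome),
                 frames = frames, table = table),
            class = "six_frame_index")
}

#' @export
print.six_frame_index <- function(x, ...) {
  cat(sprintf("six_frame_index: %d replicon(s), %d nt total, code %s\n",
              length(x$genome), sum(x$info$length), x$table))
  invisible(x)
}

as_sfindex <- function(x, table = "11") {
  if (inherits(x, "six_frame_index")) x else six_frame_index(x, table)
}

replicon_lengths <- function(x) {
  info <- if (inherits(x, "six_frame_index")) x$info else replicon_info(x)
  stats::setNames(info$length, info$replicon_id)
}

#' Map peptides onto a genome by exact unique six-frame match
#'
#' Each peptide sequence is searched for exact occurrences in all six
#' translation frames of every replicon.  A peptide occurring exactly once
#' genome-wide is mapped to that locus; a peptide with two or more
#' occurrences is discarded as ambiguous; one with none is discarded as
#' unmatched.  Uniqueness is assessed over the whole input genome (all
#' replicons, both strands).  I and L are distinct residues during matching.
#' Peptides carrying trusted precomputed coordinates are validated by
#' re-translation and accepted without search; failed validation counts as
#' unmatched.
#'
#' @param peptides data.frame as returned by [read_peptides()]: columns
#'   `peptide_id`, `aa_seq`, and optionally `replicon_id`, `start`, `end`,
#'   `strand` for precomputed coordinates.
#' @param genome A `DNAStringSet`, named character vector, or a prebuilt
#'   [six_frame_index()].
#' @param use_precomputed Validate and accept precomputed coordinates
#'   instead of searching (default TRUE).
#' @return A list with elements
#'   \describe{
#'     \item{mapped}{data.frame `peptide_id`, `aa_seq`, `replicon_id`,
#'       `strand`, `start`, `end` (0-based half-open, `end - start ==
#'       3 * nchar(aa_seq)`), `frame`.}
#'     \item{discarded}{data.frame `peptide_id`, `aa_seq`, `status` in
#'       `ambiguous` / `unmatched`.}
#'     \item{report}{list `n_input`, `n_mapped`, `n_ambiguous_discarded`,
#'       `n_unmatched`, `n_short_flagged` (peptides < 6 aa, processed but
#'       flagged as high ambiguity risk).  The first four satisfy
#'       `n_input = n_mapped + n_ambiguous_discarded + n_unmatched`.}
#'   }
#' @export
map_peptides <- function(peptides, genome, use_precomputed = TRUE) {
  idx <- as_sfindex(genome)
  peptides <- as_peptide_input(peptides)
  n <- nrow(peptides)
  has_pre <- use_precomputed && all(c("replicon_id", "start", "end", "strand")
                                    %in% names(peptides)) &&
    !all(is.na(peptides$start))

  status <- character(n)
  res <- vector("list", n)

  pre_ok <- rep(FALSE, n)
  if (has_pre) {
    cand <- which(!is.na(peptides$start) & !is.na(peptides$replicon_id))
    for (i in cand) {
      ok <- validate_mapping(idx, peptides$replicon_id[i], peptides$strand[i],
                             peptides$start[i], peptides$end[i],
                             peptides$aa_seq[i])
      if (ok) {
        L <- replicon_lengths(idx)[[peptides$replicon_id[i]]]
        res[[i]] <- data.frame(
          peptide_id = peptides$peptide_id[i], aa_seq = peptides$aa_seq[i],
          replicon_id = peptides$replicon_id[i], strand = peptides$strand[i],
          start = as.integer(peptides$start[i]),
          end = as.integer(peptides$end[i]),
          frame = as.integer(frame_of(peptides$start[i], peptides$end[i],
                                      peptides$strand[i], L)),
          stringsAsFactors = FALSE
        )
        status[i] <- "mapped"
        pre_ok[i] <- TRUE
      }
      # failed validation falls through to search below
    }
  }

  todo <- which(!pre_ok)
  if (length(todo)) {
    uniq <- unique(peptides$aa_seq[todo])
    hits <- lapply(uniq, function(p) six_frame_hits(idx, p))
    names(hits) <- uniq
    for (i in todo) {
      h <- hits[[peptides$aa_seq[i]]]
      if (nrow(h) == 1L) {
        res[[i]] <- data.frame(
          peptide_id = peptides$peptide_id[i], aa_seq = peptides$aa_seq[i],
          replicon_id = h$replicon_id, strand = h$strand,
          start = h$start, end = h$end, frame = h$frame,
          stringsAsFactors = FALSE
        )
        status[i] <- "mapped"
      } else if (nrow(h) > 1L) {
        status[i] <- "ambiguous"
      } else {
        status[i] <- "unmatched"
      }
    }
  }

  mapped <- do.call(rbind, res[status == "mapped"])
  if (is.null(mapped)) mapped <- empty_mapped()
  rownames(mapped) <- NULL
  disc <- data.frame(peptide_id = peptides$peptide_id[status != "mapped"],
                     aa_seq = peptides$aa_seq[status != "mapped"],
                     status = status[status != "mapped"],
                     stringsAsFactors = FALSE)
  report <- list(
    n_input = n,
    n_mapped = sum(status == "mapped"),
    n_ambiguous_discarded = sum(status == "ambiguous"),
    n_unmatched = sum(status == "unmatched"),
    n_short_flagged = sum(nchar(peptides$aa_seq) < 6L)
  )
  list(mapped = mapped, discarded = disc, report = report)
}

empty_mapped <- function() {
  data.frame(peptide_id = character(), aa_seq = character(),
             replicon_id = character(), strand = character(),
             start = integer(), end = integer(), frame = integer(),
             stringsAsFactors = FALSE)
}

# All exact occurrences of peptide p across the six frames of all replicons.
six_frame_hits <- function(idx, p) {
  fr <- idx$frames
  out <- list()
  pat <- Biostrings::AAString(p)
  k <- nchar(p)
  for (r in seq_len(nrow(fr))) {
    if (nchar(fr$aa_seq[r]) < k) next
    m <- Biostrings::matchPattern(pat, Biostrings::AAString(fr$aa_seq[r]))
    if (length(m) == 0L) next
    st <- Biostrings::start(m)
    for (s in st) {
      g <- aa_to_genomic(s, s + k - 1L, fr$strand[r], fr$frame[r],
                         fr$seq_length[r])
      out[[length(out) + 1L]] <- data.frame(
        replicon_id = fr$replicon_id[r], strand = fr$strand[r],
        start = g[1L], end = g[2L], frame = fr$frame[r],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L)
    return(data.frame(replicon_id = character(), strand = character(),
                      start = integer(), end = integer(), frame = integer()))
  do.call(rbind, out)
}

# TRUE iff translating [start, end) on the given strand reproduces aa_seq.
validate_mapping <- function(idx, replicon_id, strand, start, end, aa_seq) {
  if (is.na(replicon_id) || !(replicon_id %in% names(idx$genome))) return(FALSE)
  L <- replicon_lengths(idx)[[replicon_id]]
  if (is.na(start) || is.na(end) || start < 0L || end > L ||
      (end - start) != 3L * nchar(aa_seq) || !(strand %in% c("+", "-")))
    return(FALSE)
  identical(translate_interval(idx$genome, replicon_id, strand, start, end,
                               idx$table), aa_seq)
}

#' Translate a genomic interval on a given strand
#'
#' @param genome `DNAStringSet`.
#' @param replicon_id Replicon name.
#' @param strand "+" or "-".
#' @param start,end 0-based half-open interval; `end - start` a multiple of 3.
#' @param table Genetic code id.
#' @return Amino-acid string ('*' for stops, 'X' across N).
#' @export
translate_interval <- function(genome, replicon_id, strand, start, end,
                               table = "11") {
  stopifnot((end - start) %% 3L == 0L, end > start)
  s <- Biostrings::subseq(genome[[replicon_id]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(Biostrings::translate(
    s, genetic.code = Biostrings::getGeneticCode(table),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}
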