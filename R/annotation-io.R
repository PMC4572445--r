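# GFF3 / TSV input and output for gene calls, peptides and conflict tracks.
#
# GFF3 files are 1-based inclusive; everything in memory is 0-based
# half-open.  Conversion happens here and nowhere else.

AA20 <- "ACDEFGHIKLMNPQRSTVWY"

#' Construct a gene-call set
#'
#' A gene-call set holds one caller's predicted CDSs.  Each call has a
#' full-span interval and one or more fragments; multi-fragment calls
#' represent genes disrupted by frameshifts or internal stops whose pieces
#' were retained by the caller (tagged as pseudogenes or not).
#'
#' @param calls data.frame with columns `gene_id`, `replicon_id`, `strand`
#'   ("+"/"-"), `start`, `end` (0-based half-open, full span),
#'   `is_pseudogene` (logical), and optionally a list-column `fragments`
#'   (each a data.frame with `start`, `end`).  Missing `fragments` default
#'   to the full span.
#' @param caller_id Identifier of the gene caller that produced the calls.
#' @return An object of class `gene_call_set`.
#' @export
gene_call_set <- function(calls, caller_id) {
  stopifnot(is.character(caller_id), length(caller_id) == 1L, nzchar(caller_id))
  need <- c("gene_id", "replicon_id", "strand", "start", "end")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "))
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(calls)) {
    if (!all(calls$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(calls$end <= calls$start)) stop("calls must have end > start")
    key <- paste(calls$replicon_id, calls$strand, calls$start, calls$end)
    if (anyDuplicated(key))
      stop("duplicate call (same replicon, strand, start, end)")
    if (anyDuplicated(calls$gene_id)) stop("duplicate gene_id")
  }
  if (is.null(calls$is_pseudogene)) calls$is_pseudogene <- rep(FALSE, nrow(calls))
  if (is.null(calls$fragments))
    calls$fragments <- lapply(seq_len(nrow(calls)), function(i)
      data.frame(start = calls$start[i], end = calls$end[i]))
  for (i in seq_len(nrow(calls))) {
    f <- calls$fragments[[i]]
    f <- f[order(f$start), , drop = FALSE]
    if (any(f$start < calls$start[i]) || any(f$end > calls$end[i]))
      stop("fragment outside call span for ", calls$gene_id[i])
    if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)]))
      stop("overlapping fragments for ", calls$gene_id[i])
    if (sum(f$end - f$start) < 3L)
      stop("total fragment length < 3 for ", calls$gene_id[i])
    calls$fragments[[i]] <- f
  }
  calls$start <- as.integer(calls$start)
  calls$end <- as.integer(calls$end)
  rownames(calls) <- NULL
  structure(list(caller_id = caller_id, calls = calls),
            class = "gene_call_set")
}

#' @export
print.gene_call_set <- function(x, ...) {
  cat(sprintf("gene_call_set '%s': %d call(s) on %d replicon(s), %d pseudogene-tagged\n",
              x$caller_id, nrow(x$calls),
              length(unique(x$calls$replicon_id)), sum(x$calls$is_pseudogene)))
  invisible(x)
}

#' Number of calls in a gene-call set
#' @param x A `gene_call_set`.
#' @return Integer count.
#' @export
n_calls <- function(x) nrow(x$calls)

# One row per fragment, with the fragment's own reading frame.
fragment_table <- function(x, lengths) {
  calls <- x$calls
  if (nrow(calls) == 0L)
    return(data.frame(gene_id = character(), replicon_id = character(),
                      strand = character(), fstart = integer(),
                      fend = integer(), frame = integer(),
                      call_start = integer(), call_end = integer(),
                      is_pseudogene = logical(), n_fragments = integer()))
  out <- lapply(seq_len(nrow(calls)), function(i) {
    f <- calls$fragments[[i]]
    L <- lengths[[calls$replicon_id[i]]]
    data.frame(gene_id = calls$gene_id[i], replicon_id = calls$replicon_id[i],
               strand = calls$strand[i], fstart = as.integer(f$start),
               fend = as.integer(f$end),
               frame = as.integer(frame_of(f$start, f$end, calls$strand[i], L)),
               call_start = calls$start[i], call_end = calls$end[i],
               is_pseudogene = calls$is_pseudogene[i],
               n_fragments = nrow(f), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read gene calls from a GFF3 file
#'
#' CDS features sharing a `Parent` (or, failing that, an `ID` or
#' `locus_tag`) become fragments of one call.  A call is flagged as a
#' pseudogene when its parent feature type is `pseudogene` or when any of
#' its rows carries the attribute `pseudo=true`.  Coordinates are converted
#' from GFF3 1-based inclusive to 0-based half-open.
#'
#' @param path GFF3 file path.
#' @param caller_id Caller identifier to attach to the set.
#' @return A [gene_call_set()].
#' @export
read_gene_calls <- function(path, caller_id) {
  check_gff_coords(path)
  g <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(g)
  type <- as.character(m$type)
  is_cds <- type %in% c("CDS", "exon")
  ids <- if ("ID" %in% names(m)) as.character(m$ID) else rep(NA_character_, length(g))
  parents <- rep(NA_character_, length(g))
  if ("Parent" %in% names(m)) {
    pl <- m$Parent
    parents <- vapply(seq_along(g), function(i) {
      p <- pl[[i]]
      if (length(p)) as.character(p)[1L] else NA_character_
    }, "")
  }
  locus <- if ("locus_tag" %in% names(m)) as.character(m$locus_tag)
           else rep(NA_character_, length(g))
  pseudo_attr <- if ("pseudo" %in% names(m)) tolower(as.character(m$pseudo)) %in% "true"
                 else rep(FALSE, length(g))

  cds <- which(is_cds)
  if (any(as.character(GenomicRanges::strand(g))[cds] == "*"))
    stop("CDS feature with unknown strand '.' in ", path)
  group <- ifelse(!is.na(parents[cds]), parents[cds],
                  ifelse(!is.na(ids[cds]), ids[cds],
                         ifelse(!is.na(locus[cds]), locus[cds],
                                paste0("cds", seq_along(cds)))))
  # parent features, keyed by ID
  par_rows <- which(!is_cds & type %in% c("gene", "pseudogene"))
  par_type <- stats::setNames(type[par_rows], ids[par_rows])
  par_pseudo <- stats::setNames(pseudo_attr[par_rows], ids[par_rows])

  seqn <- as.character(GenomicRanges::seqnames(g))
  strn <- as.character(GenomicRanges::strand(g))
  st0 <- GenomicRanges::start(g) - 1L
  en0 <- GenomicRanges::end(g)

  ug <- unique(group)
  rows <- lapply(ug, function(gr) {
    i <- cds[group == gr]
    if (length(unique(seqn[i])) != 1L || length(unique(strn[i])) != 1L)
      stop("CDS fragments of '", gr, "' disagree on replicon or strand")
    f <- data.frame(start = st0[i], end = en0[i])
    f <- f[order(f$start), , drop = FALSE]
    pseudo <- any(pseudo_attr[i]) ||
      (!is.na(gr) && gr %in% names(par_type) &&
         (par_type[[gr]] == "pseudogene" || isTRUE(par_pseudo[[gr]])))
    data.frame(gene_id = gr, replicon_id = seqn[i][1L], strand = strn[i][1L],
               start = min(f$start), end = max(f$end), is_pseudogene = pseudo,
               stringsAsFactors = FALSE, fragments = I(list(f)))
  })
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    calls <- data.frame(gene_id = character(), replicon_id = character(),
                        strand = character(), start = integer(),
                        end = integer(), is_pseudogene = logical(),
                        stringsAsFactors = FALSE)
  gene_call_set(calls, caller_id)
}

# GFF3 guarantees start <= end; report the offending line number otherwise.
check_gff_coords <- function(path) {
  ln <- readLines(path, warn = FALSE)
  body <- which(!startsWith(ln, "#") & nzchar(ln))
  for (i in body) {
    f <- strsplit(ln[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 5L) {
      s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
      if (!is.na(s) && !is.na(e) && e < s)
        stop(sprintf("end < start at line %d of %s", i, path))
    }
  }
  invisible(TRUE)
}

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write a gene-call set as GFF3
#'
#' Each call is written as a parent feature of type `gene` (or `pseudogene`)
#' plus one `CDS` row per fragment carrying `Parent`.  Round-trips through
#' [read_gene_calls()].
#'
#' @param x A `gene_call_set`.
#' @param path Output path.
#' @export
write_gene_calls <- function(x, path) {
  calls <- x$calls
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(calls))) {
    type <- if (calls$is_pseudogene[i]) "pseudogene" else "gene"
    gid <- gff_escape(calls$gene_id[i])
    lines <- c(lines, paste(
      calls$replicon_id[i], x$caller_id, type,
      calls$start[i] + 1L, calls$end[i], ".", calls$strand[i], ".",
      paste0("ID=", gid), sep = "\t"))
    f <- calls$fragments[[i]]
    for (k in seq_len(nrow(f))) {
      lines <- c(lines, paste(
        calls$replicon_id[i], x$caller_id, "CDS",
        f$start[k] + 1L, f$end[k], ".", calls$strand[i], "0",
        paste0("ID=", gid, ".cds", k, ";Parent=", gid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

as_peptide_input <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("peptide_id", "aa_seq") %in% names(x)))
    stop("peptides need columns peptide_id and aa_seq")
  bad <- grepl(sprintf("[^%s]", AA20), x$aa_seq) | !nzchar(x$aa_seq)
  if (any(bad))
    stop("non-amino-acid characters in peptide row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  x
}

#' Read peptide inputs from TSV or GFF
#'
#' TSV files must have columns `peptide_id` and `aa_seq` (extra columns
#' `replicon_id`, `start`, `end`, `strand` are carried along as precomputed
#' 0-based half-open coordinates).  GFF files must carry the peptide
#' sequence in an `aa_seq` attribute; their coordinates are taken as
#' precomputed mappings.  File order is preserved and duplicate sequences
#' are retained as distinct observations.
#'
#' @param path Input file.
#' @param format "auto" (by extension), "tsv" or "gff".
#' @return data.frame with columns `peptide_id`, `aa_seq` and, when
#'   available, `replicon_id`, `start`, `end`, `strand`.
#' @export
read_peptides <- function(path, format = c("auto", "tsv", "gff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff" else "tsv"
  if (format == "gff") {
    g <- rtracklayer::import(path, format = "gff3")
    if (length(g) == 0L) {
      warning("no peptide features in ", path)
      return(data.frame(peptide_id = character(), aa_seq = character(),
                        stringsAsFactors = FALSE))
    }
    m <- S4Vectors::mcols(g)
    if (!("aa_seq" %in% names(m)))
      stop("GFF peptide file lacks an aa_seq attribute: ", path)
    ids <- if ("ID" %in% names(m)) as.character(m$ID)
           else sprintf("pep%05d", seq_along(g))
    out <- data.frame(
      peptide_id = ids, aa_seq = as.character(m$aa_seq),
      replicon_id = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1L, end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      stringsAsFactors = FALSE
    )
    return(as_peptide_input(out))
  }
  first <- tryCatch(readLines(path, n = 1L, warn = FALSE), error = function(e) character())
  if (length(first) == 0L) {
    warning("empty peptide file: ", path)
    return(data.frame(peptide_id = character(), aa_seq = character(),
                      stringsAsFactors = FALSE))
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_peptide_input(x)
}

#' Write peptide inputs as TSV
#' @param peptides data.frame as in [read_peptides()].
#' @param path Output path.
#' @export
write_peptides <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write mapped peptides as a GFF3 track
#' @param mapped data.frame from [map_peptides()]'s `mapped` element.
#' @param path Output path.
#' @param source Source column value.
#' @export
write_peptide_gff <- function(mapped, path, source = "progeval") {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(mapped))) {
    lines <- c(lines, paste(
      mapped$replicon_id[i], source, "polypeptide",
      mapped$start[i] + 1L, mapped$end[i], ".", mapped$strand[i], ".",
      paste0("ID=", gff_escape(mapped$peptide_id[i]),
             ";aa_seq=", mapped$aa_seq[i]), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write conflicting peptides as a GFF3 track
#'
#' One `polypeptide` feature per conflicting peptide, with attributes
#' `relation` (the conflict class) and `caller_id`.
#'
#' @param conflicts data.frame from [find_conflicts()].
#' @param path Output path.
#' @param source Source column value.
#' @export
write_conflict_gff <- function(conflicts, path, source = "progeval") {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(conflicts))) {
    attrs <- paste0("ID=", gff_escape(conflicts$peptide_id[i]),
                    ";aa_seq=", conflicts$aa_seq[i],
                    ";relation=", conflicts$relation[i],
                    ";caller_id=", gff_escape(conflicts$caller_id[i]))
    if (!is.na(conflicts$nearest_gene_id[i]))
      attrs <- paste0(attrs, ";nearest_call=",
                      gff_escape(conflicts$nearest_gene_id[i]))
    lines <- c(lines, paste(
      conflicts$replicon_id[i], source, "polypeptide",
      conflicts$start[i] + 1L, conflicts$end[i], ".", conflicts$strand[i],
      ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a conflict GFF3 track written by [write_conflict_gff()]
#'
#' @param path Input path.
#' @return data.frame with `peptide_id`, `aa_seq`, `replicon_id`, `start`,
#'   `end`, `strand`, `relation`, `caller_id`, `nearest_gene_id`.
#' @export
read_conflict_gff <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(g)
  if (length(g) == 0L)
    return(data.frame(peptide_id = character(), aa_seq = character(),
                      replicon_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      relation = character(), caller_id = character(),
                      nearest_gene_id = character(), stringsAsFactors = FALSE))
  data.frame(
    peptide_id = as.character(m$ID), aa_seq = as.character(m$aa_seq),
    replicon_id = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L, end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    relation = as.character(m$relation), caller_id = as.character(m$caller_id),
    nearest_gene_id = if ("nearest_call" %in% names(m))
      as.character(m$nearest_call) else NA_character_,
    stringsAsFactors = FALSE
  )
}
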