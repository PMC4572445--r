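# Seeded generator for synthetic replicons, truth gene sets, perturbed
# caller outputs and tryptic peptide evidence.
#
# Intergenic regions carry a 12 nt AT-only cassette (TTAATTAATTAA) that
# contains a stop codon in every reading frame on both strands, so maximal
# ORFs never bridge two genes and planted missed genes stay separable.

STOP_CASSETTE <- "TTAATTAATTAA"
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation parameters for a synthetic replicon
#'
#' @param genome_length Replicon length in nt.
#' @param gc_percent Target GC content (25-75).
#' @param n_genes Number of genes to place.
#' @param gene_length_mean,gene_length_sd Gene length distribution in nt
#'   (rounded to multiples of 3, floored at 150 nt so genes carry several
#'   tryptic peptides).
#' @param intergenic_mean,intergenic_sd Intergenic gap distribution in nt
#'   (floored at 30 nt to fit the frame-closing cassette).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(genome_length = 100000L, gc_percent = 57.7,
                       n_genes = 80L, gene_length_mean = 900,
                       gene_length_sd = 200, intergenic_mean = 150,
                       intergenic_sd = 50, seed = 1L) {
  if (gc_percent < 25 || gc_percent > 75)
    stop("gc_percent must be in [25, 75]")
  if (n_genes > 0 && n_genes * gene_length_mean >= genome_length)
    stop("infeasible packing: n_genes * gene_length_mean >= genome_length; ",
         "reduce n_genes")
  structure(list(genome_length = as.integer(genome_length),
                 gc_percent = gc_percent, n_genes = as.integer(n_genes),
                 gene_length_mean = gene_length_mean,
                 gene_length_sd = gene_length_sd,
                 intergenic_mean = intergenic_mean,
                 intergenic_sd = intergenic_sd, seed = as.integer(seed)),
            class = "sim_params")
}

#' Caller error profile for synthetic perturbation
#'
#' Per gene, a single categorical draw selects at most one perturbation:
#' delete the call (a detectable missed gene), truncate its start (short),
#' call it in the wrong reading frame over the same locus (wrong), or split
#' it into retained fragments as a disrupted gene, tagged as a pseudogene
#' with probability `p_pseudogene_tag`.  Exact counts (`n_*`), when given,
#' override the probabilities and are drawn without replacement from the
#' genes whose tryptic peptide complement guarantees detectability at the
#' two-peptide threshold.
#'
#' @param caller_id Caller identifier.
#' @param p_miss_gene,p_start_truncate,p_wrong_frame,p_pseudogene_split
#'   Per-gene probabilities (sum must be <= 1).
#' @param p_pseudogene_tag Probability that a split gene is tagged
#'   `pseudogene` (untagged splits emulate frameshifted genes kept as good
#'   calls).
#' @param n_miss_gene,n_start_truncate,n_wrong_frame,n_pseudogene_split
#'   Optional exact event counts (override probabilities).
#' @param truncate_extra_codons Integer vector; extra codons (beyond the
#'   second peptide start) removed by a start truncation, sampled uniformly.
#' @param peptide_len_range Tryptic peptide length filter in aa, used to
#'   judge detectability; keep equal to the detection parameters.
#' @return List of class `error_profile`.
#' @export
error_profile <- function(caller_id, p_miss_gene = 0, p_start_truncate = 0,
                          p_wrong_frame = 0, p_pseudogene_split = 0,
                          p_pseudogene_tag = 1,
                          n_miss_gene = NULL, n_start_truncate = NULL,
                          n_wrong_frame = NULL, n_pseudogene_split = NULL,
                          truncate_extra_codons = 0:5,
                          peptide_len_range = c(6L, 50L)) {
  p <- c(p_miss_gene, p_start_truncate, p_wrong_frame, p_pseudogene_split,
         p_pseudogene_tag)
  if (any(p < 0) || any(p > 1)) stop("probabilities must be in [0, 1]")
  if (p_miss_gene + p_start_truncate + p_wrong_frame + p_pseudogene_split > 1)
    stop("per-gene event probabilities must sum to <= 1")
  structure(list(caller_id = caller_id, p_miss_gene = p_miss_gene,
                 p_start_truncate = p_start_truncate,
                 p_wrong_frame = p_wrong_frame,
                 p_pseudogene_split = p_pseudogene_split,
                 p_pseudogene_tag = p_pseudogene_tag,
                 n_miss_gene = n_miss_gene,
                 n_start_truncate = n_start_truncate,
                 n_wrong_frame = n_wrong_frame,
                 n_pseudogene_split = n_pseudogene_split,
                 truncate_extra_codons = as.integer(truncate_extra_codons),
                 peptide_len_range = as.integer(peptide_len_range)),
            class = "error_profile")
}

#' Peptide detection parameters
#'
#' @param p_gene_expressed Probability a gene is expressed at detectable
#'   levels (default 0.4, matching the roughly 40 percent peptide coverage
#'   typical of large prokaryotic proteogenomic compilations).
#' @param p_peptide_detected Per-tryptic-peptide detection probability for
#'   an expressed gene.
#' @param peptide_len_range Detectable peptide length range in aa.
#' @param false_match_rate Per-peptide false identification rate (default
#'   0.003, i.e. 0.3 percent FDR); false peptides are emitted as uniquely
#'   mapping out-of-frame genomic substrings so they exercise the false
#'   discovery pathway rather than the ambiguity discard.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(p_gene_expressed = 0.4,
                             p_peptide_detected = 0.5,
                             peptide_len_range = c(6L, 50L),
                             false_match_rate = 0.003) {
  p <- c(p_gene_expressed, p_peptide_detected, false_match_rate)
  if (any(p < 0) || any(p > 1)) stop("probabilities must be in [0, 1]")
  if (peptide_len_range[1L] < 1L) stop("peptide_len_range[1] must be >= 1")
  structure(list(p_gene_expressed = p_gene_expressed,
                 p_peptide_detected = p_peptide_detected,
                 peptide_len_range = as.integer(peptide_len_range),
                 false_match_rate = false_match_rate),
            class = "detection_params")
}

# n random sense (non-stop) codons at per-base GC probability p.
sample_codons <- function(n, p) {
  if (n == 0L) return(character())
  bases <- c("A", "C", "G", "T")
  wt <- c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)
  draw <- function(m) {
    b <- matrix(sample(bases, 3L * m, replace = TRUE, prob = wt), ncol = 3L)
    paste0(b[, 1L], b[, 2L], b[, 3L])
  }
  cod <- draw(n)
  bad <- cod %in% STOP_CODONS
  while (any(bad)) {
    cod[bad] <- draw(sum(bad))
    bad <- cod %in% STOP_CODONS
  }
  cod
}

sample_bases <- function(n, p) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)),
        collapse = "")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Simulate a replicon with a planted truth gene set
#'
#' Genes are placed non-overlapping on alternating random strands, each an
#' ATG start, a stop-free run of sense codons and a stop codon.  Codon
#' composition is tuned toward the target GC (base-sampling probability is
#' compensated for the AT-rich fixed elements).  Every intergenic gap
#' carries a cassette with stops in all six frames.  Fully deterministic
#' given `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @param replicon_id Name for the replicon.
#' @return List with `genome` (length-1 `DNAStringSet`), `truth`
#'   (a `gene_call_set` with caller id "truth") and `params`.
#' @export
simulate_replicon <- function(params, replicon_id = "repsim1") {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  L <- params$genome_length

  glen <- if (n > 0)
    pmax(150L, as.integer(round(stats::rnorm(n, params$gene_length_mean,
                                             params$gene_length_sd) / 3)) * 3L)
  else integer()
  ilen <- pmax(30L, as.integer(round(stats::rnorm(
    n + 1L, params$intergenic_mean, params$intergenic_sd))))
  tot <- sum(glen) + sum(ilen)
  if (tot > L)
    stop("infeasible packing (", tot, " nt needed for ", L,
         " nt replicon); reduce n_genes or gene lengths")
  ilen[n + 1L] <- ilen[n + 1L] + (L - tot)

  # GC compensation for fixed AT-rich elements (cassettes, starts, stops)
  n_fixed <- 12L * (n + 1L) + 6L * n
  gc_target_nt <- params$gc_percent / 100 * L
  p <- (gc_target_nt - n * (1 + 2 / 3)) / (L - n_fixed)
  p <- min(max(p, 0.05), 0.95)

  strands <- if (n > 0) sample(c("+", "-"), n, replace = TRUE) else character()
  pieces <- character(0)
  calls <- list()
  pos <- 0L
  intergenic <- function(m) {
    s <- sample_bases(m, p)
    mid <- (m - 12L) %/% 2L
    paste0(substr(s, 1L, mid), STOP_CASSETTE, substr(s, mid + 13L, m))
  }
  for (i in seq_len(n)) {
    ig <- intergenic(ilen[i])
    pieces <- c(pieces, ig)
    pos <- pos + ilen[i]
    body <- paste(sample_codons(glen[i] %/% 3L - 2L, p), collapse = "")
    gseq <- paste0("ATG", body, sample(STOP_CODONS, 1L))
    if (strands[i] == "-") gseq <- revcomp_chr(gseq)
    pieces <- c(pieces, gseq)
    calls[[i]] <- data.frame(
      gene_id = sprintf("tgene%03d", i), replicon_id = replicon_id,
      strand = strands[i], start = pos, end = pos + glen[i],
      is_pseudogene = FALSE, stringsAsFactors = FALSE)
    pos <- pos + glen[i]
  }
  pieces <- c(pieces, intergenic(ilen[n + 1L]))
  seq <- paste(pieces, collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, replicon_id))
  truth_calls <- if (n > 0) do.call(rbind, calls) else
    data.frame(gene_id = character(), replicon_id = character(),
               strand = character(), start = integer(), end = integer(),
               is_pseudogene = logical(), stringsAsFactors = FALSE)
  list(genome = genome, truth = gene_call_set(truth_calls, "truth"),
       params = params)
}

#' In-silico tryptic digest of a protein
#'
#' Cleaves after K or R except when the next residue is P.
#'
#' @param aa Amino-acid string (no stops).
#' @param len_range Optional length filter `c(min, max)` in aa.
#' @return data.frame with `aa_start`, `aa_end` (1-based, inclusive) and
#'   `seq`, in N- to C-terminal order.
#' @export
tryptic_peptides <- function(aa, len_range = NULL) {
  n <- nchar(aa)
  if (n == 0L)
    return(data.frame(aa_start = integer(), aa_end = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  res <- strsplit(aa, "")[[1L]]
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[cut_after + 1L] != "P" |
                           cut_after == n]
  bounds <- unique(c(0L, cut_after, n))
  bounds <- sort(bounds)
  out <- data.frame(aa_start = bounds[-length(bounds)] + 1L,
                    aa_end = bounds[-1L], stringsAsFactors = FALSE)
  out$seq <- substring(aa, out$aa_start, out$aa_end)
  if (!is.null(len_range)) {
    len <- out$aa_end - out$aa_start + 1L
    out <- out[len >= len_range[1L] & len <= len_range[2L], , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Genomic interval of protein residues [a1, a2] of a gene whose coding
# region (excluding the stop codon) starts at the gene's 5' terminus.
pep_interval <- function(start, end, strand, a1, a2) {
  if (strand == "+") c(start + 3L * (a1 - 1L), start + 3L * a2)
  else c(end - 3L * a2, end - 3L * (a1 - 1L))
}

# Protein sequence (no stop) of a truth-style single-fragment gene call.
gene_protein <- function(genome, replicon_id, strand, start, end) {
  if (strand == "+")
    translate_interval(genome, replicon_id, "+", start, end - 3L)
  else
    translate_interval(genome, replicon_id, "-", start + 3L, end)
}

#' Sample tryptic peptide evidence from a truth gene set
#'
#' Each gene is expressed with probability `p_gene_expressed`; each of its
#' tryptic peptides inside the length window is detected independently with
#' probability `p_peptide_detected`.  False identifications are added at
#' `false_match_rate` per true peptide: each is an out-of-frame or
#' intergenic genomic substring, rejection-sampled to map uniquely in the
#' six-frame translation and not to coincide with any true peptide, so it
#' exercises the false-discovery pathway rather than the ambiguity discard.
#'
#' @param truth `gene_call_set` of truth genes (single-fragment calls).
#' @param genome The replicon(s) the genes live on.
#' @param det A [detection_params()] object.
#' @param seed Integer seed.
#' @return List with `peptides` (data.frame `peptide_id`, `aa_seq`, in
#'   emission order) and `ledger` (the same rows plus true `replicon_id`,
#'   `strand`, `start`, `end`, `gene_id`, `is_false`).
#' @export
sample_peptides <- function(truth, genome, det = detection_params(),
                            seed = 1L) {
  stopifnot(inherits(det, "detection_params"))
  genome <- as_genome(genome)
  set.seed(seed)
  cl <- truth$calls
  rows <- list()
  for (i in seq_len(nrow(cl))) {
    if (stats::runif(1L) >= det$p_gene_expressed) next
    prot <- gene_protein(genome, cl$replicon_id[i], cl$strand[i],
                         cl$start[i], cl$end[i])
    peps <- tryptic_peptides(prot, det$peptide_len_range)
    if (nrow(peps) == 0L) next
    hit <- stats::runif(nrow(peps)) < det$p_peptide_detected
    peps <- peps[hit, , drop = FALSE]
    for (k in seq_len(nrow(peps))) {
      g <- pep_interval(cl$start[i], cl$end[i], cl$strand[i],
                        peps$aa_start[k], peps$aa_end[k])
      rows[[length(rows) + 1L]] <- data.frame(
        aa_seq = peps$seq[k], replicon_id = cl$replicon_id[i],
        strand = cl$strand[i], start = g[1L], end = g[2L],
        gene_id = cl$gene_id[i], is_false = FALSE, stringsAsFactors = FALSE)
    }
  }
  ledger <- if (length(rows)) do.call(rbind, rows) else
    data.frame(aa_seq = character(), replicon_id = character(),
               strand = character(), start = integer(), end = integer(),
               gene_id = character(), is_false = logical(),
               stringsAsFactors = FALSE)

  n_true <- nrow(ledger)
  n_false <- if (n_true > 0 && det$false_match_rate > 0)
    stats::rbinom(1L, n_true, det$false_match_rate) else 0L
  if (n_false > 0L) {
    idx <- six_frame_index(genome)
    lengths <- replicon_lengths(idx)
    ftab <- fragment_table(truth, lengths)
    fr <- idx$frames
    made <- 0L
    guard <- 0L
    while (made < n_false && guard < 10000L) {
      guard <- guard + 1L
      r <- sample.int(nrow(fr), 1L)
      alen <- nchar(fr$aa_seq[r])
      plen <- sample(7:20, 1L)
      if (alen < plen + 2L) next
      a1 <- sample.int(alen - plen + 1L, 1L)
      s <- substr(fr$aa_seq[r], a1, a1 + plen - 1L)
      if (grepl("[*X]", s)) next
      g <- aa_to_genomic(a1, a1 + plen - 1L, fr$strand[r], fr$frame[r],
                         fr$seq_length[r])
      # must not sit in-frame inside a truth gene (would act as true support)
      inside <- any(ftab$replicon_id == fr$replicon_id[r] &
                      ftab$strand == fr$strand[r] & ftab$frame == fr$frame[r] &
                      ftab$fstart <= g[1L] & ftab$fend >= g[2L])
      if (inside) next
      if (s %in% ledger$aa_seq) next
      if (nrow(six_frame_hits(idx, s)) != 1L) next
      ledger <- rbind(ledger, data.frame(
        aa_seq = s, replicon_id = fr$replicon_id[r], strand = fr$strand[r],
        start = g[1L], end = g[2L], gene_id = NA_character_, is_false = TRUE,
        stringsAsFactors = FALSE))
      made <- made + 1L
    }
  }
  if (nrow(ledger)) {
    ledger <- cbind(peptide_id = sprintf("pep%05d", seq_len(nrow(ledger))),
                    ledger, stringsAsFactors = FALSE)
  } else {
    ledger <- cbind(data.frame(peptide_id = character()), ledger)
  }
  rownames(ledger) <- NULL
  list(peptides = ledger[, c("peptide_id", "aa_seq")], ledger = ledger)
}

#' Perturb a truth gene set into a synthetic caller's output
#'
#' Applies at most one event per gene (see [error_profile()]) and records
#' every planted deviation in a ledger with the error category the
#' evaluation is expected to recover under noiseless peptide detection.
#' Genes whose tryptic peptide complement cannot satisfy the two-peptide
#' evidence rule are still perturbed (except for pseudogene splits) but
#' flagged `detectable = FALSE`.
#'
#' @param truth Truth `gene_call_set` (single-fragment calls).
#' @param profile An [error_profile()].
#' @param genome The replicon(s).
#' @param seed Integer seed.
#' @return List with `calls` (the perturbed `gene_call_set`, caller id from
#'   the profile) and `ledger` (data.frame `gene_id`, `event`,
#'   `expected_category`, `detectable`, `strand`, `replicon_id`,
#'   `orig_start`, `orig_end`, `new_start`, `new_end`).
#' @export
perturb_calls <- function(truth, profile, genome, seed = 1L) {
  stopifnot(inherits(profile, "error_profile"))
  genome <- as_genome(genome)
  set.seed(seed)
  cl <- truth$calls
  n <- nrow(cl)
  if (n == 0L) stop("truth gene set is empty")

  digests <- lapply(seq_len(n), function(i) {
    prot <- gene_protein(genome, cl$replicon_id[i], cl$strand[i],
                         cl$start[i], cl$end[i])
    tryptic_peptides(prot, profile$peptide_len_range)
  })
  aa_len <- (cl$end - cl$start) %/% 3L - 1L

  # Eligibility under the two-peptide rule.  The anchoring evidence peptides
  # are required to be >= 7-8 aa so they map uniquely in practice (a 6-mer
  # has a non-negligible chance of a second six-frame occurrence, which
  # would discard it as ambiguous and starve the planted error of support).
  d8 <- lapply(digests, function(d)
    d[d$aa_end - d$aa_start + 1L >= 8L, , drop = FALSE])
  elig_short <- vapply(seq_len(n), function(i) {
    d <- d8[[i]]
    nrow(d) >= 2L &&
      d$aa_start[2L] + 1L + max(profile$truncate_extra_codons) <=
        aa_len[i] - 20L
  }, NA)
  elig_basic <- vapply(digests, function(d)
    sum(d$aa_end - d$aa_start + 1L >= 7L) >= 2L, NA)
  elig_pseudo <- vapply(seq_len(n), function(i) {
    d <- digests[[i]]
    nrow(d) >= 3L && sum(d$aa_end - d$aa_start + 1L >= 7L) >= 3L &&
      any((d$aa_end - d$aa_start + 1L)[-c(1L, nrow(d))] >= 4L)
  }, NA)

  event <- rep("keep", n)
  exact <- !is.null(profile$n_miss_gene) || !is.null(profile$n_start_truncate) ||
    !is.null(profile$n_wrong_frame) || !is.null(profile$n_pseudogene_split)
  if (exact) {
    pick <- function(pool, k, what) {
      k <- if (is.null(k)) 0L else k
      if (length(pool) < k)
        stop("not enough eligible genes for ", what)
      if (k == 0L) integer() else pool[sample.int(length(pool), k)]
    }
    free <- seq_len(n)
    i_miss <- pick(free[elig_basic[free]], profile$n_miss_gene, "miss")
    free <- setdiff(free, i_miss)
    i_wrong <- pick(free[elig_basic[free]], profile$n_wrong_frame, "wrong")
    free <- setdiff(free, i_wrong)
    i_pseudo <- pick(free[elig_pseudo[free]], profile$n_pseudogene_split,
                     "pseudogene split")
    free <- setdiff(free, i_pseudo)
    i_short <- pick(free[elig_short[free]], profile$n_start_truncate, "short")
    event[i_miss] <- "miss"; event[i_wrong] <- "wrong_frame"
    event[i_pseudo] <- "pseudo_split"; event[i_short] <- "truncate"
  } else {
    u <- stats::runif(n)
    p1 <- profile$p_miss_gene
    p2 <- p1 + profile$p_start_truncate
    p3 <- p2 + profile$p_wrong_frame
    p4 <- p3 + profile$p_pseudogene_split
    event[u < p1] <- "miss"
    event[u >= p1 & u < p2] <- "truncate"
    event[u >= p2 & u < p3] <- "wrong_frame"
    event[u >= p3 & u < p4 & elig_pseudo] <- "pseudo_split"
  }

  out_calls <- list()
  ledger <- list()
  add_ledger <- function(i, ev, cat, detectable, ns, ne, tagged = NA) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      gene_id = cl$gene_id[i], event = ev, expected_category = cat,
      detectable = detectable, tagged = tagged, strand = cl$strand[i],
      replicon_id = cl$replicon_id[i], orig_start = cl$start[i],
      orig_end = cl$end[i], new_start = ns, new_end = ne,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(n)) {
    ev <- event[i]
    if (ev == "keep") {
      out_calls[[length(out_calls) + 1L]] <- cl[i, , drop = FALSE]
    } else if (ev == "miss") {
      add_ledger(i, "miss", "missed", elig_basic[i], NA_integer_, NA_integer_)
    } else if (ev == "truncate") {
      d <- d8[[i]]
      if (elig_short[i]) {
        extra <- sample(profile$truncate_extra_codons, 1L)
        s_aa <- d$aa_start[2L] + 1L + extra   # first kept codon (1-based)
      } else {
        # undetectable fallback still removes >= 9 nt (>= 3 codons)
        s_aa <- max(4L, min(5L, aa_len[i] - 20L))
      }
      cut <- 3L * (s_aa - 1L)
      new <- cl[i, , drop = FALSE]
      if (cl$strand[i] == "+") new$start <- cl$start[i] + cut
      else new$end <- cl$end[i] - cut
      new$fragments <- list(data.frame(start = new$start, end = new$end))
      out_calls[[length(out_calls) + 1L]] <- new
      add_ledger(i, "truncate", "short", elig_short[i], new$start, new$end)
    } else if (ev == "wrong_frame") {
      shift <- sample(1:2, 1L)
      ns <- cl$start[i] + shift
      ne <- cl$end[i] - 3L + shift
      new <- cl[i, , drop = FALSE]
      new$start <- ns; new$end <- ne
      new$fragments <- list(data.frame(start = ns, end = ne))
      out_calls[[length(out_calls) + 1L]] <- new
      add_ledger(i, "wrong_frame", "wrong", elig_basic[i], ns, ne)
    } else if (ev == "pseudo_split") {
      d <- digests[[i]]
      mid <- which((d$aa_end - d$aa_start + 1L) >= 4L)
      mid <- mid[mid > 1L & mid < nrow(d)][1L]
      gap <- pep_interval(cl$start[i], cl$end[i], cl$strand[i],
                          d$aa_start[mid] + 1L, d$aa_start[mid] + 2L)
      frags <- data.frame(start = c(cl$start[i], gap[2L]),
                          end = c(gap[1L], cl$end[i]))
      tagged <- stats::runif(1L) < profile$p_pseudogene_tag
      new <- cl[i, , drop = FALSE]
      new$is_pseudogene <- tagged
      new$fragments <- list(frags)
      out_calls[[length(out_calls) + 1L]] <- new
      add_ledger(i, "pseudo_split", if (tagged) "missed" else "none",
                 TRUE, cl$start[i], cl$end[i], tagged = tagged)
    }
  }

  calls <- if (length(out_calls)) do.call(rbind, out_calls) else
    cl[integer(), , drop = FALSE]
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(gene_id = character(), event = character(),
               expected_category = character(), detectable = logical(),
               tagged = logical(), strand = character(),
               replicon_id = character(), orig_start = integer(),
               orig_end = integer(), new_start = integer(),
               new_end = integer(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  rownames(ledger) <- NULL
  list(calls = gene_call_set(calls, profile$caller_id), ledger = ledger)
}

#' Build a self-contained benchmark bundle on disk
#'
#' Simulates a replicon and truth gene set, perturbs it once per caller
#' profile, samples peptide evidence, and writes FASTA, per-caller GFF3,
#' peptide TSV and truth/planted-error ledgers into `dir`.  Re-running with
#' the same seed reproduces the files byte for byte.
#'
#' @param dir Output directory (created if missing).
#' @param params A [sim_params()].
#' @param profiles List of [error_profile()] objects (>= 1).
#' @param det A [detection_params()].
#' @param seed Integer master seed; sub-seeds for the simulation,
#'   peptide sampling and each perturbation are derived from it.
#' @return (Invisibly) a list with the in-memory objects (`genome`,
#'   `truth`, `calls`, `peptides`, `peptide_ledger`, `planted`) and `paths`.
#' @export
make_benchmark <- function(dir, params = sim_params(), profiles,
                           det = detection_params(), seed = 1L) {
  if (length(profiles) < 1L) stop("need at least one error_profile")
  if (inherits(profiles, "error_profile")) profiles <- list(profiles)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L + length(profiles))
  params$seed <- seeds[1L]
  sim <- simulate_replicon(params)
  pep <- sample_peptides(sim$truth, sim$genome, det, seed = seeds[2L])
  pert <- lapply(seq_along(profiles), function(i)
    perturb_calls(sim$truth, profiles[[i]], sim$genome,
                  seed = seeds[2L + i]))
  names(pert) <- vapply(profiles, function(p) p$caller_id, "")

  paths <- list(genome = file.path(dir, "genome.fasta"),
                truth = file.path(dir, "truth.gff3"),
                peptides = file.path(dir, "peptides.tsv"),
                peptide_ledger = file.path(dir, "peptide_ledger.tsv"))
  write_genome(sim$genome, paths$genome)
  write_gene_calls(sim$truth, paths$truth)
  write_peptides(pep$peptides, paths$peptides)
  utils::write.table(pep$ledger, paths$peptide_ledger, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$calls <- character(0)
  paths$planted <- character(0)
  for (nm in names(pert)) {
    cp <- file.path(dir, paste0("calls_", nm, ".gff3"))
    lp <- file.path(dir, paste0("planted_", nm, ".tsv"))
    write_gene_calls(pert[[nm]]$calls, cp)
    utils::write.table(pert[[nm]]$ledger, lp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$calls <- c(paths$calls, stats::setNames(cp, nm))
    paths$planted <- c(paths$planted, stats::setNames(lp, nm))
  }
  cfg <- list(seed = seed, genome_length = params$genome_length,
              gc_percent = params$gc_percent, n_genes = params$n_genes,
              callers = names(pert),
              detection = unclass(det))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$config <- file.path(dir, "config.json")
  invisible(list(genome = sim$genome, truth = sim$truth,
                 calls = lapply(pert, `[[`, "calls"),
                 planted = lapply(pert, `[[`, "ledger"),
                 peptides = pep$peptides, peptide_ledger = pep$ledger,
                 paths = paths))
}
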