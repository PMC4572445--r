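# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's own code paths: translation goes
# through seqinr, substring search through base-R regexpr loops.

revcomp_str <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# Codon-by-codon translation via seqinr (bacterial code 11 shares the
# standard codon->aa map; initiation differences are irrelevant here).
oracle_translate <- function(seq, off = 0) {
  n <- (nchar(seq) - off) %/% 3
  if (n <= 0) return("")
  aa <- seqinr::translate(strsplit(seq, "")[[1]], frame = off, numcode = 11,
                          NAstring = "X", ambiguous = FALSE)
  paste(aa[seq_len(n)], collapse = "")
}

oracle_six_frames <- function(seq) {
  rc <- revcomp_str(seq)
  out <- list()
  for (st in c("+", "-")) {
    s <- if (st == "+") seq else rc
    for (off in 0:2)
      out[[paste(st, off)]] <- list(strand = st, frame = off,
                                    aa = oracle_translate(s, off))
  }
  out
}

# All (possibly overlapping) occurrence start positions of pat in subject.
oracle_find_all <- function(pat, subject) {
  hits <- integer()
  from <- 1L
  repeat {
    m <- regexpr(pat, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (m == -1L) break
    hits <- c(hits, from + as.integer(m) - 1L)
    from <- from + as.integer(m)
  }
  hits
}

# Naive all-positions six-frame mapping of one peptide against one replicon
# (character scalar).  Returns a data.frame of hits with genomic 0-based
# half-open coordinates.
oracle_map_peptide <- function(pep, seq) {
  L <- nchar(seq)
  k <- nchar(pep)
  frames <- oracle_six_frames(seq)
  rows <- list()
  for (f in frames) {
    for (m in oracle_find_all(pep, f$aa)) {
      if (f$strand == "+") {
        gs <- f$frame + 3L * (m - 1L); ge <- gs + 3L * k
      } else {
        rs <- f$frame + 3L * (m - 1L)
        gs <- L - (rs + 3L * k); ge <- L - rs
      }
      rows[[length(rows) + 1L]] <- data.frame(strand = f$strand,
                                              frame = f$frame,
                                              start = gs, end = ge)
    }
  }
  if (!length(rows))
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer()))
  do.call(rbind, rows)
}

# Exhaustive stop-delimited ORF scan over all six frames.
oracle_orfs <- function(seq, min_len_nt) {
  L <- nchar(seq)
  frames <- oracle_six_frames(seq)
  rows <- list()
  for (f in frames) {
    ch <- strsplit(f$aa, "")[[1]]
    n <- length(ch)
    i <- 1L
    while (i <= n) {
      if (ch[i] == "*") { i <- i + 1L; next }
      j <- i
      while (j < n && ch[j + 1L] != "*") j <- j + 1L
      if (3L * (j - i + 1L) >= min_len_nt) {
        if (f$strand == "+") {
          gs <- f$frame + 3L * (i - 1L); ge <- f$frame + 3L * j
        } else {
          gs <- L - (f$frame + 3L * j); ge <- L - (f$frame + 3L * (i - 1L))
        }
        rows[[length(rows) + 1L]] <- data.frame(strand = f$strand,
                                                frame = f$frame,
                                                start = gs, end = ge)
      }
      i <- j + 1L
    }
  }
  if (!length(rows))
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_sense_codons <- function(n) {
  cod <- character(0)
  while (length(cod) < n) {
    b <- matrix(sample(c("A", "C", "G", "T"), 3L * (n - length(cod)),
                       replace = TRUE), ncol = 3L)
    new <- paste0(b[, 1L], b[, 2L], b[, 3L])
    cod <- c(cod, new[!(new %in% c("TAA", "TAG", "TGA"))])
  }
  cod[seq_len(n)]
}

# Tiny handcrafted genome: one '+' gene at [100, 400) and one '-' gene at
# [500, 800) planted in random background, with frame-closing padding left
# to chance.  Returns list(genome, truth).
toy_genome <- function(seed = 101) {
  set.seed(seed)
  gene_plus <- paste0("ATG", paste(random_sense_codons(98), collapse = ""),
                      "TAA")
  gene_minus_sense <- paste0("ATG", paste(random_sense_codons(98),
                                          collapse = ""), "TGA")
  stopifnot(nchar(gene_plus) == 300, nchar(gene_minus_sense) == 300)
  seq <- paste0(random_dna(100), gene_plus, random_dna(100),
                revcomp_str(gene_minus_sense), random_dna(200))
  truth <- gene_call_set(data.frame(
    gene_id = c("gP", "gM"), replicon_id = "toy",
    strand = c("+", "-"), start = c(100L, 500L), end = c(400L, 800L),
    is_pseudogene = FALSE, stringsAsFactors = FALSE), "truth")
  list(genome = as_genome(c(toy = seq)), truth = truth)
}
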