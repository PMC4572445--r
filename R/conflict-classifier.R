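# Core scoring engine: peptide support, conflict detection, wrong/short/
# missed error classification, pseudogene re-scoring, FDR arithmetic.

empty_errors <- function() {
  data.frame(category = character(), caller_id = character(),
             replicon_id = character(), strand = character(),
             gene_id = character(), implied_start = integer(),
             implied_end = integer(), frame = integer(),
             n_nonredundant = integer(), peptide_ids = character(),
             stringsAsFactors = FALSE)
}

# Logical vector: is mapped peptide i wholly inside some fragment of `calls`
# with matching strand and reading frame?
supporting_flags <- function(mapped, calls, lengths) {
  supp <- rep(FALSE, nrow(mapped))
  ft <- fragment_table(calls, lengths)
  if (nrow(ft) == 0L || nrow(mapped) == 0L) return(supp)
  for (j in seq_len(nrow(ft))) {
    hit <- mapped$replicon_id == ft$replicon_id[j] &
      mapped$strand == ft$strand[j] &
      mapped$frame == ft$frame[j] &
      mapped$start >= ft$fstart[j] & mapped$end <= ft$fend[j]
    supp <- supp | hit
  }
  supp
}

#' Peptide support and gene coverage for one caller
#'
#' A mapped peptide supports a gene call when it falls wholly inside one of
#' the call's fragments on the same strand and in the same reading frame.
#' Coverage is the percentage of calls with at least one supporting peptide.
#'
#' @param mapped data.frame of mapped peptides from [map_peptides()].
#' @param calls A `gene_call_set`.
#' @param genome `DNAStringSet`, named character vector or
#'   [six_frame_index()] (used for replicon lengths / frame arithmetic).
#' @return List of class `support_summary`: `caller_id`,
#'   `n_supporting_peptides`, `n_conflicting_peptides`, `n_mapped`,
#'   `n_genes_with_peptide`, `n_genes_total`, `coverage_percent`.
#' @export
peptide_support <- function(mapped, calls, genome) {
  lengths <- replicon_lengths(genome)
  supp <- supporting_flags(mapped, calls, lengths)
  ft <- fragment_table(calls, lengths)
  genes_with <- character()
  if (nrow(ft) && any(supp)) {
    mm <- mapped[supp, , drop = FALSE]
    for (j in seq_len(nrow(ft))) {
      if (ft$gene_id[j] %in% genes_with) next
      hit <- mm$replicon_id == ft$replicon_id[j] &
        mm$strand == ft$strand[j] & mm$frame == ft$frame[j] &
        mm$start >= ft$fstart[j] & mm$end <= ft$fend[j]
      if (any(hit)) genes_with <- c(genes_with, ft$gene_id[j])
    }
  }
  n_total <- n_calls(calls)
  structure(list(
    caller_id = calls$caller_id,
    n_supporting_peptides = sum(supp),
    n_conflicting_peptides = sum(!supp),
    n_mapped = nrow(mapped),
    n_genes_with_peptide = length(genes_with),
    n_genes_total = n_total,
    coverage_percent = if (n_total > 0) 100 * length(genes_with) / n_total else 0
  ), class = "support_summary")
}

#' @export
print.support_summary <- function(x, ...) {
  cat(sprintf(
    "support_summary '%s': %d/%d peptides supporting, %d conflicting; %d/%d genes covered (%.1f%%)\n",
    x$caller_id, x$n_supporting_peptides, x$n_mapped,
    x$n_conflicting_peptides, x$n_genes_with_peptide, x$n_genes_total,
    x$coverage_percent))
  invisible(x)
}

#' Find peptides conflicting with a caller's gene calls
#'
#' Conflicts are exactly the mapped peptides that support no call.  Each is
#' labelled with its relation to the call set:
#' \describe{
#'   \item{extends_upstream}{in frame with an overlapped call but starting
#'     5' of the call's start on the coding strand.}
#'   \item{spans_boundary}{in frame with an overlapped call but extending
#'     past its 3' end, or falling in a gap between the call's fragments.}
#'   \item{overlaps_out_of_frame}{overlaps at least one call but matches no
#'     overlapped call's strand and frame.}
#'   \item{outside_all}{overlaps no call.}
#' }
#'
#' @inheritParams peptide_support
#' @return data.frame: the conflicting subset of `mapped` plus `caller_id`,
#'   `relation` and `nearest_gene_id` (the overlapped call that determined
#'   the relation; NA for `outside_all`).
#' @export
find_conflicts <- function(mapped, calls, genome) {
  lengths <- replicon_lengths(genome)
  supp <- supporting_flags(mapped, calls, lengths)
  conf <- mapped[!supp, , drop = FALSE]
  rownames(conf) <- NULL
  conf$caller_id <- rep(calls$caller_id, nrow(conf))
  conf$relation <- rep(NA_character_, nrow(conf))
  conf$nearest_gene_id <- rep(NA_character_, nrow(conf))
  if (nrow(conf) == 0L) return(conf)
  cl <- calls$calls
  ft <- fragment_table(calls, lengths)
  for (i in seq_len(nrow(conf))) {
    ov <- which(cl$replicon_id == conf$replicon_id[i] &
                  cl$start < conf$end[i] & cl$end > conf$start[i])
    if (length(ov) == 0L) {
      conf$relation[i] <- "outside_all"
      next
    }
    best <- "overlaps_out_of_frame"
    best_gene <- cl$gene_id[ov[1L]]
    prio <- c(overlaps_out_of_frame = 1L, spans_boundary = 2L,
              extends_upstream = 3L)
    for (j in ov) {
      if (cl$strand[j] != conf$strand[i]) next
      frames_j <- ft$frame[ft$gene_id == cl$gene_id[j]]
      if (!(conf$frame[i] %in% frames_j)) next
      up <- if (conf$strand[i] == "+") conf$start[i] < cl$start[j]
            else conf$end[i] > cl$end[j]
      rel <- if (up) "extends_upstream" else "spans_boundary"
      if (prio[[rel]] > prio[[best]]) {
        best <- rel
        best_gene <- cl$gene_id[j]
      }
    }
    conf$relation[i] <- best
    conf$nearest_gene_id[i] <- best_gene
  }
  conf
}

# Upstream in-frame ORF extension limit of a call: the 5'-most genomic
# coordinate (on '+') / 5'-most end (on '-') reachable without crossing an
# in-frame stop.  `frame` is the frame of the call's 5'-terminal fragment.
upstream_limit <- function(idx, replicon_id, strand, frame, call_start,
                           call_end) {
  fr <- idx$frames
  r <- which(fr$replicon_id == replicon_id & fr$strand == strand &
               fr$frame == frame)
  aa <- fr$aa_seq[r]
  L <- fr$seq_length[r]
  stops <- aa_stop_positions(aa)
  i_call <- genomic_to_aa(call_start, call_end, strand, frame, L)
  p <- if (length(stops) && any(stops < i_call)) max(stops[stops < i_call]) else 0L
  if (strand == "+") frame + 3L * p           # min allowed peptide start
  else L - frame - 3L * p                     # max allowed peptide end
}

# Maximal stop-to-stop ORF (genomic interval) containing the peptide's
# codon run in its own frame.
orf_around <- function(idx, replicon_id, strand, frame, pstart, pend) {
  fr <- idx$frames
  r <- which(fr$replicon_id == replicon_id & fr$strand == strand &
               fr$frame == frame)
  aa <- fr$aa_seq[r]
  L <- fr$seq_length[r]
  n <- nchar(aa)
  stops <- aa_stop_positions(aa)
  i1 <- genomic_to_aa(pstart, pend, strand, frame, L)
  i2 <- i1 + (pend - pstart) %/% 3L - 1L
  p <- if (length(stops) && any(stops < i1)) max(stops[stops < i1]) else 0L
  q <- if (length(stops) && any(stops > i2)) min(stops[stops > i2]) else n + 1L
  aa_to_genomic(p + 1L, q - 1L, strand, frame, L)
}

n_nonredundant <- function(df)
  length(unique(paste(df$replicon_id, df$strand, df$start, df$end)))

collapse_ids <- function(df) {
  o <- order(df$start, df$end, df$peptide_id)
  paste(df$peptide_id[o], collapse = ",")
}

#' Classify conflicting peptides into gene-calling errors
#'
#' Applies the three error-scoring rules, each requiring at least
#' `min_support` non-redundant peptides (peptides count once per distinct
#' genomic interval):
#' \describe{
#'   \item{wrong}{a call overlapped by conflicting peptides that all share a
#'     strand and reading frame different from the call's.}
#'   \item{short}{a call with in-frame conflicting peptides starting 5' of
#'     its annotated start, each lying within the call's maximal in-frame
#'     upstream ORF extension (no in-frame stop between peptide and start).
#'     The implied interval extends the call to the 5'-most supporting
#'     peptide.  Peptides wholly upstream of the call (overlapping no call)
#'     count when they satisfy the same ORF condition.}
#'   \item{missed}{peptides overlapping no call, sharing strand and frame
#'     within one maximal ORF that contains no in-frame call; the implied
#'     interval is that stop-to-stop ORF.}
#' }
#' Each peptide contributes to at most one error; an upstream peptide is
#' assigned to the nearest qualifying call.
#'
#' @param conflicts data.frame from [find_conflicts()].
#' @param calls The `gene_call_set` the conflicts were computed against.
#' @param genome Genome or [six_frame_index()].
#' @param min_support Minimum non-redundant peptides per error (default 2).
#' @return data.frame of error calls: `category`, `caller_id`,
#'   `replicon_id`, `strand`, `gene_id` (NA for missed), `implied_start`,
#'   `implied_end`, `frame`, `n_nonredundant`, `peptide_ids`.
#' @export
classify_errors <- function(conflicts, calls, genome, min_support = 2L) {
  if (min_support < 1L) stop("min_support must be >= 1")
  idx <- as_sfindex(genome)
  lengths <- replicon_lengths(idx)
  cl <- calls$calls
  ft <- fragment_table(calls, lengths)
  errors <- list()

  ## --- wrong: out-of-frame peptide groups over a call -------------------
  oofr <- conflicts[conflicts$relation %in% "overlaps_out_of_frame", ,
                    drop = FALSE]
  for (j in seq_len(nrow(cl))) {
    ov <- oofr[oofr$replicon_id == cl$replicon_id[j] &
                 oofr$start < cl$end[j] & oofr$end > cl$start[j], ,
               drop = FALSE]
    if (nrow(ov) == 0L) next
    # drop peptides in frame with this call (conflicting with another call)
    frames_j <- ft$frame[ft$gene_id == cl$gene_id[j]]
    ov <- ov[!(ov$strand == cl$strand[j] & ov$frame %in% frames_j), ,
             drop = FALSE]
    if (nrow(ov) == 0L) next
    grp <- split(ov, paste(ov$strand, ov$frame))
    sizes <- vapply(grp, n_nonredundant, 0L)
    if (max(sizes) < min_support) next
    g <- grp[[which.max(sizes)]]
    errors[[length(errors) + 1L]] <- data.frame(
      category = "wrong", caller_id = calls$caller_id,
      replicon_id = cl$replicon_id[j], strand = g$strand[1L],
      gene_id = cl$gene_id[j],
      implied_start = min(g$start), implied_end = max(g$end),
      frame = g$frame[1L], n_nonredundant = max(sizes),
      peptide_ids = collapse_ids(g), stringsAsFactors = FALSE)
  }

  ## --- short: upstream in-frame peptides within the ORF extension -------
  up <- conflicts[conflicts$relation %in% c("extends_upstream", "outside_all"), ,
                  drop = FALSE]
  short_assign <- NULL
  if (nrow(up) && nrow(cl)) {
    pairs <- list()
    for (j in seq_len(nrow(cl))) {
      # frame of the 5'-terminal fragment on the coding strand
      fj <- ft[ft$gene_id == cl$gene_id[j], , drop = FALSE]
      f5 <- if (cl$strand[j] == "+") fj[which.min(fj$fstart), ]
            else fj[which.max(fj$fend), ]
      lim <- upstream_limit(idx, cl$replicon_id[j], cl$strand[j], f5$frame,
                            cl$start[j], cl$end[j])
      cand <- up$replicon_id == cl$replicon_id[j] &
        up$strand == cl$strand[j] & up$frame == f5$frame
      if (cl$strand[j] == "+") {
        cand <- cand & up$start < cl$start[j] & up$start >= lim &
          up$end <= cl$end[j]
        gap <- cl$start[j] - up$start
      } else {
        cand <- cand & up$end > cl$end[j] & up$end <= lim &
          up$start >= cl$start[j]
        gap <- up$end - cl$end[j]
      }
      w <- which(cand)
      if (length(w))
        pairs[[length(pairs) + 1L]] <- data.frame(
          pep = w, call = j, gap = gap[w])
    }
    if (length(pairs)) {
      pairs <- do.call(rbind, pairs)
      pairs <- pairs[order(pairs$pep, pairs$gap), , drop = FALSE]
      short_assign <- pairs[!duplicated(pairs$pep), , drop = FALSE]
    }
  }
  claimed <- integer()
  if (!is.null(short_assign)) {
    for (j in unique(short_assign$call)) {
      w <- short_assign$pep[short_assign$call == j]
      g <- up[w, , drop = FALSE]
      if (n_nonredundant(g) < min_support) next
      claimed <- c(claimed, w)
      imp_start <- if (cl$strand[j] == "+") min(g$start) else cl$start[j]
      imp_end <- if (cl$strand[j] == "+") cl$end[j] else max(g$end)
      errors[[length(errors) + 1L]] <- data.frame(
        category = "short", caller_id = calls$caller_id,
        replicon_id = cl$replicon_id[j], strand = cl$strand[j],
        gene_id = cl$gene_id[j],
        implied_start = imp_start, implied_end = imp_end,
        frame = g$frame[1L], n_nonredundant = n_nonredundant(g),
        peptide_ids = collapse_ids(g), stringsAsFactors = FALSE)
    }
  }

  ## --- missed: outside-all peptide groups in call-free ORFs -------------
  # `claimed` indexes rows of `up`; map back to rows of `conflicts`
  up_rows <- which(conflicts$relation %in% c("extends_upstream", "outside_all"))
  claimed_conf <- up_rows[claimed]
  out_idx <- setdiff(which(conflicts$relation %in% "outside_all"), claimed_conf)
  if (length(out_idx)) {
    oo <- conflicts[out_idx, , drop = FALSE]
    orfs <- t(vapply(seq_len(nrow(oo)), function(i)
      orf_around(idx, oo$replicon_id[i], oo$strand[i], oo$frame[i],
                 oo$start[i], oo$end[i]), integer(2L)))
    oo$orf_start <- orfs[, 1L]
    oo$orf_end <- orfs[, 2L]
    # exclude ORFs containing an in-frame call (same strand+frame fragment)
    blocked <- vapply(seq_len(nrow(oo)), function(i) {
      any(ft$replicon_id == oo$replicon_id[i] & ft$strand == oo$strand[i] &
            ft$frame == oo$frame[i] & ft$fstart < oo$orf_end[i] &
            ft$fend > oo$orf_start[i])
    }, NA)
    oo <- oo[!blocked, , drop = FALSE]
    if (nrow(oo)) {
      grp <- split(oo, paste(oo$replicon_id, oo$strand, oo$frame, oo$orf_start))
      for (g in grp) {
        if (n_nonredundant(g) < min_support) next
        errors[[length(errors) + 1L]] <- data.frame(
          category = "missed", caller_id = calls$caller_id,
          replicon_id = g$replicon_id[1L], strand = g$strand[1L],
          gene_id = NA_character_,
          implied_start = g$orf_start[1L], implied_end = g$orf_end[1L],
          frame = g$frame[1L], n_nonredundant = n_nonredundant(g),
          peptide_ids = collapse_ids(g), stringsAsFactors = FALSE)
      }
    }
  }

  if (length(errors) == 0L) return(empty_errors())
  out <- do.call(rbind, errors)
  out <- out[order(out$category, out$replicon_id, out$implied_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-score pseudogene and frameshifted calls against confirming peptides
#'
#' A pseudogene-tagged call whose fragments contain at least `min_support`
#' non-redundant in-frame peptides is re-scored as a missed gene (the
#' peptides show the locus encodes a real protein).  An untagged
#' multi-fragment (frameshifted) call with that many confirming peptides is
#' considered a good call: any error previously recorded against it is
#' dropped.  Peptides confirming pseudogene fragments are never counted in
#' other categories (errors against the re-scored call are replaced by the
#' missed call).
#'
#' @param errors data.frame from [classify_errors()].
#' @param calls The `gene_call_set`.
#' @param mapped All mapped peptides (support and conflicts alike).
#' @param genome Genome or [six_frame_index()].
#' @param min_support Minimum non-redundant confirming peptides (default 2).
#' @return Updated error data.frame.
#' @export
rescore_pseudogenes <- function(errors, calls, mapped, genome,
                                min_support = 2L) {
  lengths <- replicon_lengths(genome)
  cl <- calls$calls
  ft <- fragment_table(calls, lengths)
  targets <- which(cl$is_pseudogene |
                     vapply(cl$fragments, nrow, 0L) > 1L)
  for (j in targets) {
    fj <- ft[ft$gene_id == cl$gene_id[j], , drop = FALSE]
    conf <- rep(FALSE, nrow(mapped))
    for (k in seq_len(nrow(fj))) {
      conf <- conf | (mapped$replicon_id == fj$replicon_id[k] &
                        mapped$strand == fj$strand[k] &
                        mapped$frame == fj$frame[k] &
                        mapped$start >= fj$fstart[k] &
                        mapped$end <= fj$fend[k])
    }
    g <- mapped[conf, , drop = FALSE]
    if (n_nonredundant(g) < min_support) next
    # confirmed: drop any error recorded against this call
    errors <- errors[is.na(errors$gene_id) | errors$gene_id != cl$gene_id[j], ,
                     drop = FALSE]
    if (cl$is_pseudogene[j]) {
      errors <- rbind(errors, data.frame(
        category = "missed", caller_id = calls$caller_id,
        replicon_id = cl$replicon_id[j], strand = cl$strand[j],
        gene_id = cl$gene_id[j],
        implied_start = cl$start[j], implied_end = cl$end[j],
        frame = fj$frame[1L], n_nonredundant = n_nonredundant(g),
        peptide_ids = collapse_ids(g), stringsAsFactors = FALSE))
    }
  }
  errors <- errors[order(errors$category, errors$replicon_id,
                         errors$implied_start), , drop = FALSE]
  rownames(errors) <- NULL
  errors
}

#' Joint false-identification probability of k independent peptides
#'
#' The probability that `k` independent supporting peptides are all false
#' identifications, under the product rule: `per_peptide_fdr ^ k`.  With the
#' per-peptide FDR of 0.003 and the two-peptide evidence requirement this is
#' 9e-06.
#'
#' @param per_peptide_fdr Per-peptide false discovery rate in `[0, 1]`.
#' @param k Number of independent peptides (>= 1).
#' @return Probability that all `k` are false.
#' @export
joint_false_rate <- function(per_peptide_fdr, k) {
  if (!is.numeric(per_peptide_fdr) || any(per_peptide_fdr < 0) ||
      any(per_peptide_fdr > 1))
    stop("per_peptide_fdr must be in [0, 1]")
  if (!is.numeric(k) || any(k < 1) || any(k != floor(k)))
    stop("k must be an integer >= 1")
  per_peptide_fdr ^ k
}

#' Tally error calls by caller, replicon and/or category
#'
#' @param errors data.frame of error calls (possibly from several callers,
#'   row-bound).
#' @param group_by Character vector among "caller", "replicon", "category".
#' @return data.frame of counts with one row per observed group combination
#'   and a column `n`.  The sum of `n` equals `nrow(errors)`.
#' @export
tally_errors <- function(errors, group_by = c("caller", "category")) {
  cols <- c(caller = "caller_id", replicon = "replicon_id",
            category = "category")
  if (!all(group_by %in% names(cols)))
    stop("group_by must be among: ", paste(names(cols), collapse = ", "))
  sel <- unname(cols[group_by])
  if (nrow(errors) == 0L) {
    out <- stats::setNames(
      as.data.frame(matrix(character(), ncol = length(sel)),
                    stringsAsFactors = FALSE), sel)
    out$n <- integer()
    return(out)
  }
  out <- stats::aggregate(list(n = seq_len(nrow(errors))),
                          by = errors[, sel, drop = FALSE], FUN = length)
  out <- out[do.call(order, out[, sel, drop = FALSE]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
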