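# Consensus and disagreement statistics between gene-call sets.

call_key <- function(calls)
  paste(calls$replicon_id, calls$strand, calls$start, calls$end, sep = "\r")

# 3'-terminal coordinate on the coding strand ("stop" key).
stop_key <- function(calls)
  paste(calls$replicon_id, calls$strand,
        ifelse(calls$strand == "+", calls$end, calls$start), sep = "\r")

#' Identical gene calls between two callers
#'
#' Two calls coincide only if replicon, strand, start and stop are all
#' equal.  Each call is matched at most once (sets cannot hold duplicate
#' coordinates, so matching is one-to-one).
#'
#' @param a,b `gene_call_set` objects.
#' @return data.frame of matched pairs: `gene_id_a`, `gene_id_b`,
#'   `replicon_id`, `strand`, `start`, `end`.
#' @export
identical_genes <- function(a, b) {
  ka <- call_key(a$calls); kb <- call_key(b$calls)
  i <- match(ka, kb)
  hit <- which(!is.na(i))
  data.frame(gene_id_a = a$calls$gene_id[hit],
             gene_id_b = b$calls$gene_id[i[hit]],
             replicon_id = a$calls$replicon_id[hit],
             strand = a$calls$strand[hit],
             start = a$calls$start[hit], end = a$calls$end[hit],
             stringsAsFactors = FALSE)
}

#' Gene calls agreeing on the stop but not the start
#'
#' Pairs of calls sharing replicon, strand and the 3'-terminal coordinate on
#' the coding strand (the `end` boundary for '+' calls, the `start` boundary
#' for '-' calls) whose 5' starts differ.  Disjoint from
#' [identical_genes()].  When a caller emits several calls with the same
#' stop (rare), each call is paired at most once, in coordinate order.
#'
#' @param a,b `gene_call_set` objects.
#' @return data.frame of matched pairs: `gene_id_a`, `gene_id_b`,
#'   `replicon_id`, `strand`, `stop3p`.
#' @export
stop_agree_genes <- function(a, b) {
  ca <- a$calls[order(call_key(a$calls)), , drop = FALSE]
  cb <- b$calls[order(call_key(b$calls)), , drop = FALSE]
  sa <- stop_key(ca); sb <- stop_key(cb)
  full_a <- call_key(ca); full_b <- call_key(cb)
  out <- list()
  used_b <- rep(FALSE, nrow(cb))
  for (i in seq_len(nrow(ca))) {
    j <- which(sb == sa[i] & !used_b & full_b != full_a[i])
    if (length(j)) {
      j <- j[1L]
      used_b[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        gene_id_a = ca$gene_id[i], gene_id_b = cb$gene_id[j],
        replicon_id = ca$replicon_id[i], strand = ca$strand[i],
        stop3p = if (ca$strand[i] == "+") ca$end[i] else ca$start[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id_a = character(), gene_id_b = character(),
                      replicon_id = character(), strand = character(),
                      stop3p = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Consensus summary across two or more gene-call sets
#'
#' Computes, for every caller pair, the number of identical calls (same
#' replicon, strand, start and stop) and of stop-consensus calls (same stop,
#' different start); the all-way identical and all-way stop-consensus
#' counts; and each caller's unique calls (identical to a call in no other
#' set).  Percentages are reported under each caller's own total as the
#' denominator.
#'
#' @param sets List of 2 or more `gene_call_set` objects with distinct
#'   caller ids.
#' @return Object of class `consensus_summary`: list with `caller_ids`,
#'   `n_calls` (named), `n_identical_all`, `n_stop_agree_all` (stop shared
#'   by all callers, starts not all equal), `pct_identical_all` (named, per
#'   caller denominator), `pairwise` (data.frame `caller_a`, `caller_b`,
#'   `n_identical`, `n_stop_agree`, `pct_identical_of_a`,
#'   `pct_identical_of_b`), `n_unique` and `pct_unique` (named).
#' @export
consensus_summary <- function(sets) {
  if (length(sets) < 2L) stop("need at least two gene_call_sets")
  ids <- vapply(sets, function(s) s$caller_id, "")
  if (anyDuplicated(ids)) stop("duplicate caller_ids")
  names(sets) <- ids
  n_calls <- vapply(sets, n_calls, 0L)
  keys <- lapply(sets, function(s) call_key(s$calls))
  skeys <- lapply(sets, function(s) stop_key(s$calls))

  all_ident_keys <- Reduce(intersect, keys)
  n_identical_all <- length(all_ident_keys)
  # stops present in every set where starts do not all coincide
  all_stop_keys <- Reduce(intersect, skeys)
  n_stop_agree_all <- 0L
  for (sk in all_stop_keys) {
    full <- vapply(seq_along(sets), function(m) {
      j <- which(skeys[[m]] == sk)[1L]
      keys[[m]][j]
    }, "")
    if (length(unique(full)) > 1L) n_stop_agree_all <- n_stop_agree_all + 1L
  }

  pw <- list()
  cmb <- utils::combn(length(sets), 2L)
  for (c1 in seq_len(ncol(cmb))) {
    i <- cmb[1L, c1]; j <- cmb[2L, c1]
    ni <- nrow(identical_genes(sets[[i]], sets[[j]]))
    ns <- nrow(stop_agree_genes(sets[[i]], sets[[j]]))
    pw[[c1]] <- data.frame(
      caller_a = ids[i], caller_b = ids[j],
      n_identical = ni, n_stop_agree = ns,
      pct_identical_of_a = pct(ni, n_calls[i]),
      pct_identical_of_b = pct(ni, n_calls[j]),
      stringsAsFactors = FALSE)
  }
  pw <- do.call(rbind, pw)

  n_unique <- vapply(seq_along(sets), function(i) {
    others <- unlist(keys[-i], use.names = FALSE)
    sum(!(keys[[i]] %in% others))
  }, 0L)
  names(n_unique) <- ids

  structure(list(
    caller_ids = ids,
    n_calls = n_calls,
    n_identical_all = n_identical_all,
    n_stop_agree_all = n_stop_agree_all,
    pct_identical_all = pct(n_identical_all, n_calls),
    pairwise = pw,
    n_unique = n_unique,
    pct_unique = pct(n_unique, n_calls)
  ), class = "consensus_summary")
}

pct <- function(num, den) ifelse(den > 0, 100 * num / den, 0)

#' @export
print.consensus_summary <- function(x, ...) {
  cat(sprintf("consensus_summary over %d callers: %s\n",
              length(x$caller_ids), paste(x$caller_ids, collapse = ", ")))
  cat(sprintf("  calls per caller: %s\n",
              paste(sprintf("%s=%d", names(x$n_calls), x$n_calls),
                    collapse = ", ")))
  cat(sprintf("  identical in all: %d (%s%% of each caller)\n",
              x$n_identical_all,
              paste(sprintf("%.1f", x$pct_identical_all), collapse = "/")))
  cat(sprintf("  stop-consensus (start varies) in all: %d\n",
              x$n_stop_agree_all))
  cat(sprintf("  unique calls: %s\n",
              paste(sprintf("%s=%d", names(x$n_unique), x$n_unique),
                    collapse = ", ")))
  invisible(x)
}
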