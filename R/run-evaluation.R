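# End-to-end evaluation driver and dataset-bias report.

#' Run the full proteogenomic evaluation
#'
#' Executes the whole pipeline: map peptides onto the genome by exact unique
#' six-frame match, then per caller compute peptide support and coverage,
#' conflicts, wrong/short/missed error classification and pseudogene
#' re-scoring; compute the consensus summary across callers (when two or
#' more are given) and the error tallies.  Optionally writes all report
#' tables, conflict GFF3 tracks and a machine-readable JSON summary under
#' `out_dir`.
#'
#' @param genome Genome: a `DNAStringSet`, named character vector, or a
#'   FASTA path.
#' @param calls A `gene_call_set`, a list of them, or a named character
#'   vector of GFF3 paths (names become caller ids).
#' @param peptides data.frame (`peptide_id`, `aa_seq`, optional precomputed
#'   coordinates) or a TSV/GFF path.
#' @param min_support Minimum non-redundant peptides per error call
#'   (default 2).
#' @param per_peptide_fdr Per-peptide false identification rate used for
#'   the joint false-positive arithmetic in the summary (default 0.003).
#' @param out_dir Optional output directory for report files.
#' @return List of class `evaluation_result`: `mapping` (report list),
#'   `mapped` (data.frame), `support` (named list of support summaries),
#'   `conflicts` (named list), `errors` (one data.frame, all callers),
#'   `tally` (caller x category counts), `consensus` (or NULL for a single
#'   caller), `joint_false_rate` (product-rule probability at
#'   `min_support` peptides), `params`.
#' @export
run_evaluation <- function(genome, calls, peptides, min_support = 2L,
                           per_peptide_fdr = 0.003, out_dir = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome(genome)
  genome <- as_genome(genome)
  if (inherits(calls, "gene_call_set")) calls <- list(calls)
  if (is.character(calls)) {
    if (is.null(names(calls))) stop("GFF paths must be named by caller id")
    calls <- lapply(names(calls), function(nm) read_gene_calls(calls[[nm]], nm))
  }
  if (is.character(peptides)) peptides <- read_peptides(peptides)
  names(calls) <- vapply(calls, function(s) s$caller_id, "")
  if (anyDuplicated(names(calls))) stop("duplicate caller ids")

  idx <- six_frame_index(genome)
  mp <- map_peptides(peptides, idx)

  support <- list(); conflicts <- list(); errors <- list()
  for (nm in names(calls)) {
    support[[nm]] <- peptide_support(mp$mapped, calls[[nm]], idx)
    conflicts[[nm]] <- find_conflicts(mp$mapped, calls[[nm]], idx)
    e <- classify_errors(conflicts[[nm]], calls[[nm]], idx, min_support)
    errors[[nm]] <- rescore_pseudogenes(e, calls[[nm]], mp$mapped, idx,
                                        min_support)
  }
  all_errors <- do.call(rbind, c(errors, list(empty_errors())))
  rownames(all_errors) <- NULL
  consensus <- if (length(calls) >= 2L) consensus_summary(calls) else NULL
  res <- structure(list(
    mapping = mp$report, mapped = mp$mapped, discarded = mp$discarded,
    support = support, conflicts = conflicts, errors = all_errors,
    tally = tally_errors(all_errors, c("caller", "category")),
    consensus = consensus,
    joint_false_rate = joint_false_rate(per_peptide_fdr, min_support),
    params = list(min_support = min_support,
                  per_peptide_fdr = per_peptide_fdr,
                  callers = names(calls))
  ), class = "evaluation_result")
  if (!is.null(out_dir)) write_evaluation(res, out_dir)
  res
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result: %d callers, %d/%d peptides mapped\n",
              length(x$support), x$mapping$n_mapped, x$mapping$n_input))
  for (s in x$support)
    cat(sprintf("  %s: %d supporting / %d conflicting; coverage %.1f%%\n",
                s$caller_id, s$n_supporting_peptides,
                s$n_conflicting_peptides, s$coverage_percent))
  if (nrow(x$tally)) {
    cat("  errors:\n")
    for (i in seq_len(nrow(x$tally)))
      cat(sprintf("    %s %s: %d\n", x$tally$caller_id[i],
                  x$tally$category[i], x$tally$n[i]))
  } else cat("  errors: none\n")
  invisible(x)
}

write_evaluation <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$mapped, file.path(out_dir, "mapped_peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$errors, file.path(out_dir, "errors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$tally, file.path(out_dir, "error_tally.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(res$conflicts))
    write_conflict_gff(res$conflicts[[nm]],
                       file.path(out_dir, paste0("conflicts_", nm, ".gff3")))
  summ <- list(
    mapping = res$mapping,
    support = lapply(res$support, unclass),
    tally = res$tally,
    joint_false_rate = res$joint_false_rate,
    params = res$params
  )
  if (!is.null(res$consensus)) {
    cs <- res$consensus
    summ$consensus <- list(
      caller_ids = cs$caller_ids, n_calls = as.list(cs$n_calls),
      n_identical_all = cs$n_identical_all,
      n_stop_agree_all = cs$n_stop_agree_all,
      pct_identical_all = as.list(cs$pct_identical_all),
      pairwise = cs$pairwise, n_unique = as.list(cs$n_unique),
      pct_unique = as.list(cs$pct_unique))
  }
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Dataset bias report: genome length and peptide depth versus GC
#'
#' Reports, per replicon, GC percent, length (in Mbp) and the number of
#' mapped peptides, together with Spearman rank correlations of length vs
#' GC and peptide count vs GC.  A correlation over a constant margin (zero
#' variance in either variable) is reported as 0.
#'
#' @param genome Genome (`DNAStringSet`, named character vector, or a
#'   data.frame from [replicon_info()]).
#' @param n_peptides Named integer vector of mapped-peptide counts per
#'   replicon (missing replicons count 0).
#' @return List of class `bias_report`: `table` (per-replicon data.frame)
#'   and `correlations` (named vector `length_vs_gc`, `peptides_vs_gc`).
#' @export
bias_report <- function(genome, n_peptides) {
  info <- if (is.data.frame(genome)) genome else replicon_info(genome)
  if (nrow(info) < 2L) stop("need at least two replicons")
  tab <- data.frame(
    replicon_id = info$replicon_id,
    gc_percent = info$gc_percent,
    length_mbp = info$length / 1e6,
    n_peptides = as.integer(ifelse(is.na(match(info$replicon_id,
                                               names(n_peptides))), 0L,
                                   n_peptides[info$replicon_id])),
    stringsAsFactors = FALSE)
  rho <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y, method = "spearman")
  }
  structure(list(
    table = tab,
    correlations = c(length_vs_gc = rho(tab$length_mbp, tab$gc_percent),
                     peptides_vs_gc = rho(tab$n_peptides, tab$gc_percent))
  ), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("bias_report over %d replicons\n", nrow(x$table)))
  cat(sprintf("  Spearman length vs GC: %.3f; peptides vs GC: %.3f\n",
              x$correlations[["length_vs_gc"]],
              x$correlations[["peptides_vs_gc"]]))
  invisible(x)
}
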