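# A poly-GCA replicon has no stop codon in any of the six frames, which
# makes ORF extensions unbounded and lets tests place features freely.
gca_genome <- function(n = 600L) as_genome(c(r = strrep("GCA", n %/% 3L)))

mk_call <- function(id, start, end, strand = "+", pseudo = FALSE,
                    fragments = NULL) {
  df <- data.frame(gene_id = id, replicon_id = "r", strand = strand,
                   start = start, end = end, is_pseudogene = pseudo,
                   stringsAsFactors = FALSE)
  if (!is.null(fragments)) df$fragments <- I(list(fragments))
  df
}

mk_pep <- function(id, start, end, strand = "+", L = 600L) {
  data.frame(peptide_id = id, aa_seq = strrep("A", (end - start) %/% 3L),
             replicon_id = "r", strand = strand, start = start, end = end,
             frame = frame_of(start, end, strand, L), stringsAsFactors = FALSE)
}

empty_errors_df <- function() progeval:::empty_errors()

empty_call_set <- function() gene_call_set(
  data.frame(gene_id = character(), replicon_id = character(),
             strand = character(), start = integer(), end = integer(),
             is_pseudogene = logical(), stringsAsFactors = FALSE), "empty")

test_that("support requires containment plus strand and frame agreement", {
  g <- gca_genome()
  calls <- gene_call_set(mk_call("g1", 0L, 300L), "c1")
  inside <- mk_pep("p1", 90L, 120L)
  sup <- peptide_support(inside, calls, g)
  expect_equal(sup$n_supporting_peptides, 1L)
  expect_equal(sup$coverage_percent, 100)
  # wholly inside but on the other strand: a conflict, not support
  wrong_strand <- mk_pep("p2", 90L, 120L, strand = "-")
  sup2 <- peptide_support(wrong_strand, calls, g)
  expect_equal(sup2$n_supporting_peptides, 0L)
  expect_equal(sup2$n_conflicting_peptides, 1L)
  # wholly inside but shifted out of frame: also a conflict
  off_frame <- mk_pep("p3", 91L, 121L)
  expect_equal(peptide_support(off_frame, calls, g)$n_supporting_peptides, 0L)
  # empty call set: zero genes, everything conflicts
  sup0 <- peptide_support(inside, empty_call_set(), g)
  expect_equal(sup0$n_genes_total, 0L)
  expect_equal(sup0$n_conflicting_peptides, 1L)
})

test_that("supporting plus conflicting partitions the mapped peptides", {
  sim <- simulate_replicon(sim_params(genome_length = 30000, n_genes = 20,
                                      seed = 61))
  pert <- perturb_calls(sim$truth,
                        error_profile("c", p_miss_gene = 0.2,
                                      p_start_truncate = 0.2,
                                      p_wrong_frame = 0.1),
                        sim$genome, seed = 62)
  pep <- sample_peptides(sim$truth, sim$genome,
                         detection_params(1, 0.8, c(6L, 50L), 0.003),
                         seed = 63)
  mapped <- map_peptides(pep$peptides, sim$genome)$mapped
  sup <- peptide_support(mapped, pert$calls, sim$genome)
  conf <- find_conflicts(mapped, pert$calls, sim$genome)
  expect_equal(sup$n_supporting_peptides + sup$n_conflicting_peptides,
               nrow(mapped))
  expect_equal(nrow(conf), sup$n_conflicting_peptides)
})

test_that("conflict relations are labelled by geometry and frame", {
  g <- gca_genome(6000L)
  calls <- gene_call_set(mk_call("g1", 99L, 399L), "c1")  # frame 0
  # overlapping, frame-shifted by 1
  oof <- mk_pep("p1", 130L, 160L, L = 6000L)
  # in frame, starting 5' of the call start
  up <- mk_pep("p2", 69L, 129L, L = 6000L)
  # in frame, running past the 3' end
  span <- mk_pep("p3", 390L, 420L, L = 6000L)
  # far from every call
  out <- mk_pep("p4", 5000L, 5030L, L = 6000L)
  mapped <- rbind(oof, up, span, out)
  mapped$start <- as.integer(mapped$start); mapped$end <- as.integer(mapped$end)
  conf <- find_conflicts(mapped, calls, g)
  expect_equal(nrow(conf), 4L)
  rel <- setNames(conf$relation, conf$peptide_id)
  expect_equal(rel[["p1"]], "overlaps_out_of_frame")
  expect_equal(rel[["p2"]], "extends_upstream")
  expect_equal(rel[["p3"]], "spans_boundary")
  expect_equal(rel[["p4"]], "outside_all")
  expect_equal(conf$nearest_gene_id[conf$peptide_id == "p2"], "g1")
  expect_true(is.na(conf$nearest_gene_id[conf$peptide_id == "p4"]))
})

test_that("two upstream in-frame peptides score a short call with the implied start", {
  g <- gca_genome(6000L)
  calls <- gene_call_set(mk_call("g1", 99L, 399L), "c1")
  # peptide starts must share frame 0 with the call: 69 and 84 are %% 3 == 0
  mapped <- rbind(mk_pep("p1", 69L, 129L, L = 6000L),
                  mk_pep("p2", 84L, 114L, L = 6000L))
  conf <- find_conflicts(mapped, calls, g)
  err <- classify_errors(conf, calls, g, min_support = 2L)
  expect_equal(nrow(err), 1L)
  expect_equal(err$category, "short")
  expect_equal(err$gene_id, "g1")
  expect_equal(err$implied_start, 69L)
  expect_equal(err$implied_end, 399L)
  expect_equal(err$n_nonredundant, 2L)
  # a single upstream peptide is below the evidence threshold
  err1 <- classify_errors(find_conflicts(mapped[1, ], calls, g), calls, g, 2L)
  expect_equal(nrow(err1), 0L)
  expect_error(classify_errors(conf, calls, g, min_support = 0L),
               "min_support")
})

test_that("a short call is not scored across an in-frame upstream stop", {
  # genome with a frame-0 stop (TAA) immediately 5' of the call start
  s <- paste0(strrep("GCA", 30), "TAA", strrep("GCA", 170))
  g <- as_genome(c(r = s))
  calls <- gene_call_set(mk_call("g1", 99L, 399L), "c1")
  mapped <- rbind(mk_pep("p1", 60L, 90L), mk_pep("p2", 63L, 90L))
  mapped$frame <- frame_of(mapped$start, mapped$end, "+", 603L)
  # both peptides are 5' of the stop at [90, 93): cannot extend the gene
  conf <- find_conflicts(mapped, calls, g)
  err <- classify_errors(conf, calls, g, 2L)
  expect_equal(nrow(err[err$category == "short", ]), 0L)
})

test_that("out-of-frame peptide groups score a wrong call", {
  g <- gca_genome(6000L)
  calls <- gene_call_set(mk_call("g1", 99L, 399L), "c1")
  mapped <- rbind(mk_pep("w1", 130L, 160L, L = 6000L),
                  mk_pep("w2", 250L, 280L, L = 6000L))
  conf <- find_conflicts(mapped, calls, g)
  err <- classify_errors(conf, calls, g, 2L)
  expect_equal(err$category, "wrong")
  expect_equal(err$gene_id, "g1")
  expect_equal(err$n_nonredundant, 2L)
  # peptides in two different frames do not combine into one wrong call
  mixed <- rbind(mk_pep("w1", 130L, 160L, L = 6000L),
                 mk_pep("w2", 251L, 281L, L = 6000L))
  err2 <- classify_errors(find_conflicts(mixed, calls, g), calls, g, 2L)
  expect_equal(nrow(err2), 0L)
})

test_that("outside-all peptide groups in a call-free ORF score a missed gene", {
  g <- gca_genome(6000L)
  calls <- gene_call_set(mk_call("g1", 99L, 399L), "c1")
  # frame 1 peptides: the frame-0 whole-genome ORF of poly-GCA contains the
  # call, so frame-0 peptides could never imply a call-free missed gene here
  mapped <- rbind(mk_pep("m1", 4501L, 4531L, L = 6000L),
                  mk_pep("m2", 4561L, 4591L, L = 6000L))
  conf <- find_conflicts(mapped, calls, g)
  err <- classify_errors(conf, calls, g, 2L)
  expect_equal(err$category, "missed")
  expect_true(is.na(err$gene_id))
  # implied interval is the maximal ORF containing the peptides
  expect_lte(err$implied_start, 4501L)
  expect_gte(err$implied_end, 4591L)
  # non-redundancy: the same interval twice is one peptide of evidence
  dup <- rbind(mk_pep("m1", 4501L, 4531L, L = 6000L),
               mk_pep("m1b", 4501L, 4531L, L = 6000L))
  err0 <- classify_errors(find_conflicts(dup, calls, g), calls, g, 2L)
  expect_equal(nrow(err0), 0L)
})

test_that("no peptide feeds two error calls of different categories", {
  sim <- simulate_replicon(sim_params(genome_length = 50000, n_genes = 40,
                                      seed = 71))
  pert <- perturb_calls(sim$truth,
                        error_profile("c", n_miss_gene = 5L,
                                      n_start_truncate = 5L,
                                      n_wrong_frame = 5L),
                        sim$genome, seed = 72)
  pep <- sample_peptides(sim$truth, sim$genome,
                         detection_params(1, 1, c(6L, 50L), 0), seed = 73)
  mapped <- map_peptides(pep$peptides, sim$genome)$mapped
  conf <- find_conflicts(mapped, pert$calls, sim$genome)
  err <- classify_errors(conf, pert$calls, sim$genome, 2L)
  ids <- strsplit(err$peptide_ids, ",")
  cat_of <- rep(err$category, lengths(ids))
  tab <- table(unlist(ids), cat_of)
  expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("pseudogene calls with confirming peptides are re-scored as missed", {
  g <- gca_genome(6000L)
  frags <- data.frame(start = c(99L, 255L), end = c(249L, 399L))
  pseudo <- gene_call_set(mk_call("ps1", 99L, 399L, pseudo = TRUE,
                                  fragments = frags), "c1")
  mapped <- rbind(mk_pep("c1p", 102L, 132L, L = 6000L),   # inside fragment 1
                  mk_pep("c2p", 258L, 288L, L = 6000L))   # inside fragment 2
  err <- rescore_pseudogenes(empty_errors_df(), pseudo, mapped, g, 2L)
  expect_equal(err$category, "missed")
  expect_equal(err$gene_id, "ps1")
  expect_equal(c(err$implied_start, err$implied_end), c(99L, 399L))
  # a single confirming peptide is below threshold
  err1 <- rescore_pseudogenes(empty_errors_df(), pseudo, mapped[1, ], g, 2L)
  expect_equal(nrow(err1), 0L)
})

test_that("untagged frameshifted calls with confirming peptides are good calls", {
  g <- gca_genome(6000L)
  frags <- data.frame(start = c(99L, 255L), end = c(249L, 399L))
  fs <- gene_call_set(mk_call("fs1", 99L, 399L, pseudo = FALSE,
                              fragments = frags), "c1")
  mapped <- rbind(mk_pep("c1p", 102L, 132L, L = 6000L),
                  mk_pep("c2p", 258L, 288L, L = 6000L))
  # a stray error recorded against the call is withdrawn on confirmation
  stray <- data.frame(category = "wrong", caller_id = "c1", replicon_id = "r",
                      strand = "+", gene_id = "fs1", implied_start = 99L,
                      implied_end = 399L, frame = 0L, n_nonredundant = 2L,
                      peptide_ids = "x1,x2", stringsAsFactors = FALSE)
  err <- rescore_pseudogenes(stray, fs, mapped, g, 2L)
  expect_equal(nrow(err), 0L)
})

test_that("joint false rate follows the product rule", {
  expect_equal(joint_false_rate(0.003, 1), 0.003)
  # two-peptide requirement: 9e-06, well under the 0.09 % bound
  expect_equal(joint_false_rate(0.003, 2), 9e-06)
  expect_lte(joint_false_rate(0.003, 2), 0.0009)
  expect_equal(joint_false_rate(0, 5), 0)
  expect_equal(joint_false_rate(1, 5), 1)
  expect_error(joint_false_rate(1.2, 2), "per_peptide_fdr")
  expect_error(joint_false_rate(0.3, 0), "k must be")
})

test_that("error tallies are marginally consistent", {
  err <- rbind(
    data.frame(category = c("wrong", "short", "missed", "wrong"),
               caller_id = c("a", "a", "b", "b"),
               replicon_id = "r", strand = "+", gene_id = NA_character_,
               implied_start = 0L, implied_end = 3L, frame = 0L,
               n_nonredundant = 2L, peptide_ids = "p", stringsAsFactors = FALSE))
  by_cat <- tally_errors(err, "category")
  by_caller <- tally_errors(err, "caller")
  expect_equal(sum(by_cat$n), nrow(err))
  expect_equal(sum(by_caller$n), nrow(err))
  expect_equal(tally_errors(err[0, ], "category")$n, integer())
  expect_error(tally_errors(err, "flavour"), "group_by")
})
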