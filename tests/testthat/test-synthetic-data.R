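test_that("simulated replicons honour their structural guarantees", {
  sim <- simulate_replicon(sim_params(genome_length = 100000, n_genes = 80,
                                      gc_percent = 57.7, seed = 8))
  info <- replicon_info(sim$genome)
  expect_equal(info$length, 100000L)
  # realized GC within 2 points of target at 100 kb
  expect_lt(abs(info$gc_percent - 57.7), 2)
  # every truth gene is re-found as (part of) a maximal ORF in its frame
  orfs <- find_orfs(sim$genome, 39)
  cl <- sim$truth$calls
  L <- info$length
  for (i in seq_len(nrow(cl))) {
    body <- if (cl$strand[i] == "+") c(cl$start[i], cl$end[i] - 3L)
            else c(cl$start[i] + 3L, cl$end[i])
    f <- frame_of(cl$start[i], cl$end[i], cl$strand[i], L)
    expect_true(any(orfs$strand == cl$strand[i] & orfs$frame == f &
                      orfs$start <= body[1] & orfs$end >= body[2]),
                info = cl$gene_id[i])
  }
  # genes do not overlap
  o <- order(cl$start)
  expect_true(all(cl$start[o][-1] >= cl$end[o][-nrow(cl)]))
})

test_that("n_genes = 0 yields pure intergenic sequence and an empty truth set", {
  sim <- simulate_replicon(sim_params(genome_length = 5000, n_genes = 0,
                                      seed = 2))
  expect_equal(n_calls(sim$truth), 0L)
  expect_equal(replicon_info(sim$genome)$length, 5000L)
})

test_that("infeasible packing is rejected with advice", {
  expect_error(sim_params(genome_length = 10000, n_genes = 100,
                          gene_length_mean = 900), "n_genes")
})

test_that("tryptic digest cleaves after K/R but not before P", {
  # K followed by P is protected; R followed by T is cut
  d <- tryptic_peptides("MKPARTTK")
  expect_equal(d$seq, c("MKPAR", "TTK"))
  expect_equal(d$aa_start, c(1L, 6L))
  expect_equal(d$aa_end, c(5L, 8L))
  # an unprotected K site cuts normally
  expect_equal(tryptic_peptides("MKAPRTTK")$seq, c("MK", "APR", "TTK"))
  # length filter
  d2 <- tryptic_peptides("MKPARTTK", len_range = c(4L, 50L))
  expect_equal(d2$seq, "MKPAR")
  # terminal K keeps the last peptide intact; no zero-length peptides
  expect_equal(tryptic_peptides("AAKR")$seq, c("AAK", "R"))
})

test_that("saturating detection covers every gene", {
  sim <- simulate_replicon(sim_params(genome_length = 30000, n_genes = 20,
                                      seed = 5))
  pep <- sample_peptides(sim$truth, sim$genome,
                         detection_params(1, 1, c(6L, 50L), 0), seed = 6)
  expect_setequal(unique(pep$ledger$gene_id), sim$truth$calls$gene_id)
  mapped <- map_peptides(pep$peptides, sim$genome)$mapped
  sup <- peptide_support(mapped, sim$truth, sim$genome)
  expect_equal(sup$coverage_percent, 100)
})

test_that("gene detection frequency matches its closed form at defaults", {
  sim <- simulate_replicon(sim_params(genome_length = 220000, n_genes = 200,
                                      seed = 15))
  det <- detection_params(p_gene_expressed = 0.4, p_peptide_detected = 0.5,
                          false_match_rate = 0)
  pep <- sample_peptides(sim$truth, sim$genome, det, seed = 16)
  covered <- length(unique(pep$ledger$gene_id))
  # per-gene detection probability: expressed and >= 1 of its n peptides seen
  npep <- vapply(seq_len(n_calls(sim$truth)), function(i) {
    cl <- sim$truth$calls[i, ]
    prot <- progeval:::gene_protein(sim$genome, cl$replicon_id, cl$strand,
                                    cl$start, cl$end)
    nrow(tryptic_peptides(prot, det$peptide_len_range))
  }, 0L)
  p_detect <- det$p_gene_expressed * (1 - (1 - det$p_peptide_detected) ^ npep)
  mu <- sum(p_detect)
  sigma <- sqrt(sum(p_detect * (1 - p_detect)))
  expect_lt(abs(covered - mu), 3 * sigma + 1)
})

test_that("false peptides are planted at the stated rate and map uniquely", {
  sim <- simulate_replicon(sim_params(genome_length = 120000, n_genes = 100,
                                      seed = 25))
  det <- detection_params(1, 1, c(6L, 50L), false_match_rate = 0.02)
  pep <- sample_peptides(sim$truth, sim$genome, det, seed = 26)
  n_true <- sum(!pep$ledger$is_false)
  n_false <- sum(pep$ledger$is_false)
  expect_gt(n_false, 0)
  expect_lt(abs(n_false - 0.02 * n_true),
            3 * sqrt(n_true * 0.02 * 0.98) + 1)
  res <- map_peptides(pep$peptides, sim$genome)
  r <- res$report
  expect_equal(r$n_mapped + r$n_ambiguous_discarded + r$n_unmatched, r$n_input)
  # every false peptide maps uniquely, at its recorded locus
  m <- merge(res$mapped, pep$ledger[pep$ledger$is_false, ], by = "peptide_id",
             suffixes = c("", ".t"))
  expect_equal(nrow(m), n_false)
  expect_true(all(m$start == m$start.t & m$end == m$end.t))
})

test_that("perturbation with zero probabilities is the identity", {
  sim <- simulate_replicon(sim_params(genome_length = 20000, n_genes = 15,
                                      seed = 33))
  pert <- perturb_calls(sim$truth, error_profile("c"), sim$genome, seed = 34)
  expect_equal(nrow(pert$ledger), 0L)
  expect_equal(nrow(identical_genes(pert$calls, sim$truth)),
               n_calls(sim$truth))
})

test_that("p_miss_gene = 1 deletes every call and ledgers every gene as missed", {
  sim <- simulate_replicon(sim_params(genome_length = 20000, n_genes = 15,
                                      seed = 43))
  pert <- perturb_calls(sim$truth, error_profile("c", p_miss_gene = 1),
                        sim$genome, seed = 44)
  expect_equal(n_calls(pert$calls), 0L)
  expect_equal(nrow(pert$ledger), 15L)
  expect_true(all(pert$ledger$expected_category == "missed"))
})

test_that("exact-count planting yields the requested events, all detectable", {
  sim <- simulate_replicon(sim_params(genome_length = 100000, n_genes = 80,
                                      seed = 53))
  pert <- perturb_calls(sim$truth,
                        error_profile("c", n_miss_gene = 10L,
                                      n_start_truncate = 10L,
                                      n_wrong_frame = 10L,
                                      n_pseudogene_split = 3L),
                        sim$genome, seed = 54)
  tab <- table(pert$ledger$event)
  expect_equal(unname(tab[c("miss", "truncate", "wrong_frame",
                            "pseudo_split")]),
               array(c(10L, 10L, 10L, 3L)))
  expect_true(all(pert$ledger$detectable))
  # planted short calls really are start-truncations in the original frame
  sh <- pert$ledger[pert$ledger$event == "truncate", ]
  L <- replicon_info(sim$genome)$length
  expect_true(all(frame_of(sh$new_start, sh$new_end, sh$strand, L) ==
                    frame_of(sh$orig_start, sh$orig_end, sh$strand, L)))
  expect_true(all(ifelse(sh$strand == "+", sh$new_start - sh$orig_start,
                         sh$orig_end - sh$new_end) >= 9L))
})

test_that("identical-call fraction between two perturbed callers matches (1-p)^2", {
  sim <- simulate_replicon(sim_params(genome_length = 220000, n_genes = 200,
                                      seed = 63))
  prof <- function(id) error_profile(id, p_miss_gene = 0.1,
                                     p_start_truncate = 0.1,
                                     p_wrong_frame = 0.05)
  a <- perturb_calls(sim$truth, prof("a"), sim$genome, seed = 64)$calls
  b <- perturb_calls(sim$truth, prof("b"), sim$genome, seed = 65)$calls
  n <- n_calls(sim$truth)
  frac <- nrow(identical_genes(a, b)) / n
  p_keep <- 1 - 0.25
  expect_lt(abs(frac - p_keep^2), 3 * sqrt(p_keep^2 * (1 - p_keep^2) / n))
})

test_that("benchmark bundles are deterministic and reloadable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  args <- list(params = sim_params(genome_length = 20000, n_genes = 15),
               profiles = list(error_profile("c", p_miss_gene = 0.2)),
               det = detection_params(1, 1, c(6L, 50L), 0))
  b1 <- do.call(make_benchmark, c(list(dir = d1), args, seed = 9))
  b2 <- do.call(make_benchmark, c(list(dir = d2), args, seed = 9))
  b3 <- do.call(make_benchmark, c(list(dir = d3), args, seed = 10))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_false(identical(readLines(file.path(d1, "genome.fasta")),
                         readLines(file.path(d3, "genome.fasta"))))
  # bundle loads back through the I/O layer without warnings
  expect_no_warning({
    g <- read_genome(b1$paths$genome)
    calls <- read_gene_calls(b1$paths$calls[["c"]], "c")
    peps <- read_peptides(b1$paths$peptides)
  })
  expect_equal(n_calls(calls), n_calls(b1$calls$c))
  expect_equal(nrow(peps), nrow(b1$peptides))
  expect_equal(as.character(g), as.character(b1$genome))
})
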