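test_that("the doubled ancestor conserves pairs and duplicates chromosomes", {
  anc <- make_doubled_ancestor(num_pairs = 57, num_chromosomes = 5, seed = 1)
  expect_identical(nrow(anc$genome), 2L * 57L)
  expect_identical(nrow(anc$pmap$pairs), 57L)
  expect_identical(anc$pmap$m, 0L)
  chroms <- unique(anc$genome$chromosome)
  expect_identical(length(chroms), 10L)            # every chromosome doubled
  expect_true(all(table(anc$genome$chromosome) >= 1L))
  # strands identical within a pair
  strand <- stats::setNames(anc$genome$strand, anc$genome$gene_id)
  expect_true(all(strand[anc$pmap$pairs$gene_a] ==
                    strand[anc$pmap$pairs$gene_b]))
})

test_that("reduction removes exactly m pairs and conserves the rest", {
  anc <- make_doubled_ancestor(300, 4, seed = 2)
  red <- simulate_reduction(anc$genome, anc$pmap, m = 120, mu = 1.5,
                            seed = 3)
  expect_identical(nrow(red$genome), 2L * 300L - 120L)
  expect_identical(red$pmap$m, 120L)
  expect_identical(nrow(red$pmap$pairs), 300L - 120L)
  # every deletion event names genes that are gone, survivors that remain
  del <- unlist(lapply(red$events, `[[`, "genes"))
  expect_identical(length(del), 120L)
  expect_false(any(del %in% red$genome$gene_id))
  surv <- unlist(lapply(red$events, `[[`, "survivors"))
  expect_true(all(surv %in% red$genome$gene_id))
  expect_error(simulate_reduction(red$genome, red$pmap, m = 200),
               "exceeds")
})

test_that("mu = 1 deletes one gene at a time", {
  anc <- make_doubled_ancestor(100, 2, seed = 4)
  red <- simulate_reduction(anc$genome, anc$pmap, m = 80, mu = 1, seed = 5)
  expect_true(all(vapply(red$events, `[[`, 1L, "length") == 1L))
  expect_true(all(vapply(red$events, `[[`, 1L, "length_drawn") == 1L))
})

test_that("drawn run lengths have the configured geometric mean", {
  anc <- make_doubled_ancestor(12000, 8, seed = 6)
  red <- simulate_reduction(anc$genome, anc$pmap, m = 10000, mu = 2,
                            seed = 7)
  drawn <- vapply(red$events, `[[`, 1L, "length_drawn")
  se <- stats::sd(drawn) / sqrt(length(drawn))
  expect_lt(abs(mean(drawn) - 2), 3 * se)
})

test_that("rearrangements permute but never create or destroy genes", {
  anc <- make_doubled_ancestor(80, 3, seed = 8)
  rr <- apply_rearrangements(anc$genome, d = 40, seed = 9)
  expect_setequal(rr$genome$gene_id, anc$genome$gene_id)
  expect_identical(length(rr$events), 40L)
  # d = 0 leaves the genome untouched
  expect_identical(
    as.data.frame(apply_rearrangements(anc$genome, 0, seed = 1)$genome),
    as.data.frame(anc$genome)
  )
})

test_that("inverting the same interval twice restores the genome", {
  anc <- make_doubled_ancestor(50, 2, seed = 10)
  set.seed(31)
  for (i in 1:10) {
    chrom <- sample(unique(anc$genome$chromosome), 1)
    len <- sum(anc$genome$chromosome == chrom)
    ij <- sort(sample.int(len, 2, replace = TRUE))
    ev <- list(type = "inversion", chrom = chrom, start = ij[1], end = ij[2])
    twice <- replay_events(anc$genome, list(ev, ev))
    expect_identical(as.data.frame(twice), as.data.frame(anc$genome))
  }
})

test_that("translocations on a single chromosome fall back to inversions", {
  anc <- make_doubled_ancestor(30, 1, seed = 12)
  # merge the two chromosome copies into one via state: simplest is a genome
  # with a single chromosome built by hand
  g <- genome_table(data.frame(
    chromosome = "c1", rank = 0:19, gene_id = sprintf("g%02d", 1:20),
    strand = 1L
  ))
  rr <- apply_rearrangements(g, d = 10, inversion_fraction = 0, seed = 13)
  expect_identical(length(rr$events), 10L)
  expect_true(all(vapply(rr$events, `[[`, "", "type") == "inversion"))
  expect_true(all(vapply(rr$events, `[[`, TRUE, "fallback")))
})

test_that("a descendant is deterministic and replayable from its log", {
  cfg <- simulation_config(num_pairs = 250, m = 180, d = 30, mu = 1.6,
                           num_chromosomes = 3, seed = 77)
  s1 <- simulate_descendant(cfg)
  s2 <- simulate_descendant(cfg)
  expect_identical(as.data.frame(s1$genome), as.data.frame(s2$genome))
  expect_identical(s1$pmap$pairs, s2$pmap$pairs)
  expect_identical(s1$events, s2$events)
  # replay the event log from the ancestor: bit-for-bit identical
  replayed <- replay_events(s1$ancestor$genome, s1$events)
  expect_identical(as.data.frame(replayed), as.data.frame(s1$genome))
  # conservation under the matched-(n, m) convention
  expect_identical(nrow(s1$genome), 2L * 250L - 180L)
  expect_identical(s1$pmap$m, 180L)
})

test_that("full retention bias puts every survivor on chromosome copy A", {
  anc <- make_doubled_ancestor(200, 4, seed = 14)
  red <- simulate_reduction(anc$genome, anc$pmap, m = 150,
                            retention_bias = 1, seed = 15)
  singles <- setdiff(red$genome$gene_id, names(red$pmap$partner))
  expect_true(all(grepl("A$", singles)))
  # and unbiased retention splits survivors roughly evenly
  red2 <- simulate_reduction(anc$genome, anc$pmap, m = 150,
                             retention_bias = 0.5, seed = 16)
  singles2 <- setdiff(red2$genome$gene_id, names(red2$pmap$partner))
  frac_a <- mean(grepl("A$", singles2))
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / 150) + 1e-9)
})

test_that("hit-table fixtures plant recoverable WGD pairs and singletons", {
  fx <- make_hit_table_fixture(48, seed = 20)
  kept <- bracket_filter(bitscore_filter(fx$self, 140),
                         rbind(fx$lower1, fx$lower2),
                         rbind(fx$upper1, fx$upper2))
  pairs <- best_reciprocal_hits(hit_table(kept))
  expect_identical(pairs, fx$truth$pairs)
  # decoys die at the stated filter
  young <- fx$truth$decoy_pairs[1, ]
  expect_false(any(kept$query_gene %in% c(young$gene_a, young$gene_b)))
  old <- fx$truth$decoy_pairs[2, ]
  after_bracket <- bracket_filter(fx$self, rbind(fx$lower1, fx$lower2),
                                  rbind(fx$upper1, fx$upper2))
  expect_true(any(after_bracket$query_gene %in% old$gene_a))   # survives bracket
  expect_false(any(bitscore_filter(after_bracket)$query_gene %in% old$gene_a))
  # verified singletons: support in one genome of each clade
  singles <- setdiff(sprintf("g%03d", 1:48),
                     c(fx$truth$pairs$gene_a, fx$truth$pairs$gene_b,
                       unlist(fx$truth$decoy_pairs)))
  expect_identical(verify_singletons(singles, fx$lower1, fx$upper1),
                   fx$truth$verified_singletons)
})

test_that("the deletion-run experiment reports sizes the pseudo-real has", {
  res <- run_deletion_length_experiment(mu = 2, reps = 8, num_pairs = 600,
                                        m = 520, d = 25, seed = 55)
  expect_identical(res$mu, 2)
  expect_s3_class(res$comparison, "diagonal_comparison")
  real_sizes <- unique(res$comparison$points$s)
  expect_true(all(as.integer(names(res$prop_offdiag)) %in% real_sizes))
  expect_true(all(res$prop_all >= 0 & res$prop_all <= 1))
})
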