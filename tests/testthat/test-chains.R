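test_that("a planted perfect-LD block is recovered as exactly one chain", {
  set.seed(11)
  blk <- make_block_geno(100, n_block = 25, gap = 3)
  co <- make_cohort(blk$geno)
  tab <- distance_table(co, window = 10)
  chains <- find_chains(tab, co, threshold = 0.0015, min_snps = 20,
                        gap_max = 9)
  expect_equal(nrow(chains), 1)
  expect_equal(chains$members[[1]], blk$members)
  expect_equal(chains$n_snps, 25L)
  # agrees with the exhaustive oracle
  orc <- oracle_chains(blk$geno, 0.0015, 20, 9)
  expect_equal(length(orc), 1)
  expect_equal(chains$members[[1]], orc[[1]])
})

test_that("blocks below the minimum SNP count yield no chain", {
  set.seed(12)
  blk <- make_block_geno(100, n_block = 19, gap = 2)
  co <- make_cohort(blk$geno)
  chains <- find_chains(distance_table(co), co, min_snps = 20)
  expect_equal(nrow(chains), 0)
})

test_that("two distant planted blocks give two disjoint chains", {
  set.seed(13)
  b1 <- make_block_geno(80, n_block = 22, gap = 2, p_block = 0.3)
  b2 <- make_block_geno(80, n_block = 24, gap = 2, p_block = 0.6)
  g <- cbind(b1$geno, b2$geno)
  pos <- c(seq_len(ncol(b1$geno)) * 500L,
           1000000L + seq_len(ncol(b2$geno)) * 500L)
  co <- make_cohort(g, pos = pos)
  chains <- find_chains(distance_table(co), co)
  expect_equal(nrow(chains), 2)
  expect_equal(chains$members[[1]], b1$members)
  expect_equal(chains$members[[2]], ncol(b1$geno) + b2$members)
  expect_length(intersect(chains$members[[1]], chains$members[[2]]), 0)
})

test_that("reported chains satisfy the chain definition verbatim", {
  set.seed(14)
  blk <- make_block_geno(60, n_block = 30, gap = 5)
  co <- make_cohort(blk$geno)
  chains <- find_chains(distance_table(co), co)
  for (r in seq_len(nrow(chains))) {
    expect_true(validate_chain(chains$members[[r]], blk$geno,
                               0.0015, 20, 9))
  }
})

test_that("search equals brute force on random small instances", {
  set.seed(15)
  for (rep in 1:30) {
    n_sub <- sample(20:60, 1)
    base <- vapply(1:8, function(i) rbinom(n_sub, 2, runif(1, 0.2, 0.8)),
                   integer(n_sub))
    # random instances built by duplicating random base columns so that
    # qualifying pairs and chains actually occur
    g <- base[, sample(8, sample(15:40, 1), replace = TRUE), drop = FALSE]
    co <- make_cohort(g)
    min_snps <- sample(3:6, 1)
    gap_max <- sample(2:9, 1)
    chains <- find_chains(distance_table(co, window = gap_max + 1), co,
                          threshold = 0.0015, min_snps = min_snps,
                          gap_max = gap_max)
    orc <- oracle_chains(g, 0.0015, min_snps, gap_max)
    expect_equal(unname(chains$members), orc)
  }
})

test_that("excluded-region overlap discards chains, span semantics", {
  set.seed(16)
  blk <- make_block_geno(50, n_block = 20, gap = 1)
  co <- make_cohort(blk$geno)
  chains <- find_chains(distance_table(co), co)
  expect_equal(nrow(chains), 1)
  span <- c(chains$start, chains$end)

  # fully covering region
  reg_cover <- tibble::tibble(chrom = "1", start = span[1] - 1000L,
                              end = span[2] + 1000L)
  res <- apply_exclusions(chains, reg_cover, co, lead_call_min = 1)
  expect_false(res$kept)
  expect_equal(res$discard_reason, "alt_scaffold")

  # 1 bp overlap at the right edge: half-open region starting at end-1
  reg_edge <- tibble::tibble(chrom = "1", start = span[2] - 1L, end = span[2])
  expect_false(apply_exclusions(chains, reg_edge, co, lead_call_min = 1)$kept)

  # region beyond the span, and region on another chromosome: kept
  reg_out <- tibble::tibble(chrom = "1", start = span[2], end = span[2] + 10L)
  expect_true(apply_exclusions(chains, reg_out, co, lead_call_min = 1)$kept)
  reg_chr <- tibble::tibble(chrom = "2", start = span[1], end = span[2])
  expect_true(apply_exclusions(chains, reg_chr, co, lead_call_min = 1)$kept)
})

test_that("low lead-SNP callability discards at the printed boundary", {
  set.seed(17)
  blk <- make_block_geno(2504, n_block = 20, gap = 0, flank = 2)
  g <- blk$geno
  lead <- blk$members[1]
  g[sample(2504, 2504 - 1999), lead] <- NA # lead called in exactly 1999
  co <- make_cohort(g)
  chains <- find_chains(distance_table(co), co)
  expect_equal(nrow(chains), 1)
  expect_equal(co$variants$n_called[chains$lead_index], 1999L)
  res <- apply_exclusions(chains, NULL, co, lead_call_min = 2000)
  expect_false(res$kept)
  expect_equal(res$discard_reason, "low_call")
  expect_true(apply_exclusions(chains, NULL, co, lead_call_min = 1999)$kept)
})
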