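# Helper: a one-chain fixture over n SNPs with explicit outgroup states.
ancestry_fixture <- function(chimp_alt, neand_alt, chrom = "1",
                             third_allele_at = integer(0),
                             uncalled_at = integer(0)) {
  m <- length(chimp_alt)
  g <- matrix(rep(rbinom(30, 2, 0.5), m), ncol = m)
  co <- make_cohort(g, chrom = chrom)
  v <- co$variants
  chains <- tibble::tibble(
    chain_id = "c1", chrom = chrom, start = v$pos[1], end = v$pos[m],
    lead_index = 1L, lead_id = v$id[1], n_snps = m,
    span = v$pos[m] - v$pos[1], members = list(seq_len(m))
  )
  chimp <- ifelse(chimp_alt, v$alt, v$ref)
  neand <- ifelse(neand_alt, v$alt, v$ref)
  chimp[third_allele_at] <- "T" # matches neither ref (A) nor alt (G)
  chimp[uncalled_at] <- "."
  og <- tibble::tibble(chrom = v$chrom, pos = v$pos,
                       chimp_allele = chimp, neanderthal_allele = neand)
  list(chains = chains, cohort = co, outgroups = og)
}

test_that("canonical outgroup configurations map to their classes", {
  set.seed(61)
  # chimp all alternate, Neanderthal all reference: both haplotypes ancient
  fx <- ancestry_fixture(rep(TRUE, 20), rep(FALSE, 20))
  expect_equal(classify_ancestry(fx$chains, fx$cohort, fx$outgroups)$class,
               "ancient")
  # both outgroups reference everywhere: alternate haplotype human-derived
  fx <- ancestry_fixture(rep(FALSE, 20), rep(FALSE, 20))
  expect_equal(classify_ancestry(fx$chains, fx$cohort, fx$outgroups)$class,
               "derived")
  # both outgroups alternate everywhere: also derived (reference haplotype)
  fx <- ancestry_fixture(rep(TRUE, 20), rep(TRUE, 20))
  expect_equal(classify_ancestry(fx$chains, fx$cohort, fx$outgroups)$class,
               "derived")
  # one discordant site in each direction among concordant ones: mixed
  chimp <- c(TRUE, FALSE, rep(TRUE, 8))
  neand <- c(FALSE, TRUE, rep(TRUE, 8))
  fx <- ancestry_fixture(chimp, neand)
  expect_equal(classify_ancestry(fx$chains, fx$cohort, fx$outgroups)$class,
               "mixed")
  # subset configuration: partial
  fx <- ancestry_fixture(rep(FALSE, 10), c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(classify_ancestry(fx$chains, fx$cohort, fx$outgroups)$class,
               "partial")
})

test_that("fewer than five informative sites is uninformative", {
  set.seed(62)
  fx <- ancestry_fixture(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(classify_ancestry(fx$chains, fx$cohort, fx$outgroups)$class,
               "uninformative")
  # 20 sites but only 4 informative after uncalled/third-allele masking
  fx <- ancestry_fixture(rep(TRUE, 20), rep(FALSE, 20),
                         third_allele_at = 1:8, uncalled_at = 9:16)
  res <- classify_ancestry(fx$chains, fx$cohort, fx$outgroups)
  expect_equal(res$n_informative, 4L)
  expect_equal(res$class, "uninformative")
})

test_that("X-chromosome chains are skipped with a reason", {
  set.seed(63)
  fx <- ancestry_fixture(rep(TRUE, 20), rep(FALSE, 20), chrom = "X")
  res <- classify_ancestry(fx$chains, fx$cohort, fx$outgroups)
  expect_true(is.na(res$class))
  expect_equal(res$skip_reason, "non_autosomal")
})

test_that("classes are exclusive, exhaustive and outgroup-symmetric", {
  classes <- c("derived", "ancient", "partial", "mixed", "uninformative")
  set.seed(64)
  for (rep in 1:300) {
    counts <- as.vector(stats::rmultinom(1, sample(0:30, 1), rep(1 / 4, 4)))
    cls <- yinyangscan:::ancestry_class(counts[1], counts[2], counts[3],
                                        counts[4])
    expect_true(cls %in% classes)
    # swapping the chimpanzee and Neanderthal labels swaps the two
    # single-outgroup categories and must preserve these classes
    swapped <- yinyangscan:::ancestry_class(counts[1], counts[3], counts[2],
                                            counts[4])
    if (cls %in% c("derived", "ancient", "mixed", "uninformative")) {
      expect_equal(swapped, cls)
    }
  }
})

test_that("planted outgroup classes are recovered in a closed loop", {
  sim <- simulate_cohort(small_scenario_config(seed = 65))
  og <- simulate_outgroups(sim)
  co <- filter_maf(sim$cohort, 0.1)
  chains <- find_chains(distance_table(co), co)
  res <- classify_ancestry(chains, co, og)
  yy <- sim$truth[sim$truth$type == "yinyang", ]
  for (r in seq_len(nrow(yy))) {
    got <- res$class[chains$start == yy$start[r]]
    expect_equal(got, yy$outgroup_class[r])
  }
})
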