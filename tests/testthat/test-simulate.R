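test_that("the generator is deterministic given its seed", {
  a <- simulate_cohort(small_scenario_config(seed = 31))
  b <- simulate_cohort(small_scenario_config(seed = 31))
  expect_identical(a$cohort$geno, b$cohort$geno)
  expect_identical(a$cohort$dp, b$cohort$dp)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(small_scenario_config(seed = 32))
  expect_false(identical(a$cohort$geno, c$cohort$geno))
  expect_identical(simulate_outgroups(a), simulate_outgroups(b))
})

test_that("planted pairs are exclusive: constant dosage across the pair", {
  cfg <- scenario_config(
    n_per_superpop = c(AFR = 40, AMR = 40, EAS = 40, EUR = 40, SAS = 40),
    pairs = pair_row(25L, 100000L, 15000L, 0.3),
    repeats = no_repeats(),
    common_density = 1e-5, singleton_density = 0, doubleton_density = 0,
    seed = 33
  )
  sim <- simulate_cohort(cfg)
  mem <- sim$members
  idx <- match(mem$pos, sim$cohort$variants$pos)
  g <- sim$cohort$geno[, idx, drop = FALSE]
  # every subject's dosage vector across the planted SNPs is constant
  expect_true(all(apply(g, 1, function(x) length(unique(x)) == 1)))
})

test_that("truth table and genotype matrix are mutually consistent", {
  sim <- simulate_cohort(small_scenario_config(seed = 34))
  for (lid in sim$truth$locus_id) {
    mem <- sim$members[sim$members$locus_id == lid, ]
    idx <- match(paste(mem$chrom, mem$pos),
                 paste(sim$cohort$variants$chrom, sim$cohort$variants$pos))
    expect_equal(unname(sim$cohort$geno[, idx, drop = FALSE]),
                 unname(sim$dosage_truth[[lid]]))
  }
})

test_that("a full-heterozygote repeat locus is heterozygous in everyone", {
  cfg <- scenario_config(
    n_per_superpop = c(EUR = 60), n_children = 0,
    pairs = no_pairs("EUR"),
    repeats = tibble::tibble(
      n_snps = 20L, start = 500000L, span = 10000L, het_fraction = 1,
      aa_fraction = 0, depth_mean = 74.3, depth_sd = 34.6,
      ab_mean = 0.5, ab_sd = 0.11
    ),
    common_density = 1e-5, singleton_density = 0, doubleton_density = 0,
    seed = 35
  )
  sim <- simulate_cohort(cfg)
  idx <- match(sim$members$pos, sim$cohort$variants$pos)
  expect_true(all(sim$cohort$geno[, idx] == 1L))
})

test_that("planted allele frequencies land inside binomial bounds", {
  cfg <- scenario_config(
    n_per_superpop = c(AFR = 400, AMR = 400, EAS = 400, EUR = 400, SAS = 400),
    n_children = 0,
    pairs = pair_row(20L, 100000L, 15000L, 0.3),
    repeats = no_repeats(),
    common_density = 1e-5, singleton_density = 0, doubleton_density = 0,
    seed = 36
  )
  sim <- simulate_cohort(cfg)
  idx <- match(sim$members$pos, sim$cohort$variants$pos)
  n_chrom <- 2 * 2000
  bounds <- qbinom(c(0.005, 0.995), n_chrom, 0.3) / n_chrom
  af <- colSums(sim$cohort$geno[, idx, drop = FALSE]) / n_chrom
  expect_true(all(af >= bounds[1] & af <= bounds[2]))
})

test_that("overlapping planted spans are rejected", {
  expect_error(
    scenario_config(pairs = pair_row(20L, 295000L, 20000L, 0.3)),
    "disjoint"
  )
})

test_that("outgroup tables realise each configured class", {
  sim <- simulate_cohort(small_scenario_config(seed = 37))
  og <- simulate_outgroups(sim)
  yy <- sim$truth[sim$truth$type == "yinyang", ]
  for (lid in yy$locus_id) {
    mem <- sim$members[sim$members$locus_id == lid, ]
    o <- og[match(mem$pos, og$pos), ]
    chimp_alt <- o$chimp_allele == mem$alt
    neand_alt <- o$neanderthal_allele == mem$alt
    cls <- yy$outgroup_class[yy$locus_id == lid]
    if (cls == "derived") {
      expect_true(all(chimp_alt == neand_alt) &&
                    (all(chimp_alt) || all(!chimp_alt)))
    } else if (cls == "ancient") {
      expect_true((all(chimp_alt) && all(!neand_alt)) ||
                    (all(!chimp_alt) && all(neand_alt)))
    } else if (cls == "partial") {
      k <- sum(chimp_alt) + sum(neand_alt)
      expect_true(k > 0 && k < nrow(mem)) # strict non-empty subset
    } else if (cls == "mixed") {
      expect_true(any(chimp_alt & !neand_alt) && any(!chimp_alt & neand_alt))
    }
  }
})

test_that("scenario files round-trip through the standard formats", {
  sim <- simulate_cohort(small_scenario_config(seed = 38))
  dir <- withr::local_tempdir()
  write_scenario(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("cohort.vcf", "panel.tsv", "truth.tsv", "truth_members.tsv",
           "outgroups.tsv", "config.txt")
  ))))
  pan <- read_panel(file.path(dir, "panel.tsv"))
  back <- read_cohort_vcf(file.path(dir, "cohort.vcf"), pan)
  expect_equal(unname(back$geno), unname(sim$cohort$geno))
  og <- read_outgroup_table(file.path(dir, "outgroups.tsv"))
  expect_equal(nrow(og), sum(sim$truth$n_snps[sim$truth$type == "yinyang"]))
  expect_true(any(grepl("^seed = 38$", readLines(file.path(dir, "config.txt")))))
})
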