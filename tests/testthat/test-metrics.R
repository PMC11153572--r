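test_that("fixation index: closed-form cases", {
  expect_equal(fst(rep(0.3, 5), rep(100, 5)), 0)
  expect_equal(fst(c(0, 1), c(1, 1)), 1)
  expect_true(is.na(fst(c(0, 0), c(1, 1)))) # pooled frequency 0: undefined
  expect_error(fst(0.5, 1), "length")
})

test_that("fixation index matches an independent implementation", {
  set.seed(51)
  for (rep in 1:1000) {
    k <- sample(2:6, 1)
    p <- runif(k)
    w <- runif(k, 10, 1000)
    got <- fst(p, w)
    exp <- oracle_fst(p, w)
    if (is.na(exp)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, exp, tolerance = 1e-12)
      expect_gte(got, 0)
      expect_lte(got, 1)
    }
  }
})

test_that("genetic length: constant map rate is returned exactly", {
  chains <- tibble::tibble(chain_id = "c1", chrom = "1", start = 100000L,
                           end = 150000L, span = 50000L)
  map <- tibble::tibble(chrom = "1", start = 0L, end = 1000000L, rate = 2.5)
  out <- genetic_length(chains, map)
  expect_equal(out$cM_per_Mb, 2.5)
  expect_equal(out$cM, 2.5 * 0.05)
})

test_that("genetic length pro-rates across intervals and is additive", {
  chains <- tibble::tibble(chain_id = "c1", chrom = "1", start = 1000L,
                           end = 9000L, span = 8000L)
  map <- tibble::tibble(chrom = "1", start = c(0L, 5000L),
                        end = c(5000L, 20000L), rate = c(1, 10))
  out <- genetic_length(chains, map)
  # hand computation: 4000 bp at 1 cM/Mb + 4000 bp at 10 cM/Mb
  expect_equal(out$cM, 4000 / 1e6 * 1 + 4000 / 1e6 * 10)

  # additivity: split at an arbitrary interior point
  split_at <- 6321L
  parts <- tibble::tibble(chain_id = c("a", "b"), chrom = "1",
                          start = c(1000L, split_at),
                          end = c(split_at, 9000L),
                          span = c(split_at - 1000L, 9000L - split_at))
  got <- genetic_length(parts, map)
  expect_equal(sum(got$cM), out$cM)

  # unmapped chromosome
  chains2 <- tibble::tibble(chain_id = "c2", chrom = "9", start = 1000L,
                            end = 2000L, span = 1000L)
  expect_true(is.na(genetic_length(chains2, map)$cM))
})

test_that("the high-recombination worked example reproduces its rate", {
  # span 19:9129001-9133768; the documented hotspot interval inside it has
  # rate 41.23 cM/Mb, the remainder a low rate chosen so the map totals the
  # published genetic length of 0.1126 cM
  chain <- tibble::tibble(chain_id = "c1", chrom = "19", start = 9129001L,
                          end = 9133768L, span = 9133768L - 9129001L)
  hot_ov <- 9133768 - 9131156
  low_rate <- (0.1126 - 41.23 * hot_ov / 1e6) / ((9131156 - 9129001) / 1e6)
  map <- tibble::tibble(chrom = "19",
                        start = c(9129001L, 9131156L),
                        end = c(9131156L, 9136013L),
                        rate = c(low_rate, 41.23))
  out <- genetic_length(chain, map)
  expect_equal(out$cM, 0.1126, tolerance = 1e-9)
  expect_equal(round(out$cM_per_Mb, 2), 23.62)
})

test_that("control SNPs match on MAF, avoid chains and are reproducible", {
  set.seed(52)
  # 30 variants; a chain covering indices 5..14; candidates elsewhere
  g <- vapply(1:30, function(i) rbinom(100, 2, 0.5), integer(100))
  maf_target <- sum(g[, 5]) / 200
  maf_target <- min(maf_target, 1 - maf_target)
  co <- make_cohort(g)
  chains <- tibble::tibble(
    chain_id = "c1", chrom = "1", start = co$variants$pos[5],
    end = co$variants$pos[14], lead_index = 5L, lead_id = "v5",
    n_snps = 10L, span = co$variants$pos[14] - co$variants$pos[5],
    members = list(5:14)
  )
  ctrl <- match_control_snps(chains, co, tol = 1, seed = 9)
  expect_false(ctrl$control_index %in% 5:14)
  # nearest-MAF among eligible variants
  elig <- setdiff(1:30, 5:14)
  expect_equal(abs(ctrl$control_maf - maf_target),
               min(abs(co$variants$maf[elig] - maf_target)))
  # seed contract
  ctrl2 <- match_control_snps(chains, co, tol = 1, seed = 9)
  expect_identical(ctrl, ctrl2)
  # tolerance can rule out every candidate
  none <- match_control_snps(chains, co, tol = 0, seed = 9)
  if (!any(abs(co$variants$maf[elig] - maf_target) == 0)) {
    expect_true(is.na(none$control_index))
  }
})

test_that("an equal-MAF candidate inside another chain is rejected", {
  n <- 60
  lead_col <- c(rep(1L, 18), rep(0L, 42))     # MAF 0.15
  twin_col <- rev(lead_col)                   # exactly equal MAF
  near_col <- c(rep(1L, 20), rep(0L, 40))     # MAF ~0.167, nearest outside
  far_col <- c(rep(1L, 48), rep(0L, 12))      # MAF 0.4
  g <- cbind(lead_col, far_col, twin_col, near_col)
  co <- make_cohort(g, pos = c(1000L, 2000L, 3000L, 4000L))
  chains <- tibble::tibble(
    chain_id = c("c1", "c2"), chrom = "1",
    start = c(1000L, 2500L), end = c(1500L, 3500L),
    lead_index = c(1L, 3L), lead_id = c("v1", "v3"),
    n_snps = c(1L, 1L), span = c(500L, 1000L), members = list(1L, 3L)
  )
  ctrl <- match_control_snps(chains, co, tol = 1, seed = 3)
  # for chain c1 the equal-MAF twin sits inside chain c2's span, so the
  # next-nearest-MAF variant outside all chains must be chosen
  expect_equal(ctrl$control_index[1], 4L)
})

test_that("background densities follow direct arithmetic on a fixture", {
  # 1229 AFR + 503 EUR subjects; 10 singletons carried by AFR inside a
  # 1 Mb chain; genome 2 Mb
  n_afr <- 1229
  n_eur <- 503
  n <- n_afr + n_eur
  superpop <- c(rep("AFR", n_afr), rep("EUR", n_eur))
  inside_pos <- as.integer(seq(1000, 900000, length.out = 12))
  outside_pos <- as.integer(seq(1100000, 1900000, length.out = 3))
  g <- matrix(0L, nrow = n, ncol = 15)
  for (j in 1:10) g[j, j] <- 1L # singletons in AFR subjects, inside
  g[, 11] <- rep(c(0L, 1L), length.out = n) # common site inside
  g[1:2, 12] <- 1L                          # doubleton in AFR, inside
  g[, 13] <- 2L                             # alt-fixed site outside
  g[n, 14] <- 1L                            # singleton in EUR, outside
  g[, 15] <- rep(c(0L, 1L, 2L, 1L), length.out = n)
  co <- make_cohort(g, pos = c(inside_pos, outside_pos), superpop = superpop)
  chains <- tibble::tibble(chain_id = "c1", chrom = "1",
                           start = 1L, end = 1000000L, span = 999999L)
  bg <- background_stats(chains, co, genome_size = 2e6)
  afr <- bg[bg$superpop == "AFR", ]
  eur <- bg[bg$superpop == "EUR", ]
  expect_equal(afr$singleton_inside, 10 / 1 / n_afr)
  expect_equal(eur$singleton_inside, 0)
  expect_equal(afr$doubleton_inside, 1 / 1 / n_afr)
  expect_equal(eur$singleton_outside, 1 / 1 / n_eur)
  expect_equal(afr$singleton_outside, 0)
})

test_that("one balanced variant contributes 0.5 heterozygosity per Mb", {
  n <- 40
  g <- cbind(rep(c(0L, 2L), n / 2), rbinom(n, 2, 0.4))
  co <- make_cohort(g, pos = c(500000L, 1500000L))
  chains <- tibble::tibble(chain_id = "c1", chrom = "1",
                           start = 1L, end = 1000000L, span = 999999L)
  bg <- background_stats(chains, co, genome_size = 2e6)
  # inside span: single variant at MAF 0.5 -> 2 * 0.5 * 0.5 = 0.5 per Mb
  expect_equal(bg$het_inside, rep(0.5, nrow(bg)))
})
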