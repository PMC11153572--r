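# Seeded synthetic cohorts: planted exclusive yin-yang pairs with
# population-stratified frequencies, optional leaked intermediate
# (recombinant) haplotypes, repeat-artifact loci with heterozygote-dominated
# calls and inflated depth, and a background of common SNPs plus
# singleton/doubleton rare variants. Everything the downstream stages
# consume can be generated here, so the whole pipeline is testable without
# any external download.

#' Describe a synthetic cohort scenario
#'
#' Builds the configuration consumed by [simulate_cohort()]. The defaults
#' describe a desk-scale study: 500 unrelated subjects split evenly over five
#' superpopulations on a 2 Mb chromosome, five planted exclusive yin-yang
#' pairs spanning the observed range of differentiation (one pair strongly
#' stratified between superpopulations), three repeat-artifact loci covering
#' the three artifact signatures (all-heterozygous; heterozygote excess with
#' a missing homozygote class; few minor homozygotes with inflated depth),
#' and background variation with realistic common-SNP and singleton/doubleton
#' densities.
#'
#' @param n_per_superpop Named integer vector of unrelated subjects per
#'   superpopulation.
#' @param n_children Number of additional child subjects (flagged in the
#'   panel; excluded from analyses other than depth summaries).
#' @param chrom Chromosome name used for all simulated sites.
#' @param chrom_length Chromosome length in bp.
#' @param pairs Tibble describing planted yin-yang pairs: columns `n_snps`,
#'   `start`, `span`, one `freq_<SUPERPOP>` column per superpopulation
#'   (alternate-haplotype frequency), `n_intermediates` (leaked recombinant
#'   chromosome copies) and `outgroup_class` in
#'   `c("derived", "ancient", "partial", "mixed")`.
#' @param repeats Tibble describing repeat-artifact loci: columns `n_snps`,
#'   `start`, `span`, `het_fraction`, `aa_fraction`, `depth_mean`,
#'   `depth_sd`, `ab_mean`, `ab_sd`.
#' @param common_density Background common SNPs per bp (uniform MAF in
#'   `common_maf_range`).
#' @param common_maf_range Range of background common-SNP allele frequencies.
#' @param singleton_density,doubleton_density Rare-variant densities in
#'   variants per Mb per unrelated subject.
#' @param clean_depth_mean,clean_depth_sd Read-depth distribution (negative
#'   binomial) at non-repeat sites.
#' @param clean_ab_sd Allele-balance standard deviation of true heterozygote
#'   calls (mean 0.5).
#' @param seed Integer seed; with the seed fixed the generator is
#'   byte-reproducible.
#' @return A list of class `yy_scenario_config`.
#' @export
scenario_config <- function(
    n_per_superpop = c(AFR = 100, AMR = 100, EAS = 100, EUR = 100, SAS = 100),
    n_children = 10,
    chrom = "1",
    chrom_length = 2e6,
    pairs = default_pairs(names(n_per_superpop)),
    repeats = default_repeats(),
    common_density = 5e-4,
    common_maf_range = c(0.1, 0.5),
    singleton_density = 4,
    doubleton_density = 1.5,
    clean_depth_mean = 33.9,
    clean_depth_sd = 10.8,
    clean_ab_sd = 0.03,
    seed = 1L) {
  if (is.null(names(n_per_superpop)) || any(!nzchar(names(n_per_superpop)))) {
    abort("n_per_superpop must be a named vector")
  }
  pairs <- as_tibble(pairs)
  repeats <- as_tibble(repeats)
  freq_cols <- paste0("freq_", names(n_per_superpop))
  if (nrow(pairs) && !all(freq_cols %in% names(pairs))) {
    abort(paste("pairs must carry columns:", paste(freq_cols, collapse = ", ")))
  }
  fr <- if (nrow(pairs)) unlist(pairs[freq_cols]) else numeric()
  if (length(fr) && (any(fr < 0) || any(fr > 1))) {
    abort("planted haplotype frequencies must lie in [0, 1]")
  }
  spans <- bind_rows(
    if (nrow(pairs)) select(pairs, all_of(c("start", "span"))),
    if (nrow(repeats)) select(repeats, all_of(c("start", "span")))
  )
  if (!is.null(spans) && nrow(spans) > 1) {
    spans <- arrange(spans, .data$start)
    if (any(spans$start[-1] <= (spans$start + spans$span)[-nrow(spans)])) {
      abort("planted spans must be disjoint")
    }
  }
  structure(
    list(
      n_per_superpop = n_per_superpop, n_children = n_children,
      chrom = chrom, chrom_length = chrom_length,
      pairs = pairs, repeats = repeats,
      common_density = common_density, common_maf_range = common_maf_range,
      singleton_density = singleton_density,
      doubleton_density = doubleton_density,
      clean_depth_mean = clean_depth_mean, clean_depth_sd = clean_depth_sd,
      clean_ab_sd = clean_ab_sd,
      seed = as.integer(seed)
    ),
    class = "yy_scenario_config"
  )
}

# Five planted pairs: sizes around the observed mean (about 35 SNPs over
# about 16 kb), one pair strongly stratified between superpopulations, one
# near-balanced, the rest intermediate. Outgroup classes cover all four
# ancestry configurations (one class repeated).
default_pairs <- function(superpops) {
  base <- tibble(
    n_snps = c(25L, 30L, 20L, 40L, 22L),
    start = c(100000L, 500000L, 900000L, 1300000L, 1700000L),
    span = c(15000L, 18000L, 12000L, 25000L, 14000L),
    n_intermediates = 0L,
    outgroup_class = c("derived", "ancient", "partial", "mixed", "derived")
  )
  freqs <- rbind(
    rep(0.30, length(superpops)),
    c(0.70, rep(0.20, length(superpops) - 1)), # AFR-divergent
    rep(0.50, length(superpops)),
    seq(0.15, 0.45, length.out = length(superpops)),
    rep(0.25, length(superpops))
  )
  colnames(freqs) <- paste0("freq_", superpops)
  bind_cols(base, as_tibble(freqs))
}

# Three repeat-artifact signatures: fully heterozygous; heterozygote excess
# with essentially no minor homozygotes; moderate heterozygosity but too few
# AA homozygotes together with inflated depth. Depth and allele-balance
# parameters follow the contrast reported between artifact and clean lead
# SNPs (depth mean 74.3 sd 34.6 vs 33.9 sd 10.8; heterozygote allele balance
# sd 0.11 vs 0.03).
default_repeats <- function() {
  tibble(
    n_snps = c(22L, 24L, 21L),
    start = c(300000L, 700000L, 1100000L),
    span = c(12000L, 13000L, 11000L),
    het_fraction = c(1.0, 0.92, 0.50),
    aa_fraction = c(0.0, 0.0, 0.03),
    depth_mean = 74.3,
    depth_sd = 34.6,
    ab_mean = 0.5,
    ab_sd = 0.11
  )
}

#' Simulate a cohort with planted yin-yang pairs
#'
#' Draws an unphased diploid cohort from a [scenario_config()]. At each
#' planted pair every chromosome copy is independently the all-alternate or
#' all-reference haplotype with the subject's superpopulation frequency
#' (Hardy-Weinberg in expectation); leaked intermediates replace single
#' chromosome copies with one-breakpoint recombinants. Repeat-artifact loci
#' emit heterozygote-dominated calls with read depth and allele balance drawn
#' from their configured distributions. Background common SNPs are
#' Hardy-Weinberg draws at uniform frequencies and singletons/doubletons are
#' placed uniformly.
#'
#' @param config A [scenario_config()].
#' @return A list of class `yy_scenario` with elements `cohort` (a
#'   [yy_cohort()] with AD/DP matrices), `truth` (tibble of planted loci:
#'   `locus_id`, `type` yinyang/repeat, coordinates, `n_snps`,
#'   `outgroup_class`, frequency columns), `members` (tibble of planted SNP
#'   positions with `locus_id`, `chrom`, `pos`, `id`, `ref`, `alt`),
#'   `dosage_truth` (named list: per locus the subjects-by-SNPs planted
#'   dosage matrix) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "yy_scenario_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  sp_names <- names(config$n_per_superpop)
  n_unrel <- sum(config$n_per_superpop)
  n_all <- n_unrel + config$n_children

  panel <- tibble(
    subject = sprintf("S%04d", seq_len(n_all)),
    superpop = c(rep(sp_names, times = config$n_per_superpop),
                 sample(sp_names, config$n_children, replace = TRUE)),
    child = c(rep(FALSE, n_unrel), rep(TRUE, config$n_children))
  )
  panel$pop <- paste0(panel$superpop, "1")
  panel <- select(panel, all_of(c("subject", "pop", "superpop", "child")))

  used_pos <- integer(0)
  variant_blocks <- list()
  dosage_blocks <- list()
  depth_cfg <- list() # per block: list(kind, depth_mean, depth_sd, ab_mean, ab_sd)
  truth_rows <- list()
  member_rows <- list()
  dosage_truth <- list()

  draw_positions <- function(start, span, n) {
    if (n < 2) abort("planted loci need at least 2 SNPs")
    inner <- sort(sample(seq(start + 1, start + span - 1), n - 2))
    c(start, inner, start + span)
  }
  draw_alleles <- function(n) {
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  "")
    list(ref = ref, alt = unname(alt))
  }

  # --- planted yin-yang pairs -------------------------------------------
  pr <- config$pairs
  for (i in seq_len(nrow(pr))) {
    n_snps <- pr$n_snps[i]
    pos <- draw_positions(pr$start[i], pr$span[i], n_snps)
    al <- draw_alleles(n_snps)
    freqs <- unlist(pr[i, paste0("freq_", sp_names)])
    f_subj <- freqs[match(panel$superpop, sp_names)]
    hap1 <- rbinom(n_all, 1, f_subj)
    hap2 <- rbinom(n_all, 1, f_subj)
    dos <- matrix(rep(hap1 + hap2, n_snps), nrow = n_all)
    n_int <- pr$n_intermediates[i]
    if (n_int > 0) {
      # one-breakpoint recombinants on randomly chosen chromosome copies
      carriers <- sample(n_all, n_int, replace = FALSE)
      for (s in carriers) {
        bp <- sample(seq_len(n_snps - 1), 1)
        rec <- c(rep(1L, bp), rep(0L, n_snps - bp))
        if (runif(1) < 0.5) rec <- 1L - rec
        keep <- if (runif(1) < 0.5) hap1[s] else hap2[s]
        dos[s, ] <- keep + rec
      }
    }
    locus_id <- paste0("yy", i)
    variant_blocks[[length(variant_blocks) + 1]] <- tibble(
      chrom = config$chrom, pos = pos,
      id = paste0(locus_id, "_", seq_len(n_snps)),
      ref = al$ref, alt = al$alt
    )
    dosage_blocks[[length(dosage_blocks) + 1]] <- dos
    depth_cfg[[length(depth_cfg) + 1]] <- list(kind = "clean")
    truth_rows[[length(truth_rows) + 1]] <- bind_cols(
      tibble(locus_id = locus_id, type = "yinyang", chrom = config$chrom,
             start = pr$start[i], end = pr$start[i] + pr$span[i],
             n_snps = n_snps, outgroup_class = pr$outgroup_class[i],
             n_intermediates = n_int),
      pr[i, paste0("freq_", sp_names)]
    )
    member_rows[[length(member_rows) + 1]] <- tibble(
      locus_id = locus_id, chrom = config$chrom, pos = pos,
      id = paste0(locus_id, "_", seq_len(n_snps)), ref = al$ref, alt = al$alt
    )
    dosage_truth[[locus_id]] <- dos
    used_pos <- c(used_pos, pos)
  }

  # --- repeat-artifact loci ---------------------------------------------
  rp <- config$repeats
  for (i in seq_len(nrow(rp))) {
    n_snps <- rp$n_snps[i]
    pos <- draw_positions(rp$start[i], rp$span[i], n_snps)
    al <- draw_alleles(n_snps)
    cls <- rep(0L, n_all)
    n_het <- round(rp$het_fraction[i] * n_all)
    n_aa <- round(rp$aa_fraction[i] * n_all)
    idx <- sample(n_all)
    cls[idx[seq_len(n_het)]] <- 1L
    if (n_aa > 0) cls[idx[n_het + seq_len(n_aa)]] <- 2L
    dos <- matrix(rep(cls, n_snps), nrow = n_all)
    locus_id <- paste0("rep", i)
    variant_blocks[[length(variant_blocks) + 1]] <- tibble(
      chrom = config$chrom, pos = pos,
      id = paste0(locus_id, "_", seq_len(n_snps)),
      ref = al$ref, alt = al$alt
    )
    dosage_blocks[[length(dosage_blocks) + 1]] <- dos
    depth_cfg[[length(depth_cfg) + 1]] <- list(
      kind = "repeat", depth_mean = rp$depth_mean[i], depth_sd = rp$depth_sd[i],
      ab_mean = rp$ab_mean[i], ab_sd = rp$ab_sd[i]
    )
    truth_rows[[length(truth_rows) + 1]] <- tibble(
      locus_id = locus_id, type = "repeat", chrom = config$chrom,
      start = rp$start[i], end = rp$start[i] + rp$span[i],
      n_snps = n_snps, outgroup_class = NA_character_, n_intermediates = 0L
    )
    member_rows[[length(member_rows) + 1]] <- tibble(
      locus_id = locus_id, chrom = config$chrom, pos = pos,
      id = paste0(locus_id, "_", seq_len(n_snps)), ref = al$ref, alt = al$alt
    )
    dosage_truth[[locus_id]] <- dos
    used_pos <- c(used_pos, pos)
  }

  # --- background common SNPs -------------------------------------------
  n_common <- stats::rpois(1, config$common_density * config$chrom_length)
  if (n_common > 0) {
    pos <- sample(setdiff(seq_len(config$chrom_length), used_pos), n_common)
    pos <- sort(pos)
    al <- draw_alleles(n_common)
    f <- runif(n_common, config$common_maf_range[1], config$common_maf_range[2])
    dos <- vapply(f, function(p) rbinom(n_all, 2, p), integer(n_all))
    variant_blocks[[length(variant_blocks) + 1]] <- tibble(
      chrom = config$chrom, pos = pos,
      id = paste0(config$chrom, ":", pos),
      ref = al$ref, alt = al$alt
    )
    dosage_blocks[[length(dosage_blocks) + 1]] <- dos
    depth_cfg[[length(depth_cfg) + 1]] <- list(kind = "clean")
    used_pos <- c(used_pos, pos)
  }

  # --- rare background: singletons and doubletons ------------------------
  mb <- config$chrom_length / 1e6
  n_single <- round(config$singleton_density * mb * n_unrel)
  n_double <- round(config$doubleton_density * mb * n_unrel)
  if (n_single + n_double > 0) {
    pos <- sample(setdiff(seq_len(config$chrom_length), used_pos),
                  n_single + n_double)
    pos <- sort(pos)
    al <- draw_alleles(n_single + n_double)
    dos <- matrix(0L, nrow = n_all, ncol = n_single + n_double)
    is_double <- sample(c(rep(FALSE, n_single), rep(TRUE, n_double)))
    for (j in seq_len(n_single + n_double)) {
      copies <- if (is_double[j]) 2L else 1L
      chrom_copies <- sample(2L * n_unrel, copies)
      carriers <- (chrom_copies - 1L) %/% 2L + 1L
      for (s in carriers) dos[s, j] <- dos[s, j] + 1L
    }
    variant_blocks[[length(variant_blocks) + 1]] <- tibble(
      chrom = config$chrom, pos = pos,
      id = paste0(config$chrom, ":", pos),
      ref = al$ref, alt = al$alt
    )
    dosage_blocks[[length(dosage_blocks) + 1]] <- dos
    depth_cfg[[length(depth_cfg) + 1]] <- list(kind = "clean")
  }

  variants <- bind_rows(variant_blocks)
  geno <- do.call(cbind, dosage_blocks)

  # --- read depth and allele balance ------------------------------------
  dp <- matrix(NA_integer_, nrow = n_all, ncol = ncol(geno))
  ad_alt <- matrix(NA_integer_, nrow = n_all, ncol = ncol(geno))
  col0 <- 0L
  for (b in seq_along(dosage_blocks)) {
    nc <- ncol(dosage_blocks[[b]])
    cols <- col0 + seq_len(nc)
    cfg <- depth_cfg[[b]]
    if (cfg$kind == "clean") {
      dmean <- config$clean_depth_mean
      dsd <- config$clean_depth_sd
      ab_mean <- 0.5
      ab_sd <- config$clean_ab_sd
    } else {
      dmean <- cfg$depth_mean
      dsd <- cfg$depth_sd
      ab_mean <- cfg$ab_mean
      ab_sd <- cfg$ab_sd
    }
    ncell <- n_all * nc
    depth <- pmax(1L, rnbinom(ncell, size = nbinom_size(dmean, dsd),
                              mu = dmean))
    g <- as.vector(dosage_blocks[[b]])
    sh <- beta_shapes(ab_mean, ab_sd)
    bal <- rbeta(ncell, sh[1], sh[2])
    alt_reads <- integer(ncell)
    err <- 0.002 # sequencing-error alternate reads at homozygous calls
    alt_reads[g == 0] <- rbinom(sum(g == 0), depth[g == 0], err)
    # balance applied directly so the observed heterozygote allele-balance
    # sd recovers the configured value independent of depth
    alt_reads[g == 1] <- round(depth[g == 1] * bal[g == 1])
    alt_reads[g == 2] <- depth[g == 2] - rbinom(sum(g == 2), depth[g == 2], err)
    dp[, cols] <- matrix(as.integer(depth), nrow = n_all)
    ad_alt[, cols] <- matrix(as.integer(alt_reads), nrow = n_all)
    col0 <- col0 + nc
  }

  ord <- order(variants$pos)
  cohort <- yy_cohort(
    variants = variants[ord, ],
    geno = geno[, ord, drop = FALSE],
    panel = panel,
    dp = dp[, ord, drop = FALSE],
    ad_alt = ad_alt[, ord, drop = FALSE]
  )

  structure(
    list(
      cohort = cohort,
      truth = bind_rows(truth_rows),
      members = bind_rows(member_rows),
      dosage_truth = dosage_truth,
      config = config
    ),
    class = "yy_scenario"
  )
}

#' Simulate outgroup allele calls for planted pairs
#'
#' Builds a chimpanzee/Neanderthal allele table realising each planted pair's
#' configured outgroup class:
#' \describe{
#'   \item{derived}{both outgroups carry the same full haplotype (all
#'     reference or all alternate), so the other haplotype arose entirely in
#'     humans;}
#'   \item{ancient}{one outgroup carries the all-reference haplotype and the
#'     other the all-alternate haplotype, so both predate the
#'     human-Neanderthal split;}
#'   \item{partial}{one outgroup carries a strict non-empty subset of one
#'     haplotype's alleles;}
#'   \item{mixed}{discordant sites in both directions (chimp-ref with
#'     Neanderthal-alt, and the reverse).}
#' }
#'
#' @param scenario A `yy_scenario` from [simulate_cohort()].
#' @param seed Seed for the orientation/subsets; defaults to the scenario's
#'   own seed offset by one.
#' @return Tibble `chrom`, `pos`, `chimp_allele`, `neanderthal_allele`.
#' @export
simulate_outgroups <- function(scenario, seed = scenario$config$seed + 1L) {
  stopifnot(inherits(scenario, "yy_scenario"))
  with_seed(seed, {
    yy <- filter(scenario$truth, .data$type == "yinyang")
    rows <- purrr::map(yy$locus_id, function(lid) {
      mem <- filter(scenario$members, .data$locus_id == lid)
      cls <- yy$outgroup_class[yy$locus_id == lid]
      n <- nrow(mem)
      if (cls %in% c("partial", "mixed") && n < 5) {
        abort(paste0("outgroup class '", cls, "' needs >= 5 informative SNPs; ",
                     lid, " has ", n))
      }
      # carrier state per outgroup: TRUE = alternate allele at every site
      chimp_alt <- neand_alt <- logical(n)
      if (cls == "derived") {
        all_alt <- runif(1) < 0.5
        chimp_alt[] <- all_alt
        neand_alt[] <- all_alt
      } else if (cls == "ancient") {
        chimp_first <- runif(1) < 0.5
        chimp_alt[] <- chimp_first
        neand_alt[] <- !chimp_first
      } else if (cls == "partial") {
        # chimp all-reference; Neanderthal a strict subset of the alternate
        k <- sample(seq_len(n - 1), 1)
        neand_alt[sample(n, k)] <- TRUE
      } else if (cls == "mixed") {
        half <- sample(n, floor(n / 2))
        chimp_alt[half] <- TRUE
        neand_alt[setdiff(seq_len(n), half)] <- TRUE
      } else {
        abort(paste0("unknown outgroup class: ", cls))
      }
      tibble(
        chrom = mem$chrom, pos = mem$pos,
        chimp_allele = ifelse(chimp_alt, mem$alt, mem$ref),
        neanderthal_allele = ifelse(neand_alt, mem$alt, mem$ref)
      )
    })
    bind_rows(rows)
  })
}

#' Write a scenario's files to disk
#'
#' Dumps the standard external representations of a simulated scenario:
#' `cohort.vcf`, `panel.tsv`, `truth.tsv` (one row per planted locus),
#' `truth_members.tsv` (planted SNP positions), `outgroups.tsv` and a
#' key/value `config.txt` recording the scalar generator settings including
#' the mandatory seed.
#'
#' @param scenario A `yy_scenario` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "yy_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_vcf(scenario$cohort, file.path(dir, "cohort.vcf"))
  readr::write_tsv(scenario$cohort$panel, file.path(dir, "panel.tsv"))
  readr::write_tsv(scenario$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(scenario$members, file.path(dir, "truth_members.tsv"))
  readr::write_tsv(simulate_outgroups(scenario), file.path(dir, "outgroups.tsv"))
  cfg <- scenario$config
  scalars <- cfg[vapply(cfg, function(x) is.atomic(x) && length(x) <= 10,
                        TRUE)]
  lines <- vapply(names(scalars), function(k) {
    v <- scalars[[k]]
    if (!is.null(names(v))) {
      paste0(k, " = ", paste(names(v), v, sep = ":", collapse = ","))
    } else {
      paste0(k, " = ", paste(v, collapse = ","))
    }
  }, "")
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}
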