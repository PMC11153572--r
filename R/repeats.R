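# Repeat-artifact detection. Chains of SNPs called heterozygous in all or
# almost all subjects are the signature of unrecognised repeats: reads from
# two near-identical paralogous sequences map to one position, so paralogous
# sequence variants masquerade as heterozygous SNPs with inflated read depth
# and skewed allele balance.

#' Collect repeat evidence at chain lead SNPs
#'
#' For each chain's lead SNP: genotype counts (RR/RA/AA) and the observed
#' heterozygote fraction over unrelated subjects, and per-genotype-class
#' read-depth means/sds plus heterozygote allele balance (alternate reads /
#' total reads) over the full cohort, children included. When the cohort
#' carries no depth fields the depth columns are `NA` and
#' `depth_available` is `FALSE`; classification then degrades gracefully.
#'
#' @param chains Chain table from [find_chains()]/[apply_exclusions()].
#' @param cohort A [yy_cohort()], ideally with AD/DP matrices.
#' @return Tibble with one row per chain: `chain_id`, `lead_id`, `n_RR`,
#'   `n_RA`, `n_AA`, `het_fraction`, per-class `depth_*_mean`/`_sd`,
#'   `ab_mean`, `ab_sd`, `depth_available`.
#' @export
repeat_evidence <- function(chains, cohort) {
  stopifnot(inherits(cohort, "yy_cohort"))
  unrel <- !cohort$panel$child
  has_depth <- !is.null(cohort$dp)
  if (nrow(chains) == 0) {
    return(tibble(
      chain_id = character(), lead_id = character(), n_RR = integer(),
      n_RA = integer(), n_AA = integer(), n_called = integer(),
      het_fraction = numeric(), depth_RR_mean = numeric(),
      depth_RR_sd = numeric(), depth_RA_mean = numeric(),
      depth_RA_sd = numeric(), depth_AA_mean = numeric(),
      depth_AA_sd = numeric(), ab_mean = numeric(), ab_sd = numeric(),
      depth_available = logical()
    ))
  }
  rows <- purrr::map(seq_len(nrow(chains)), function(r) {
    li <- chains$lead_index[r]
    g_unrel <- cohort$geno[unrel, li]
    g_all <- cohort$geno[, li]
    n_rr <- sum(g_unrel == 0, na.rm = TRUE)
    n_ra <- sum(g_unrel == 1, na.rm = TRUE)
    n_aa <- sum(g_unrel == 2, na.rm = TRUE)
    n_called <- n_rr + n_ra + n_aa
    cls_stats <- function(gval) {
      if (!has_depth) return(c(NA_real_, NA_real_))
      dvec <- cohort$dp[, li][!is.na(g_all) & g_all == gval]
      if (!length(dvec)) return(c(NA_real_, NA_real_))
      c(mean(dvec, na.rm = TRUE), sd(dvec, na.rm = TRUE))
    }
    rr <- cls_stats(0); ra <- cls_stats(1); aa <- cls_stats(2)
    if (has_depth && !is.null(cohort$ad_alt)) {
      het <- !is.na(g_all) & g_all == 1
      bal <- cohort$ad_alt[het, li] / cohort$dp[het, li]
      bal <- bal[is.finite(bal)]
      ab_mean <- if (length(bal)) mean(bal) else NA_real_
      ab_sd <- if (length(bal) > 1) sd(bal) else NA_real_
    } else {
      ab_mean <- ab_sd <- NA_real_
    }
    tibble(
      chain_id = chains$chain_id[r], lead_id = chains$lead_id[r],
      n_RR = n_rr, n_RA = n_ra, n_AA = n_aa,
      n_called = n_called,
      het_fraction = if (n_called > 0) n_ra / n_called else NA_real_,
      depth_RR_mean = rr[1], depth_RR_sd = rr[2],
      depth_RA_mean = ra[1], depth_RA_sd = ra[2],
      depth_AA_mean = aa[1], depth_AA_sd = aa[2],
      ab_mean = ab_mean, ab_sd = ab_sd,
      depth_available = has_depth
    )
  })
  bind_rows(rows)
}

#' Classify chains as clean or repeat artifacts
#'
#' Verdicts, checked in order:
#' \describe{
#'   \item{repeat_all_het}{every called genotype is heterozygous - a
#'     biological impossibility for a real variant;}
#'   \item{repeat_missing_hom}{heterozygote fraction above `het_max` with
#'     zero or near-zero counts for one or both homozygote classes (bound
#'     `max(10, 0.5% of called subjects)`, overridable via
#'     `hom_near_zero`);}
#'   \item{repeat_low_AA}{fewer than `min_minor_hom` AA homozygotes together
#'     with a heterozygote read-depth mean above `depth_flag`;}
#'   \item{clean}{anything else.}
#' }
#' Raising the heterozygote fraction with all other evidence held fixed can
#' only move a verdict towards (never away from) a repeat call. Evidence
#' without depth fields cannot trigger `repeat_low_AA`; such rows are
#' reported via a message.
#'
#' @param evidence Evidence table from [repeat_evidence()].
#' @param het_max Heterozygote-fraction threshold (default 0.53).
#' @param min_minor_hom Minimum AA homozygote count for a clean call
#'   (default 20).
#' @param depth_flag Heterozygote depth mean above which a low-AA chain is
#'   flagged (default 55, midway between typical clean and repeat depth
#'   means).
#' @param hom_near_zero Near-zero homozygote bound for
#'   `repeat_missing_hom`; default `max(10, 0.005 * called subjects)`.
#' @return `evidence` with an added `verdict` column.
#' @export
classify_repeats <- function(evidence, het_max = 0.53, min_minor_hom = 20,
                             depth_flag = 55, hom_near_zero = NULL) {
  verdict <- rep("clean", nrow(evidence))
  no_depth_low_aa <- 0L
  for (r in seq_len(nrow(evidence))) {
    e <- evidence[r, ]
    bound <- if (is.null(hom_near_zero)) {
      max(10, 0.005 * e$n_called)
    } else {
      hom_near_zero
    }
    if (e$n_RA > 0 && e$n_RR == 0 && e$n_AA == 0) {
      verdict[r] <- "repeat_all_het"
    } else if (!is.na(e$het_fraction) && e$het_fraction > het_max &&
               min(e$n_RR, e$n_AA) < bound) {
      verdict[r] <- "repeat_missing_hom"
    } else if (e$n_AA < min_minor_hom) {
      if (!is.na(e$depth_RA_mean) && e$depth_RA_mean > depth_flag) {
        verdict[r] <- "repeat_low_AA"
      } else if (is.na(e$depth_RA_mean)) {
        no_depth_low_aa <- no_depth_low_aa + 1L
      }
    }
  }
  if (no_depth_low_aa > 0) {
    inform(paste0(no_depth_low_aa, " chain(s) with few AA homozygotes could ",
                  "not be depth-checked (no depth fields)"))
  }
  evidence$verdict <- verdict
  evidence
}
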