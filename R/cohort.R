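#' Construct a genotype cohort
#'
#' A `yy_cohort` bundles everything the scan needs: a variant table, a
#' subjects-by-variants matrix of alternate-allele dosages, the subject panel
#' and (optionally) per-cell read-depth and alternate-read matrices taken from
#' the VCF `DP`/`AD` FORMAT fields.
#'
#' Genotype dosages are 0, 1, 2 or `NA` (a `./.` call is missing, never 0).
#' Allele frequencies and minor-allele frequencies are computed over unrelated
#' subjects only, with the denominator counting called alleles; read-depth
#' matrices retain all subjects (children included) because depth summaries
#' deliberately use the full cohort.
#'
#' @param variants Tibble with columns `chrom`, `pos` (1-based bp), `id`,
#'   `ref`, `alt`, one row per biallelic SNP, sorted by (chrom, pos).
#' @param geno Integer matrix, subjects x variants, entries in \{0, 1, 2, NA\}.
#' @param panel Tibble with columns `subject`, `pop`, `superpop`, `child`
#'   (logical); row order must match the rows of `geno`.
#' @param dp,ad_alt Optional numeric matrices of the same shape as `geno`:
#'   total read depth and alternate-allele read count per call.
#'
#' @return An object of class `yy_cohort`: a list with elements `variants`
#'   (augmented with `n_called`, `alt_freq`, `maf` over unrelated subjects),
#'   `geno`, `panel`, `dp`, `ad_alt`.
#' @export
yy_cohort <- function(variants, geno, panel, dp = NULL, ad_alt = NULL) {
  variants <- as_tibble(variants)
  panel <- as_tibble(panel)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(variants))) {
    abort(paste("variants must have columns:", paste(need, collapse = ", ")))
  }
  if (!all(c("subject", "pop", "superpop", "child") %in% names(panel))) {
    abort("panel must have columns subject, pop, superpop, child")
  }
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(panel)) {
    abort("geno must have one row per panel subject")
  }
  if (ncol(geno) != nrow(variants)) {
    abort("geno must have one column per variant")
  }
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, ]
    geno <- geno[, ord, drop = FALSE]
    if (!is.null(dp)) dp <- dp[, ord, drop = FALSE]
    if (!is.null(ad_alt)) ad_alt <- ad_alt[, ord, drop = FALSE]
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("geno entries must be 0, 1, 2 or NA")
  }
  unrel <- !panel$child
  if (!any(unrel)) abort("panel contains no unrelated subjects")
  g <- geno[unrel, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  if (any(n_called == 0)) {
    abort("every variant must have a dosage for at least one unrelated subject")
  }
  alt_freq <- colSums(g, na.rm = TRUE) / (2 * n_called)
  variants$n_called <- as.integer(n_called)
  variants$alt_freq <- alt_freq
  variants$maf <- pmin(alt_freq, 1 - alt_freq)
  structure(
    list(variants = variants, geno = geno, panel = panel,
         dp = dp, ad_alt = ad_alt),
    class = "yy_cohort"
  )
}

#' @export
print.yy_cohort <- function(x, ...) {
  cat("<yy_cohort> ", nrow(x$panel), " subjects (",
      sum(!x$panel$child), " unrelated), ",
      nrow(x$variants), " biallelic SNPs on ",
      length(unique(x$variants$chrom)), " chromosome(s)\n", sep = "")
  cat("  depth fields: ", if (is.null(x$dp)) "absent" else "present", "\n",
      sep = "")
  invisible(x)
}

#' Filter a cohort to common variants
#'
#' Keeps variants whose global minor allele frequency, computed over unrelated
#' subjects with called alleles in the denominator, is at least `maf_min`.
#' The default 0.1 restricts the scan to variants common enough to have a
#' worldwide distribution; the unfiltered cohort is still needed downstream
#' for singleton/doubleton background statistics, so filtering is a separate
#' step from loading.
#'
#' @param cohort A [yy_cohort()].
#' @param maf_min Minimum global minor allele frequency (default 0.1).
#' @return A `yy_cohort` restricted to the passing variants.
#' @export
filter_maf <- function(cohort, maf_min = 0.1) {
  stopifnot(inherits(cohort, "yy_cohort"))
  keep <- cohort$variants$maf >= maf_min
  subset_cohort(cohort, keep)
}

# Column subset preserving all matrices.
subset_cohort <- function(cohort, keep) {
  yy_cohort(
    variants = cohort$variants[keep, c("chrom", "pos", "id", "ref", "alt")],
    geno = cohort$geno[, keep, drop = FALSE],
    panel = cohort$panel,
    dp = if (is.null(cohort$dp)) NULL else cohort$dp[, keep, drop = FALSE],
    ad_alt = if (is.null(cohort$ad_alt)) NULL else
      cohort$ad_alt[, keep, drop = FALSE]
  )
}

# Dosage matrix over unrelated subjects only.
unrelated_geno <- function(cohort) {
  cohort$geno[!cohort$panel$child, , drop = FALSE]
}
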