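# Average genotype distance: a fast, phase-free LD proxy. For a pair of
# variants it is the mean over subjects of |dosage difference|; pairs of
# variants in complete LD with identical reference/alternate orientation
# have distance 0.

#' Average genotype distance between two dosage vectors
#'
#' The sum of absolute differences between the alternate-allele counts
#' carried by each subject at the two loci, divided by the number of
#' subjects. Subjects missing a call at either locus are excluded from both
#' numerator and denominator, so with complete data the distance times the
#' subject count is an integer.
#'
#' @param a,b Integer dosage vectors (0/1/2/NA) over the same subject list.
#' @return The average distance, or `NA` (with a warning) when no subject is
#'   called at both loci.
#' @export
genotype_distance <- function(a, b) {
  if (length(a) != length(b)) abort("dosage vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0) {
    warn("no subject called at both loci; distance undefined")
    return(NA_real_)
  }
  sum(abs(a[ok] - b[ok])) / n
}

#' Build the windowed genotype-distance table
#'
#' For every variant, computes the average genotype distance between it and
#' each of the next `window` variants on the same chromosome (fewer at a
#' chromosome end; no pair ever spans a chromosome boundary). Distances are
#' computed over unrelated subjects.
#'
#' @param cohort A [yy_cohort()], normally MAF-filtered via [filter_maf()].
#' @param window Number of following variants compared to each variant
#'   (default 10).
#' @return Tibble with one row per in-window pair: `chrom`, `i`, `j` (column
#'   indices into the cohort's variant table), `pos_i`, `pos_j`, `d`
#'   (average genotype distance) and `n` (subjects called at both loci).
#' @export
distance_table <- function(cohort, window = 10) {
  stopifnot(inherits(cohort, "yy_cohort"))
  g <- unrelated_geno(cohort)
  v <- cohort$variants
  out <- vector("list", length(unique(v$chrom)) * window)
  slot <- 0L
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    m <- length(idx)
    if (m < 2) next
    for (k in seq_len(min(window, m - 1))) {
      i <- idx[seq_len(m - k)]
      j <- idx[k + seq_len(m - k)]
      diffs <- abs(g[, i, drop = FALSE] - g[, j, drop = FALSE])
      n <- colSums(!is.na(diffs))
      s <- colSums(diffs, na.rm = TRUE)
      slot <- slot + 1L
      out[[slot]] <- tibble(
        chrom = chr, i = i, j = j,
        pos_i = v$pos[i], pos_j = v$pos[j],
        d = ifelse(n > 0, s / n, NA_real_), n = as.integer(n)
      )
    }
  }
  if (slot == 0L) {
    return(tibble(chrom = character(), i = integer(), j = integer(),
                  pos_i = integer(), pos_j = integer(),
                  d = numeric(), n = integer()))
  }
  arrange(bind_rows(out[seq_len(slot)]), .data$i, .data$j)
}
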