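# Per-haplotype characterisation: recombination-map genetic length,
# Wright's fixation index over superpopulations (with MAF-matched control
# SNPs), and singleton/doubleton/heterozygosity background statistics
# inside versus outside the haplotype spans.

#' Wright's fixation index from superpopulation frequencies
#'
#' Computes
#' \deqn{F_{ST} = \frac{\bar p (1-\bar p) - \sum_i c_i p_i (1-p_i)}
#'                     {\bar p (1-\bar p)}}
#' where \eqn{p_i} is the minor allele frequency in superpopulation *i*,
#' \eqn{c_i} its relative sample size (renormalised to sum to one) and
#' \eqn{\bar p = \sum_i c_i p_i} the pooled frequency. The same allele must
#' be tracked in every superpopulation, so individual \eqn{p_i} may exceed
#' 0.5.
#'
#' @param p Per-superpopulation frequencies of one tracked allele.
#' @param c_i Relative sample sizes (any positive weights; renormalised).
#' @return The fixation index in \[0, 1\], or `NA` when the pooled frequency
#'   is 0 or 1 (undefined).
#' @export
fst <- function(p, c_i) {
  if (length(p) < 2 || length(p) != length(c_i)) {
    abort("fst needs matching frequency and weight vectors of length >= 2")
  }
  if (any(p < 0 | p > 1)) abort("frequencies must lie in [0, 1]")
  if (any(c_i <= 0)) abort("weights must be positive")
  c_i <- c_i / sum(c_i)
  pbar <- sum(c_i * p)
  denom <- pbar * (1 - pbar)
  if (denom == 0) return(NA_real_)
  (denom - sum(c_i * p * (1 - p))) / denom
}

#' Genetic length of chains from a recombination map
#'
#' The genetic length of a chain span is the sum over map intervals of
#' rate x overlap length (bp pro-rated to Mb); map gaps contribute zero.
#' The rate column is then `cM / (span / 1e6)`. Chains on chromosomes absent
#' from the map get `NA` for both metrics.
#'
#' @param chains Chain table from [find_chains()].
#' @param map Recombination map from [read_recombination_map()] (`chrom`,
#'   `start`, `end` in bp half-open, `rate` in cM/Mb).
#' @return `chains` with added columns `cM` and `cM_per_Mb`.
#' @export
genetic_length <- function(chains, map) {
  cm <- rep(NA_real_, nrow(chains))
  for (r in seq_len(nrow(chains))) {
    mi <- map[map$chrom == chains$chrom[r], , drop = FALSE]
    if (nrow(mi) == 0) next
    ov <- overlap_bp(chains$start[r], chains$end[r], mi$start, mi$end)
    cm[r] <- sum(mi$rate * ov / 1e6)
  }
  chains$cM <- cm
  chains$cM_per_Mb <- cm / (chains$span / 1e6)
  chains
}

#' Superpopulation frequencies and fixation indices for chain lead SNPs
#'
#' For each chain's lead SNP, obtains the globally minor allele's frequency
#' in every superpopulation (the same allele tracked throughout) and two
#' fixation indices: over all superpopulations, and excluding one (by
#' default AFR, to allow for out-of-Africa bottleneck effects), with the
#' weights renormalised after exclusion. Weights are the per-superpopulation
#' counts of unrelated subjects with called genotypes at the SNP.
#'
#' @param chains Chain table.
#' @param cohort A [yy_cohort()].
#' @param exclude Superpopulation code excluded from the second index
#'   (default `"AFR"`).
#' @return Tibble: `chain_id`, `lead_id`, one `maf_<SP>` column per
#'   superpopulation, `fst_all`, `fst_excl`.
#' @export
fst_table <- function(chains, cohort, exclude = "AFR") {
  stopifnot(inherits(cohort, "yy_cohort"))
  res <- snp_fst(chains$lead_index, cohort, exclude = exclude)
  bind_cols(tibble(chain_id = chains$chain_id, lead_id = chains$lead_id), res)
}

# Fixation indices for arbitrary variant column indices.
snp_fst <- function(indices, cohort, exclude = "AFR") {
  unrel <- !cohort$panel$child
  sp <- cohort$panel$superpop[unrel]
  sps <- sort(unique(sp))
  g <- cohort$geno[unrel, , drop = FALSE]
  rows <- purrr::map(indices, function(li) {
    gv <- g[, li]
    minor_is_alt <- cohort$variants$alt_freq[li] <= 0.5
    p <- vapply(sps, function(s) {
      gs <- gv[sp == s]
      nc <- sum(!is.na(gs))
      if (nc == 0) return(NA_real_)
      af <- sum(gs, na.rm = TRUE) / (2 * nc)
      if (minor_is_alt) af else 1 - af
    }, 0.0)
    w <- vapply(sps, function(s) sum(!is.na(gv[sp == s])), 0.0)
    ok <- !is.na(p) & w > 0
    f_all <- if (sum(ok) >= 2) fst(p[ok], w[ok]) else NA_real_
    keep <- ok & sps != exclude
    f_excl <- if (sum(keep) >= 2) fst(p[keep], w[keep]) else NA_real_
    out <- as.list(p)
    names(out) <- paste0("maf_", sps)
    out$fst_all <- f_all
    out$fst_excl <- f_excl
    as_tibble(out)
  })
  bind_rows(rows)
}

#' Match control SNPs by minor allele frequency
#'
#' For each chain, selects a control SNP on the same chromosome, outside
#' every chain span and not a member of any chain, with global MAF as close
#' as possible to the lead SNP's. Exact equality is rarely attainable, so
#' candidates within `tol` of the lead MAF are eligible, the nearest wins,
#' and ties are broken by a seeded random choice (reproducible across runs).
#'
#' @param chains Chain table.
#' @param cohort A [yy_cohort()] (normally the MAF-filtered one, so controls
#'   are drawn from the same common-variant pool as the chains).
#' @param tol Maximum |MAF difference| for eligibility (default 0.005).
#' @param seed Integer seed for tie-breaking.
#' @return Tibble: `chain_id`, `control_index`, `control_id`, `control_maf`
#'   (`NA` when no eligible candidate exists).
#' @export
match_control_snps <- function(chains, cohort, tol = 0.005, seed = 1L) {
  stopifnot(inherits(cohort, "yy_cohort"))
  v <- cohort$variants
  member_idx <- unique(unlist(chains$members))
  in_span <- rep(FALSE, nrow(v))
  for (r in seq_len(nrow(chains))) {
    in_span <- in_span | (v$chrom == chains$chrom[r] &
                            v$pos >= chains$start[r] & v$pos <= chains$end[r])
  }
  eligible <- !in_span
  eligible[member_idx] <- FALSE
  with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(chains)), function(r) {
      lead_maf <- v$maf[chains$lead_index[r]]
      cand <- which(eligible & v$chrom == chains$chrom[r])
      if (length(cand)) {
        dmaf <- abs(v$maf[cand] - lead_maf)
        best <- dmaf <= tol & dmaf == min(dmaf)
        cand <- cand[best]
      }
      if (!length(cand)) {
        return(tibble(chain_id = chains$chain_id[r],
                      control_index = NA_integer_,
                      control_id = NA_character_, control_maf = NA_real_))
      }
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      tibble(chain_id = chains$chain_id[r], control_index = pick,
             control_id = v$id[pick], control_maf = v$maf[pick])
    })
    bind_rows(rows)
  })
}

#' Background variation inside versus outside haplotype spans
#'
#' Partitions the analysed genome into the union of autosomal chain spans
#' and the rest, then reports per superpopulation: singleton and doubleton
#' densities (variants whose minor allele is observed exactly once or twice
#' across all unrelated subjects, assigned to the superpopulations of their
#' carriers and expressed per Mb per subject) and average heterozygosity
#' (the sum over variants of `2 * MAF * (1 - MAF)` using superpopulation
#' MAFs, per Mb).
#'
#' @param chains Chain table (only autosomal chains are used).
#' @param cohort The unfiltered [yy_cohort()] so that rare variants are
#'   present for singleton/doubleton counting.
#' @param genome_size Total analysed length in bp; defaults to the sum over
#'   chromosomes of the largest observed variant position.
#' @return Tibble with one row per superpopulation: `superpop`,
#'   `n_subjects`, `singleton_inside`, `singleton_outside`,
#'   `doubleton_inside`, `doubleton_outside`, `het_inside`, `het_outside`.
#'   The inside/outside Mb used are attached as attributes `inside_mb` and
#'   `outside_mb`.
#' @export
background_stats <- function(chains, cohort, genome_size = NULL) {
  stopifnot(inherits(cohort, "yy_cohort"))
  v <- cohort$variants
  unrel <- !cohort$panel$child
  sp <- cohort$panel$superpop[unrel]
  sps <- sort(unique(sp))
  g <- cohort$geno[unrel, , drop = FALSE]

  auto <- chains[is_autosome(chains$chrom), , drop = FALSE]
  inside <- rep(FALSE, nrow(v))
  inside_bp <- 0
  for (chr in unique(auto$chrom)) {
    ci <- which(auto$chrom == chr)
    red <- IRanges::reduce(IRanges::IRanges(start = auto$start[ci],
                                            end = auto$end[ci]))
    inside_bp <- inside_bp + sum(IRanges::width(red))
    vi <- which(v$chrom == chr)
    if (length(vi)) {
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(start = v$pos[vi], width = 1L), red)
      inside[vi[hit]] <- TRUE
    }
  }
  if (is.null(genome_size)) {
    genome_size <- sum(vapply(split(v$pos, v$chrom), max, 0))
  }
  inside_mb <- inside_bp / 1e6
  outside_mb <- genome_size / 1e6 - inside_mb
  if (outside_mb <= 0) outside_mb <- NA_real_

  n_called <- colSums(!is.na(g))
  ac_alt <- colSums(g, na.rm = TRUE)
  mac <- pmin(ac_alt, 2 * n_called - ac_alt)
  minor_is_alt <- ac_alt <= n_called # alt count <= half of called alleles

  carrier_superpops <- function(j) {
    gv <- g[, j]
    carriers <- if (minor_is_alt[j]) {
      which(!is.na(gv) & gv > 0)
    } else {
      which(!is.na(gv) & gv < 2)
    }
    unique(sp[carriers])
  }

  count_rare <- function(target_mac, region_inside) {
    idx <- which(mac == target_mac & inside == region_inside &
                   is_autosome(v$chrom))
    counts <- setNames(numeric(length(sps)), sps)
    for (j in idx) {
      for (s in carrier_superpops(j)) counts[s] <- counts[s] + 1
    }
    counts
  }

  het_sum <- function(region_inside) {
    idx <- which(inside == region_inside & is_autosome(v$chrom))
    out <- setNames(numeric(length(sps)), sps)
    if (!length(idx)) return(out)
    for (s in sps) {
      gs <- g[sp == s, idx, drop = FALSE]
      nc <- colSums(!is.na(gs))
      af <- ifelse(nc > 0, colSums(gs, na.rm = TRUE) / (2 * nc), NA_real_)
      maf_s <- pmin(af, 1 - af)
      out[s] <- sum(2 * maf_s * (1 - maf_s), na.rm = TRUE)
    }
    out
  }

  n_sp <- vapply(sps, function(s) sum(sp == s), 0L)
  s_in <- count_rare(1, TRUE); s_out <- count_rare(1, FALSE)
  d_in <- count_rare(2, TRUE); d_out <- count_rare(2, FALSE)
  h_in <- het_sum(TRUE); h_out <- het_sum(FALSE)

  out <- tibble(
    superpop = sps,
    n_subjects = as.integer(unname(n_sp)),
    singleton_inside = if (inside_mb > 0) {
      unname(s_in / inside_mb / n_sp)
    } else NA_real_,
    singleton_outside = unname(s_out / outside_mb / n_sp),
    doubleton_inside = if (inside_mb > 0) {
      unname(d_in / inside_mb / n_sp)
    } else NA_real_,
    doubleton_outside = unname(d_out / outside_mb / n_sp),
    het_inside = if (inside_mb > 0) unname(h_in / inside_mb) else NA_real_,
    het_outside = unname(h_out / outside_mb)
  )
  attr(out, "inside_mb") <- inside_mb
  attr(out, "outside_mb") <- outside_mb
  out
}
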