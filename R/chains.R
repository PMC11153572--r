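# Greedy assembly of candidate exclusive yin-yang pairs from the windowed
# distance table, followed by region and callability exclusions.

#' Find candidate yin-yang haplotype chains
#'
#' Starting from every variant, a chain is extended greedily: from its
#' current last member, the nearest following variant within the next
#' `gap_max + 1` positions whose average genotype distance from that member
#' is at most `threshold` is appended, until no such variant exists. Chains
#' shorter than `min_snps` are dropped, and chains whose member set is
#' contained in another reported chain are removed so that only maximal
#' chains are reported (overlapping but non-nested chains are all kept).
#' Because extension always picks the nearest qualifying successor, a chain
#' started at an interior member of a longer chain is a suffix of it, and
#' maximal chains are exactly those whose start is never chosen as a
#' successor.
#'
#' @param dist Distance table from [distance_table()]; its window must be at
#'   least `gap_max + 1`.
#' @param cohort The [yy_cohort()] the table was built from (supplies
#'   positions and lead-SNP metadata).
#' @param threshold Maximum average genotype distance for two variants to be
#'   chained (default 0.0015: with 2504 fully-called subjects, at most 3
#'   subjects differing by one allele).
#' @param min_snps Minimum chain length in SNPs (default 20).
#' @param gap_max Maximum number of intervening non-member SNPs between
#'   consecutive members (default 9).
#' @return Tibble with one row per chain: `chain_id`, `chrom`, `start`,
#'   `end` (positions of first and last member), `lead_index`, `lead_id`,
#'   `n_snps`, `span` (bp, last minus first position) and `members`
#'   (list-column of variant column indices).
#' @export
find_chains <- function(dist, cohort, threshold = 0.0015, min_snps = 20,
                        gap_max = 9) {
  stopifnot(inherits(cohort, "yy_cohort"))
  v <- cohort$variants
  m <- nrow(v)
  qual <- dist[!is.na(dist$d) & dist$d <= threshold &
                 (dist$j - dist$i) <= gap_max + 1L, , drop = FALSE]
  nxt <- rep(NA_integer_, m)
  if (nrow(qual)) {
    # nearest qualifying successor of each variant
    first <- qual %>% group_by(.data$i) %>%
      summarise(j = min(.data$j), .groups = "drop")
    nxt[first$i] <- first$j
  }
  starts <- setdiff(seq_len(m), nxt[!is.na(nxt)])
  chains <- list()
  for (s in starts) {
    mem <- s
    cur <- s
    while (!is.na(nxt[cur])) {
      cur <- nxt[cur]
      mem <- c(mem, cur)
    }
    if (length(mem) >= min_snps) chains[[length(chains) + 1]] <- mem
  }
  if (!length(chains)) {
    return(tibble(
      chain_id = character(), chrom = character(), start = integer(),
      end = integer(), lead_index = integer(), lead_id = character(),
      n_snps = integer(), span = integer(), members = list()
    ))
  }
  lead <- vapply(chains, `[`, 1L, 1)
  last <- vapply(chains, function(x) x[length(x)], 1L)
  ord <- order(chrom_rank(v$chrom[lead]), v$pos[lead])
  chains <- chains[ord]
  lead <- lead[ord]
  last <- last[ord]
  tibble(
    chain_id = sprintf("chain_%03d", seq_along(chains)),
    chrom = v$chrom[lead],
    start = v$pos[lead],
    end = v$pos[last],
    lead_index = lead,
    lead_id = v$id[lead],
    n_snps = lengths(chains),
    span = v$pos[last] - v$pos[lead],
    members = chains
  )
}

#' Apply region and callability exclusions to candidate chains
#'
#' A chain is discarded when its span overlaps an excluded region (for
#' example a documented alternate scaffold or patch) by at least one base
#' pair, or when its lead SNP has called genotypes in fewer than
#' `lead_call_min` unrelated subjects. Discard reasons are recorded; region
#' overlap takes precedence when both apply.
#'
#' @param chains Chain table from [find_chains()].
#' @param regions Excluded regions from [read_excluded_regions()] (0-based
#'   half-open), or `NULL` for none.
#' @param cohort The [yy_cohort()] (supplies lead-SNP call counts).
#' @param lead_call_min Minimum called unrelated subjects at the lead SNP
#'   (default 2000, appropriate for a 2504-subject cohort; scale to roughly
#'   80% of subjects for other cohort sizes).
#' @return The chain table with added columns `kept` (logical) and
#'   `discard_reason` (`NA`, `"alt_scaffold"` or `"low_call"`).
#' @export
apply_exclusions <- function(chains, regions, cohort, lead_call_min = 2000) {
  stopifnot(inherits(cohort, "yy_cohort"))
  reason <- rep(NA_character_, nrow(chains))
  if (!is.null(regions) && nrow(regions) > 0 && nrow(chains) > 0) {
    for (chr in unique(chains$chrom)) {
      ci <- which(chains$chrom == chr)
      ri <- which(regions$chrom == chr)
      if (!length(ri)) next
      q <- IRanges::IRanges(start = chains$start[ci], end = chains$end[ci])
      # regions are 0-based half-open; convert to 1-based inclusive
      subj <- IRanges::IRanges(start = regions$start[ri] + 1L,
                               end = regions$end[ri])
      hit <- IRanges::overlapsAny(q, subj)
      reason[ci[hit]] <- "alt_scaffold"
    }
  }
  if (nrow(chains) > 0) {
    calls <- cohort$variants$n_called[chains$lead_index]
    low <- is.na(reason) & calls < lead_call_min
    reason[low] <- "low_call"
  }
  chains$kept <- is.na(reason)
  chains$discard_reason <- reason
  chains
}
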