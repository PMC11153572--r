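# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can adjudicate the fast implementations.

# Element-wise average genotype distance.
oracle_distance <- function(a, b) {
  total <- 0
  n <- 0
  for (s in seq_along(a)) {
    if (!is.na(a[s]) && !is.na(b[s])) {
      total <- total + abs(a[s] - b[s])
      n <- n + 1
    }
  }
  if (n == 0) return(NA_real_)
  total / n
}

# Fixation index via the heterozygosity partition:
# F_ST = (H_T - H_S) / H_T with H_T = 2 pbar (1 - pbar),
# H_S = sum_i c_i 2 p_i (1 - p_i).
oracle_fst <- function(p, w) {
  c_i <- w / sum(w)
  pbar <- sum(c_i * p)
  h_t <- 2 * pbar * (1 - pbar)
  if (h_t == 0) return(NA_real_)
  h_s <- sum(c_i * 2 * p * (1 - p))
  (h_t - h_s) / h_t
}

# Greedy chain search from every start with explicit per-pair distances,
# then removal of chains contained in longer ones. Single chromosome.
oracle_chains <- function(g, threshold, min_snps, gap_max) {
  m <- ncol(g)
  found <- list()
  for (s in seq_len(m)) {
    mem <- s
    cur <- s
    repeat {
      if (cur >= m) break
      nxt <- NA
      for (j in seq(cur + 1, min(cur + gap_max + 1, m))) {
        d <- oracle_distance(g[, cur], g[, j])
        if (!is.na(d) && d <= threshold) {
          nxt <- j
          break
        }
      }
      if (is.na(nxt)) break
      mem <- c(mem, nxt)
      cur <- nxt
    }
    if (length(mem) >= min_snps) found[[length(found) + 1]] <- mem
  }
  keep <- rep(TRUE, length(found))
  for (a in seq_along(found)) {
    for (b in seq_along(found)) {
      if (a != b && length(found[[a]]) < length(found[[b]]) &&
          all(found[[a]] %in% found[[b]])) {
        keep[a] <- FALSE
      }
    }
  }
  found[keep]
}

# All-pairs interval overlap (1-based inclusive coordinates).
oracle_gene_overlap <- function(chains, genes) {
  out <- vector("list", nrow(chains))
  for (i in seq_len(nrow(chains))) {
    syms <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (chains$chrom[i] == genes$chrom[j] &&
          chains$start[i] <= genes$end[j] &&
          genes$start[j] <= chains$end[i]) {
        syms <- c(syms, genes$symbol[j])
      }
    }
    out[[i]] <- syms
  }
  out
}

# Independent validator of the chain definition: length, inter-member index
# gaps and consecutive-member distances.
validate_chain <- function(members, g, threshold, min_snps, gap_max) {
  if (length(members) < min_snps) return(FALSE)
  for (k in seq_len(length(members) - 1)) {
    if (members[k + 1] - members[k] > gap_max + 1) return(FALSE)
    d <- oracle_distance(g[, members[k]], g[, members[k + 1]])
    if (is.na(d) || d > threshold) return(FALSE)
  }
  TRUE
}

# Build a yy_cohort from a dosage matrix with auto-generated metadata.
make_cohort <- function(geno, pos = NULL, chrom = "1", superpop = NULL,
                        child = NULL, dp = NULL, ad_alt = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (length(chrom) == 1) chrom <- rep(chrom, m)
  if (is.null(superpop)) superpop <- rep("EUR", n)
  if (is.null(child)) child <- rep(FALSE, n)
  variants <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    id = paste0("v", seq_len(m)),
    ref = rep("A", m), alt = rep("G", m)
  )
  panel <- tibble::tibble(
    subject = sprintf("P%04d", seq_len(n)),
    pop = paste0(superpop, "1"), superpop = superpop, child = child
  )
  yy_cohort(variants, geno, panel, dp = dp, ad_alt = ad_alt)
}

# Dosage matrix with a perfect-LD block of `n_block` copies of one random
# column, interleaved with `gap` uncorrelated columns between members, plus
# flanking noise columns.
make_block_geno <- function(n_subjects, n_block, gap = 3, flank = 5,
                            p_block = 0.3) {
  block_col <- stats::rbinom(n_subjects, 2, p_block)
  noise <- function(k) {
    vapply(seq_len(k),
           function(i) stats::rbinom(n_subjects, 2, stats::runif(1, 0.2, 0.8)),
           integer(n_subjects))
  }
  cols <- list(noise(flank))
  member_idx <- integer(0)
  at <- flank
  for (b in seq_len(n_block)) {
    cols[[length(cols) + 1]] <- matrix(block_col, ncol = 1)
    at <- at + 1
    member_idx <- c(member_idx, at)
    if (b < n_block && gap > 0) {
      cols[[length(cols) + 1]] <- noise(gap)
      at <- at + gap
    }
  }
  cols[[length(cols) + 1]] <- noise(flank)
  list(geno = do.call(cbind, cols), members = member_idx)
}

# Planted-pair description rows for scenario_config().
pair_row <- function(n_snps, start, span, freq,
                     superpops = c("AFR", "AMR", "EAS", "EUR", "SAS"),
                     class = "derived", n_intermediates = 0L) {
  out <- tibble::tibble(
    n_snps = as.integer(n_snps), start = as.integer(start),
    span = as.integer(span), n_intermediates = as.integer(n_intermediates),
    outgroup_class = class
  )
  freq <- rep_len(freq, length(superpops))
  for (k in seq_along(superpops)) {
    out[[paste0("freq_", superpops[k])]] <- freq[k]
  }
  out
}

no_pairs <- function(superpops = c("AFR", "AMR", "EAS", "EUR", "SAS")) {
  pair_row(20L, 1L, 10L, 0.3, superpops)[0, ]
}

no_repeats <- function() {
  tibble::tibble(
    n_snps = integer(), start = integer(), span = integer(),
    het_fraction = numeric(), aa_fraction = numeric(),
    depth_mean = numeric(), depth_sd = numeric(),
    ab_mean = numeric(), ab_sd = numeric()
  )
}

# Quick small scenario for pipeline tests: trimmed subject count and
# densities so repeated simulation stays cheap.
small_scenario_config <- function(seed = 1, ...) {
  scenario_config(
    n_per_superpop = c(AFR = 40, AMR = 40, EAS = 40, EUR = 40, SAS = 40),
    n_children = 4,
    singleton_density = 1,
    doubleton_density = 0.5,
    common_density = 2e-4,
    seed = seed,
    ...
  )
}
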