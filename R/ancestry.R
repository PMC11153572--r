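# Ancestry classification of haplotype pairs against chimpanzee and Altai
# Neanderthal outgroup alleles. Informative sites are chain members called
# in both outgroups with an allele matching the VCF reference or alternate;
# each is categorised by where the alternate allele is observed, and the
# haplotype pair is classified from the multiset of categories.

#' Classify haplotype ancestry from outgroup alleles
#'
#' Each informative chain member (called in both outgroups, with both calls
#' matching the VCF reference or alternate allele) falls into one of four
#' categories: alternate allele in neither outgroup, in the chimpanzee only,
#' in the Neanderthal only, or in both. The haplotype pair is then
#' classified:
#' \describe{
#'   \item{derived}{every informative site is `alt_in_both` or every one is
#'     `alt_in_neither`: both outgroups carry the same full haplotype, so
#'     the other haplotype arose entirely in humans after the
#'     human-Neanderthal split;}
#'   \item{ancient}{one outgroup matches the all-reference haplotype at
#'     every informative site and the other the all-alternate haplotype:
#'     both haplotypes predate the split;}
#'   \item{mixed}{discordant sites in both directions (at least one
#'     chimp-only and one Neanderthal-only), suggesting recombination
#'     between earlier haplotypes;}
#'   \item{partial}{anything else: an outgroup carries a partial form of a
#'     haplotype;}
#'   \item{uninformative}{fewer than `min_informative` informative sites.}
#' }
#' Chains on the X chromosome are skipped (class `NA`, reason recorded), as
#' the outgroup comparison is restricted to autosomal variants.
#'
#' @param chains Chain table from [find_chains()].
#' @param cohort The [yy_cohort()] the chains were found in.
#' @param outgroups Outgroup allele table from [read_outgroup_table()] or
#'   [simulate_outgroups()].
#' @param min_informative Minimum informative sites for a classification
#'   (default 5).
#' @return Tibble: `chain_id`, `n_informative`, `n_alt_in_neither`,
#'   `n_alt_in_chimp_only`, `n_alt_in_neanderthal_only`, `n_alt_in_both`,
#'   `class`, `skip_reason`.
#' @export
classify_ancestry <- function(chains, cohort, outgroups, min_informative = 5) {
  stopifnot(inherits(cohort, "yy_cohort"))
  v <- cohort$variants
  key <- paste(outgroups$chrom, outgroups$pos)
  rows <- purrr::map(seq_len(nrow(chains)), function(r) {
    base <- tibble(
      chain_id = chains$chain_id[r], n_informative = 0L,
      n_alt_in_neither = 0L, n_alt_in_chimp_only = 0L,
      n_alt_in_neanderthal_only = 0L, n_alt_in_both = 0L,
      class = NA_character_, skip_reason = NA_character_
    )
    if (!is_autosome(chains$chrom[r])) {
      base$skip_reason <- "non_autosomal"
      return(base)
    }
    mem <- chains$members[[r]]
    hit <- match(paste(v$chrom[mem], v$pos[mem]), key)
    ok <- !is.na(hit)
    chimp <- outgroups$chimp_allele[hit[ok]]
    neand <- outgroups$neanderthal_allele[hit[ok]]
    ref <- v$ref[mem][ok]
    alt <- v$alt[mem][ok]
    informative <- (chimp == ref | chimp == alt) & (neand == ref | neand == alt)
    informative[is.na(informative)] <- FALSE
    chimp_alt <- chimp[informative] == alt[informative]
    neand_alt <- neand[informative] == alt[informative]
    base$n_informative <- sum(informative)
    base$n_alt_in_neither <- sum(!chimp_alt & !neand_alt)
    base$n_alt_in_chimp_only <- sum(chimp_alt & !neand_alt)
    base$n_alt_in_neanderthal_only <- sum(!chimp_alt & neand_alt)
    base$n_alt_in_both <- sum(chimp_alt & neand_alt)
    base$class <- ancestry_class(
      base$n_alt_in_neither, base$n_alt_in_chimp_only,
      base$n_alt_in_neanderthal_only, base$n_alt_in_both,
      min_informative
    )
    base
  })
  bind_rows(rows)
}

# Class from category counts; exported logic kept separate so it can be
# property-tested over arbitrary category multisets.
ancestry_class <- function(n_neither, n_chimp_only, n_neand_only, n_both,
                           min_informative = 5) {
  n_inf <- n_neither + n_chimp_only + n_neand_only + n_both
  if (n_inf < min_informative) return("uninformative")
  if (n_inf == n_both || n_inf == n_neither) return("derived")
  if (n_inf == n_chimp_only || n_inf == n_neand_only) return("ancient")
  if (n_chimp_only > 0 && n_neand_only > 0) return("mixed")
  "partial"
}
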