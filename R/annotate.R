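# Gene-overlap and GWAS-catalogue annotation of haplotype chains.

#' Annotate chains with overlapping genes
#'
#' A gene (first-exon start to last-exon end, 1-based inclusive) is listed
#' for a chain when the two intervals overlap by at least one base pair.
#'
#' @param chains Chain table.
#' @param genes Gene table from [read_gene_table()].
#' @return Tibble `chain_id`, `genes` (list-column of symbols), `n_genes`;
#'   the fraction of chains overlapping at least one gene is attached as
#'   attribute `gene_fraction`.
#' @export
annotate_genes <- function(chains, genes) {
  hits <- vector("list", nrow(chains))
  for (i in seq_len(nrow(chains))) hits[[i]] <- character(0)
  for (chr in unique(chains$chrom)) {
    ci <- which(chains$chrom == chr)
    gi <- which(genes$chrom == chr)
    if (!length(gi)) next
    q <- IRanges::IRanges(start = chains$start[ci], end = chains$end[ci])
    s <- IRanges::IRanges(start = genes$start[gi], end = genes$end[gi])
    ov <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (k in seq_along(qh)) {
      i <- ci[qh[k]]
      hits[[i]] <- c(hits[[i]], genes$symbol[gi[sh[k]]])
    }
  }
  out <- tibble(
    chain_id = chains$chain_id,
    genes = hits,
    n_genes = lengths(hits)
  )
  attr(out, "gene_fraction") <-
    if (nrow(out)) mean(out$n_genes > 0) else NA_real_
  out
}

#' Annotate chain lead SNPs with GWAS-catalogue traits
#'
#' Exact-identifier join of each chain's lead SNP against the association
#' table; a lead SNP reported for several traits yields one row per
#' association (multiplicity preserved).
#'
#' @param chains Chain table.
#' @param gwas Association table from [read_gwas_catalog()] (`snp`,
#'   `trait`).
#' @return Tibble `chain_id`, `lead_id`, `trait`, one row per association;
#'   chains without any association are absent.
#' @export
annotate_gwas <- function(chains, gwas) {
  joined <- chains %>%
    select(all_of(c("chain_id", "lead_id"))) %>%
    dplyr::inner_join(gwas, by = c(lead_id = "snp"),
                      relationship = "many-to-many")
  as_tibble(joined)
}
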