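# Readers and writers for the pipeline's external formats: VCF, subject
# panel, excluded-region BED, recombination map, outgroup alleles, gene
# intervals and GWAS-catalogue associations.

#' Read a multi-sample VCF into a cohort
#'
#' Loads biallelic SNPs from a VCF 4.x file (GT required; AD and DP consumed
#' when present), intersects its samples with a subject panel and returns a
#' [yy_cohort()]. Multi-allelic sites and indels are dropped. Sites are
#' returned sorted by (chromosome, position). Reference/alternate orientation
#' is taken from the VCF as-is; there is no re-polarisation to an ancestral
#' allele, because the yin-yang definition is in terms of reference and
#' alternate designations.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param panel Subject panel tibble from [read_panel()]; its subjects must be
#'   a subset of the VCF samples.
#' @param maf_min Optional minor-allele-frequency filter applied after
#'   loading via [filter_maf()]; `NULL` (default) keeps all sites so that
#'   rare variants remain available for background statistics.
#' @return A [yy_cohort()].
#' @export
read_cohort_vcf <- function(path, panel, maf_min = NULL) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  missing_subj <- setdiff(panel$subject, samples)
  if (length(missing_subj)) {
    abort(paste0("panel subjects absent from VCF: ",
                 paste(utils::head(missing_subj, 5), collapse = ", ")))
  }
  if (nrow(panel) == 0) abort("no subjects after panel intersection")

  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (!any(snp)) abort("VCF contains no biallelic SNPs")

  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, panel$subject, drop = FALSE]

  dosage_map <- c(
    "0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
    "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2,
    "0" = 0, "1" = 2
  )
  dm <- matrix(unname(dosage_map[gt]), nrow = nrow(gt))
  geno <- t(dm) # subjects x variants

  dp <- ad_alt <- NULL
  fmt_has <- function(key) {
    any(grepl(paste0("(^|:)", key, "(:|$)"), vcf@gt[snp, 1]))
  }
  if (fmt_has("AD")) {
    ad <- vcfR::extract.gt(vcf, element = "AD")[snp, panel$subject, drop = FALSE]
    ref_reads <- suppressWarnings(as.numeric(sub(",.*", "", ad)))
    alt_reads <- suppressWarnings(
      as.numeric(sub(",.*$", "", sub("^[^,]*,", "", ad))))
    ad_alt <- t(matrix(alt_reads, nrow = nrow(ad)))
    dp_from_ad <- t(matrix(ref_reads + alt_reads, nrow = nrow(ad)))
  } else {
    dp_from_ad <- NULL
  }
  if (fmt_has("DP")) {
    dpm <- vcfR::extract.gt(vcf, element = "DP",
                            as.numeric = TRUE)[snp, panel$subject, drop = FALSE]
    dp <- t(dpm)
  } else if (!is.null(dp_from_ad)) {
    dp <- dp_from_ad
  }

  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(id) | id == "."]
  variants <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = id,
    ref = fix$REF,
    alt = fix$ALT
  )
  cohort <- yy_cohort(variants, geno, panel, dp = dp, ad_alt = ad_alt)
  if (!is.null(maf_min)) cohort <- filter_maf(cohort, maf_min)
  cohort
}

#' Write a cohort back to VCF
#'
#' Emits an uncompressed VCF 4.2 with unphased GT calls (`./.` for missing)
#' and, when the cohort carries depth matrices, AD and DP FORMAT fields.
#' Round-trips with [read_cohort_vcf()]: reloading reproduces the dosage
#' matrix exactly.
#'
#' @param cohort A [yy_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  gt_str <- matrix("./.", nrow = nrow(cohort$geno), ncol = ncol(cohort$geno))
  gt_str[cohort$geno == 0] <- "0/0"
  gt_str[cohort$geno == 1] <- "0/1"
  gt_str[cohort$geno == 2] <- "1/1"
  has_depth <- !is.null(cohort$dp) && !is.null(cohort$ad_alt)
  if (has_depth) {
    dp <- cohort$dp
    ada <- cohort$ad_alt
    adr <- dp - ada
    cells <- matrix(
      paste0(gt_str, ":", ifelse(is.na(adr), ".", adr), ",",
             ifelse(is.na(ada), ".", ada), ":", ifelse(is.na(dp), ".", dp)),
      nrow = nrow(gt_str)
    )
    fmt <- "GT:AD:DP"
  } else {
    cells <- gt_str
    fmt <- "GT"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=yinyangscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_depth) c(
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
    ),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$panel$subject), collapse = "\t")
  )
  body <- paste(
    v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", fmt,
    apply(cells, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a subject panel
#'
#' Tab-separated file with columns `subject`, `pop`, `superpop` and either a
#' logical/0-1 `child` column or none (all subjects then treated as
#' unrelated). Children are excluded from every analysis except read-depth
#' summaries, which deliberately pool the full cohort.
#'
#' @param path Path to the panel TSV.
#' @return Tibble with columns `subject`, `pop`, `superpop`, `child`.
#' @export
read_panel <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab) <- tolower(names(tab))
  if ("sample" %in% names(tab) && !"subject" %in% names(tab)) {
    tab <- rename(tab, subject = "sample")
  }
  if ("super_pop" %in% names(tab) && !"superpop" %in% names(tab)) {
    tab <- rename(tab, superpop = "super_pop")
  }
  if (!all(c("subject", "pop", "superpop") %in% names(tab))) {
    abort("panel must have columns subject, pop, superpop")
  }
  if (!"child" %in% names(tab)) tab$child <- FALSE
  tab$child <- as.logical(tab$child) %in% TRUE
  select(tab, all_of(c("subject", "pop", "superpop", "child")))
}

#' Read an excluded-region list
#'
#' Three-column BED-like file (`chrom`, `start`, `end`), 0-based half-open,
#' mirroring lists of documented alternate scaffolds and patches. Candidate
#' haplotypes whose span overlaps any of these regions by at least one base
#' pair are discarded downstream.
#'
#' @param path Path to the interval file; an empty file yields an empty set.
#' @return Tibble `chrom`, `start`, `end`, sorted.
#' @export
read_excluded_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3 ||
        is.na(suppressWarnings(as.integer(p[2]))) ||
        is.na(suppressWarnings(as.integer(p[3])))) {
      abort(paste0("malformed interval at line ", i, ": ", lines[i]))
    }
  }
  out <- tibble(
    chrom = vapply(parts, `[`, "", 1),
    start = vapply(parts, function(p) as.integer(p[2]), 1L),
    end = vapply(parts, function(p) as.integer(p[3]), 1L)
  )
  if (any(out$end < out$start)) abort("excluded region with negative length")
  arrange(out, chrom_rank(.data$chrom), .data$start)
}

#' Read a recombination map
#'
#' Tab-separated columns `chrom`, `start`, `end` (bp, half-open) and `rate`
#' in cM/Mb. Within a chromosome intervals must not overlap; gaps are allowed
#' and contribute zero genetic length.
#'
#' @param path Path to the map TSV.
#' @return Tibble `chrom`, `start`, `end`, `rate`.
#' @export
read_recombination_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("chrom", "start", "end", "rate") %in% names(tab))) {
    abort("recombination map must have columns chrom, start, end, rate")
  }
  if (any(tab$rate < 0)) abort("recombination rates must be non-negative")
  tab <- arrange(tab, chrom_rank(.data$chrom), .data$start)
  ov <- tab %>%
    group_by(.data$chrom) %>%
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]))
  if (any(ov$bad)) abort("recombination map intervals overlap within a chromosome")
  select(tab, all_of(c("chrom", "start", "end", "rate")))
}

#' Read an outgroup allele table
#'
#' Per-site chimpanzee and Neanderthal allele calls: tab-separated columns
#' `chrom`, `pos`, `chimp_allele`, `neanderthal_allele` with nucleotides or
#' `.` for uncalled. Only positions present in the variant set are consulted
#' by the ancestry classifier; alleles matching neither the VCF reference nor
#' alternate render a site non-informative.
#'
#' @param path Path to the outgroup TSV.
#' @return Tibble `chrom`, `pos`, `chimp_allele`, `neanderthal_allele`.
#' @export
read_outgroup_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  names(tab) <- tolower(names(tab))
  need <- c("chrom", "pos", "chimp_allele", "neanderthal_allele")
  if (!all(need %in% names(tab))) {
    abort(paste("outgroup table must have columns:", paste(need, collapse = ", ")))
  }
  tab$pos <- as.integer(tab$pos)
  select(tab, all_of(need))
}

#' Read a gene interval table
#'
#' Tab-separated columns `symbol`, `chrom`, `start`, `end`, where the
#' interval runs from the start of the gene's first exon to the end of its
#' last exon (1-based inclusive).
#'
#' @param path Path to the gene TSV.
#' @return Tibble `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("symbol", "chrom", "start", "end") %in% names(tab))) {
    abort("gene table must have columns symbol, chrom, start, end")
  }
  if (any(tab$start >= tab$end)) abort("gene intervals must have start < end")
  select(tab, all_of(c("symbol", "chrom", "start", "end")))
}

#' Read a GWAS-catalogue association table
#'
#' Accepts the GWAS catalogue download format (columns `SNPS` and
#' `DISEASE/TRAIT`) or any TSV with columns named `snp` and `trait`
#' (case-insensitive). Rows with a missing identifier or trait are skipped
#' and their count reported.
#'
#' @param path Path to the associations TSV.
#' @return Tibble `snp`, `trait`, one row per reported association.
#' @export
read_gwas_catalog <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  lower <- tolower(names(tab))
  snp_col <- which(lower %in% c("snps", "snp", "snp_id"))[1]
  trait_col <- which(lower %in% c("disease/trait", "trait", "phenotype"))[1]
  if (is.na(snp_col) || is.na(trait_col)) {
    abort("GWAS table must have SNP and trait columns (e.g. SNPS, DISEASE/TRAIT)")
  }
  out <- tibble(snp = tab[[snp_col]], trait = tab[[trait_col]])
  bad <- is.na(out$snp) | is.na(out$trait) | out$snp == "" | out$trait == ""
  if (any(bad)) {
    inform(paste0("skipped ", sum(bad), " malformed GWAS row(s)"))
    out <- out[!bad, ]
  }
  out
}
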