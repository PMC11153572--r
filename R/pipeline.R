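# End-to-end orchestration: load -> distance scan -> chain search ->
# exclusions -> repeat filter -> metrics -> ancestry -> annotation, with a
# stage-count ledger that always balances.

#' Pipeline parameters
#'
#' Every tunable constant of the pipeline in one place. Defaults are the
#' canonical operating point for a 2504-subject cohort: MAF at least 0.1,
#' distance threshold 0.0015 over a 10-variant window, chains of at least
#' 20 SNPs with at most 9 intervening SNPs between consecutive members,
#' lead SNPs called in at least 2000 subjects, repeat filter at heterozygote
#' fraction 0.53 / 20 AA homozygotes / heterozygote depth 55.
#'
#' @param maf_min Global minor-allele-frequency floor for the scan.
#' @param distance_threshold Maximum average genotype distance between
#'   chained variants.
#' @param window Distance-scan window (following variants per variant).
#' @param min_snps Minimum SNPs per chain.
#' @param gap_max Maximum intervening SNPs between consecutive members.
#' @param lead_call_min Minimum called unrelated subjects at the lead SNP;
#'   scale to roughly 80% of subjects for cohorts of other sizes.
#' @param het_max,min_minor_hom,depth_flag Repeat-filter thresholds, see
#'   [classify_repeats()].
#' @param control_maf_tol Control-SNP MAF matching tolerance.
#' @param min_informative Minimum informative sites for ancestry
#'   classification.
#' @param genome_size Analysed genome size in bp for background densities
#'   (`NULL`: inferred from the data).
#' @param seed Seed for the pipeline's randomised steps (control-SNP
#'   tie-breaking).
#' @return A list of class `yy_params`.
#' @export
yy_params <- function(maf_min = 0.1, distance_threshold = 0.0015, window = 10,
                      min_snps = 20, gap_max = 9, lead_call_min = 2000,
                      het_max = 0.53, min_minor_hom = 20, depth_flag = 55,
                      control_maf_tol = 0.005, min_informative = 5,
                      genome_size = NULL, seed = 1L) {
  p <- list(
    maf_min = maf_min, distance_threshold = distance_threshold,
    window = window, min_snps = min_snps, gap_max = gap_max,
    lead_call_min = lead_call_min, het_max = het_max,
    min_minor_hom = min_minor_hom, depth_flag = depth_flag,
    control_maf_tol = control_maf_tol, min_informative = min_informative,
    genome_size = genome_size, seed = as.integer(seed)
  )
  num <- unlist(p[setdiff(names(p), "genome_size")])
  if (any(num <= 0)) abort("all pipeline thresholds must be positive")
  structure(p, class = "yy_params")
}

#' Run the full yin-yang haplotype pipeline
#'
#' Executes every stage on an in-memory cohort: MAF filter, windowed
#' distance scan, greedy chain search, region/callability exclusions,
#' repeat-artifact filter, per-haplotype metrics (genetic length, fixation
#' indices with matched control SNPs, background variation) and, when the
#' corresponding inputs are supplied, ancestry classification and gene/GWAS
#' annotation. A stage-count ledger records candidates, each discard class
#' and the final count; the identity `final = candidates - sum(discards)`
#' is asserted on every run.
#'
#' @param cohort Unfiltered [yy_cohort()] (rare variants are used for
#'   background statistics).
#' @param excluded_regions Optional excluded-region tibble
#'   ([read_excluded_regions()]).
#' @param recomb_map Optional recombination map
#'   ([read_recombination_map()]).
#' @param outgroups Optional outgroup allele table.
#' @param genes Optional gene interval table.
#' @param gwas Optional GWAS association table.
#' @param params A [yy_params()].
#' @return An object of class `yy_result`: list with `chains` (final
#'   haplotypes with metrics), `discarded` (with reasons), `candidates`
#'   (all chains pre-exclusion), `evidence` (repeat evidence + verdicts for
#'   all candidates surviving exclusions), `controls`, `background`,
#'   `ancestry`, `gene_annotation`, `gwas_annotation`, `ledger`, `params`.
#' @export
run_yinyang <- function(cohort, excluded_regions = NULL, recomb_map = NULL,
                        outgroups = NULL, genes = NULL, gwas = NULL,
                        params = yy_params()) {
  stopifnot(inherits(cohort, "yy_cohort"), inherits(params, "yy_params"))

  common <- filter_maf(cohort, params$maf_min)
  dist <- distance_table(common, window = max(params$window,
                                              params$gap_max + 1))
  cand <- find_chains(dist, common, threshold = params$distance_threshold,
                      min_snps = params$min_snps, gap_max = params$gap_max)
  cand <- apply_exclusions(cand, excluded_regions, common,
                           lead_call_min = params$lead_call_min)

  surviving <- cand[cand$kept, , drop = FALSE]
  evidence <- classify_repeats(
    repeat_evidence(surviving, common),
    het_max = params$het_max, min_minor_hom = params$min_minor_hom,
    depth_flag = params$depth_flag
  )
  verdict <- evidence$verdict[match(surviving$chain_id, evidence$chain_id)]
  surviving$discard_reason <- as.character(
    ifelse(verdict == "clean", NA_character_, verdict))
  surviving$kept <- is.na(surviving$discard_reason)

  final <- surviving[surviving$kept, , drop = FALSE]
  discarded <- bind_rows(cand[!cand$kept, , drop = FALSE],
                         surviving[!surviving$kept, , drop = FALSE])

  ledger <- tibble(
    stage = c("candidates", "discard_alt_scaffold", "discard_low_call",
              "discard_repeat_all_het", "discard_repeat_missing_hom",
              "discard_repeat_low_AA", "final"),
    count = c(
      nrow(cand),
      sum(cand$discard_reason == "alt_scaffold", na.rm = TRUE),
      sum(cand$discard_reason == "low_call", na.rm = TRUE),
      sum(verdict == "repeat_all_het"),
      sum(verdict == "repeat_missing_hom"),
      sum(verdict == "repeat_low_AA"),
      nrow(final)
    )
  )
  if (ledger_final(ledger$count[1], ledger$count[2:6]) != ledger$count[7]) {
    abort("internal error: stage-count ledger does not balance")
  }

  if (!is.null(recomb_map)) final <- genetic_length(final, recomb_map)
  if (nrow(final)) {
    fsts <- fst_table(final, common)
    final <- left_join(final, fsts, by = c("chain_id", "lead_id"))
    controls <- match_control_snps(final, common, tol = params$control_maf_tol,
                                   seed = params$seed)
    ctrl_ok <- !is.na(controls$control_index)
    if (any(ctrl_ok)) {
      cf <- snp_fst(controls$control_index[ctrl_ok], common)
      controls$control_fst_all <- NA_real_
      controls$control_fst_excl <- NA_real_
      controls$control_fst_all[ctrl_ok] <- cf$fst_all
      controls$control_fst_excl[ctrl_ok] <- cf$fst_excl
    } else {
      controls$control_fst_all <- NA_real_
      controls$control_fst_excl <- NA_real_
    }
    final <- left_join(
      final, select(controls, all_of(c("chain_id", "control_id",
                                       "control_maf", "control_fst_all",
                                       "control_fst_excl"))),
      by = "chain_id")
  } else {
    controls <- tibble()
  }

  background <- background_stats(final, cohort,
                                 genome_size = params$genome_size)
  ancestry <- if (!is.null(outgroups) && nrow(final)) {
    classify_ancestry(final, common, outgroups,
                      min_informative = params$min_informative)
  }
  gene_annotation <- if (!is.null(genes) && nrow(final)) {
    annotate_genes(final, genes)
  }
  gwas_annotation <- if (!is.null(gwas) && nrow(final)) {
    annotate_gwas(final, gwas)
  }

  structure(
    list(
      chains = final, discarded = discarded, candidates = cand,
      evidence = evidence, controls = controls, background = background,
      ancestry = ancestry, gene_annotation = gene_annotation,
      gwas_annotation = gwas_annotation, ledger = ledger, params = params
    ),
    class = "yy_result"
  )
}

#' Reconcile a filtering ledger
#'
#' The bookkeeping identity used throughout: the final haplotype count is
#' the candidate count minus every discard.
#'
#' @param candidates Number of candidate chains.
#' @param discards Vector of discard counts.
#' @return `candidates - sum(discards)`.
#' @export
ledger_final <- function(candidates, discards) {
  candidates - sum(discards)
}

#' @export
print.yy_result <- function(x, ...) {
  cat("<yy_result>\n")
  for (r in seq_len(nrow(x$ledger))) {
    cat(sprintf("  %-28s %6d\n", x$ledger$stage[r], x$ledger$count[r]))
  }
  invisible(x)
}

#' Summarise a pipeline result
#'
#' Prints the filtering ledger in pipeline order, means and sds of SNPs per
#' haplotype, span, genetic-map rate and fixation indices, the ancestry
#' class breakdown, the gene-overlap fraction and the background-density
#' matrix. Deterministic given the result.
#'
#' @param object A `yy_result`.
#' @param ... Unused.
#' @return `object`, invisibly.
#' @export
summary.yy_result <- function(object, ...) {
  print(object)
  ch <- object$chains
  if (nrow(ch)) {
    ms <- function(x) sprintf("%.3g (sd %.3g)", mean(x, na.rm = TRUE),
                              sd(x, na.rm = TRUE))
    cat("  SNPs per haplotype: ", ms(ch$n_snps), "\n", sep = "")
    cat("  span kb:            ", ms(ch$span / 1000), "\n", sep = "")
    if ("cM_per_Mb" %in% names(ch)) {
      cat("  cM/Mb:              ", ms(ch$cM_per_Mb), "\n", sep = "")
    }
    if ("fst_all" %in% names(ch)) {
      cat("  F_ST (all):         ", ms(ch$fst_all), "\n", sep = "")
      cat("  F_ST (excl AFR):    ", ms(ch$fst_excl), "\n", sep = "")
    }
  }
  if (!is.null(object$ancestry)) {
    tab <- table(object$ancestry$class, useNA = "no")
    cat("  ancestry classes:   ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (!is.null(object$gene_annotation)) {
    cat("  gene-overlap fraction: ",
        sprintf("%.3f", attr(object$gene_annotation, "gene_fraction")),
        "\n", sep = "")
  }
  cat("  background densities (per Mb per subject; het per Mb):\n")
  print(as.data.frame(object$background), row.names = FALSE, digits = 4)
  invisible(object)
}

#' Tidy the per-haplotype table of a result
#'
#' @param x A `yy_result`.
#' @param ... Unused.
#' @return One row per final haplotype with coordinates, size and all
#'   computed metrics; the `members` list-column is dropped.
#' @method tidy yy_result
#' @export
tidy.yy_result <- function(x, ...) {
  out <- x$chains
  out$members <- NULL
  out$lead_index <- NULL
  out$kept <- NULL
  out$discard_reason <- NULL
  if (!is.null(x$ancestry)) {
    out <- left_join(out,
                     select(x$ancestry, all_of(c("chain_id", "n_informative",
                                                 "class"))),
                     by = "chain_id")
  }
  if (!is.null(x$gene_annotation)) {
    out <- left_join(out,
                     select(x$gene_annotation, all_of(c("chain_id",
                                                        "n_genes"))),
                     by = "chain_id")
  }
  as_tibble(out)
}

#' One-row summary of a result
#'
#' @param x A `yy_result`.
#' @param ... Unused.
#' @return Tibble with candidate/final counts, discard totals, and means of
#'   haplotype size, span, genetic-map rate, fixation indices and the
#'   gene-overlap fraction.
#' @method glance yy_result
#' @export
glance.yy_result <- function(x, ...) {
  ch <- x$chains
  counts <- setNames(as.list(x$ledger$count), x$ledger$stage)
  tibble(
    n_candidates = counts$candidates,
    n_discarded = counts$candidates - counts$final,
    n_final = counts$final,
    mean_snps = if (nrow(ch)) mean(ch$n_snps) else NA_real_,
    mean_span_kb = if (nrow(ch)) mean(ch$span) / 1000 else NA_real_,
    mean_cm_per_mb = if (nrow(ch) && "cM_per_Mb" %in% names(ch)) {
      mean(ch$cM_per_Mb, na.rm = TRUE)
    } else NA_real_,
    mean_fst_all = if (nrow(ch) && "fst_all" %in% names(ch)) {
      mean(ch$fst_all, na.rm = TRUE)
    } else NA_real_,
    mean_fst_excl = if (nrow(ch) && "fst_excl" %in% names(ch)) {
      mean(ch$fst_excl, na.rm = TRUE)
    } else NA_real_,
    gene_fraction = if (!is.null(x$gene_annotation)) {
      attr(x$gene_annotation, "gene_fraction")
    } else NA_real_
  )
}

#' Write a result's report tables
#'
#' Emits stable TSVs: `haplotypes.tsv` (the tidy per-haplotype table),
#' `members.tsv` (chain id, chrom, pos, id per member SNP),
#' `discarded.tsv`, `evidence.tsv`, `ledger.tsv`, `background.tsv` and,
#' when present, `ancestry.tsv` and `gwas.tsv`. Byte-identical across reruns
#' on the same result.
#'
#' @param result A `yy_result`.
#' @param dir Output directory (created if needed).
#' @param cohort The cohort the result was computed from (supplies member
#'   coordinates); pass the same object given to [run_yinyang()].
#' @return `dir`, invisibly.
#' @export
write_yy_outputs <- function(result, dir, cohort) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  common <- filter_maf(cohort, result$params$maf_min)
  v <- common$variants
  readr::write_tsv(tidy(result), file.path(dir, "haplotypes.tsv"))
  members <- purrr::map2(result$chains$chain_id, result$chains$members,
    function(id, mem) {
      tibble(chain_id = id, chrom = v$chrom[mem], pos = v$pos[mem],
             id = v$id[mem])
    })
  readr::write_tsv(bind_rows(members), file.path(dir, "members.tsv"))
  disc <- result$discarded
  disc$members <- NULL
  readr::write_tsv(disc, file.path(dir, "discarded.tsv"))
  readr::write_tsv(result$evidence, file.path(dir, "evidence.tsv"))
  readr::write_tsv(result$ledger, file.path(dir, "ledger.tsv"))
  readr::write_tsv(result$background, file.path(dir, "background.tsv"))
  if (!is.null(result$ancestry)) {
    readr::write_tsv(result$ancestry, file.path(dir, "ancestry.tsv"))
  }
  if (!is.null(result$gwas_annotation)) {
    readr::write_tsv(result$gwas_annotation, file.path(dir, "gwas.tsv"))
  }
  invisible(dir)
}
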