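# ggplot2 views of a pipeline result.

#' Histogram of haplotype sizes and spans
#'
#' @param result A `yy_result`.
#' @param bins Histogram bin count.
#' @return A ggplot object: SNPs per haplotype and span (kb) side by side.
#' @export
plot_chain_spans <- function(result, bins = 30) {
  ch <- result$chains
  df <- bind_rows(
    tibble(metric = "SNPs per haplotype", value = as.numeric(ch$n_snps)),
    tibble(metric = "span (kb)", value = ch$span / 1000)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "haplotypes") +
    ggplot2::theme_minimal()
}

#' Fixation-index comparison: haplotype lead SNPs vs matched controls
#'
#' @param result A `yy_result` computed with control SNPs.
#' @return A ggplot density plot of the global fixation index for lead and
#'   control SNPs.
#' @export
plot_fst <- function(result) {
  ch <- result$chains
  if (!all(c("fst_all", "control_fst_all") %in% names(ch))) {
    abort("result carries no fixation-index columns")
  }
  df <- bind_rows(
    tibble(set = "lead SNPs", fst = ch$fst_all),
    tibble(set = "control SNPs", fst = ch$control_fst_all)
  )
  df <- df[!is.na(df$fst), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fst, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = expression(F[ST]), y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_chain_spans `autoplot` method dispatching on the result:
#'   `type = "spans"` (default) or `"fst"`.
#' @param object A `yy_result`.
#' @param type Which view to draw.
#' @param ... Unused.
#' @method autoplot yy_result
#' @export
autoplot.yy_result <- function(object, type = c("spans", "fst"), ...) {
  type <- match.arg(type)
  switch(type, spans = plot_chain_spans(object), fst = plot_fst(object))
}
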