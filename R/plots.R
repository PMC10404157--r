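#' @import ggplot2
NULL

#' Composition sweep of mixture binding
#'
#' Median measured binding (with replicate interquartile ranges) as the
#' composition moves from 100% of one subclass to 100% of the other, one
#' panel per valency.
#'
#' @param tbl measurement table.
#' @param receptor_label receptor variant to show.
#' @param pair_label subclass pair, e.g. `"IgG1/IgG2"`.
#' @return a ggplot.
#' @export
plot_mixture_binding <- function(tbl, receptor_label, pair_label) {
  d <- tbl |>
    dplyr::filter(.data$receptor == receptor_label,
                  .data$pair == pair_label) |>
    dplyr::group_by(.data$valency, .data$frac1) |>
    dplyr::summarise(m = stats::median(.data$rfu),
                     lo = stats::quantile(.data$rfu, 0.25),
                     hi = stats::quantile(.data$rfu, 0.75),
                     .groups = "drop")
  ggplot(d, aes(x = .data$frac1, y = .data$m)) +
    geom_line() +
    geom_pointrange(aes(ymin = .data$lo, ymax = .data$hi)) +
    facet_wrap(~ valency, scales = "free_y",
               labeller = label_both) +
    scale_y_log10() +
    labs(x = paste0("fraction ", sub("/.*$", "", pair_label)),
         y = "normalized RFU",
         title = paste(pair_label, "binding to", receptor_label))
}

#' @describeIn sample_posterior Posterior interval plot: affinity posteriors
#'   against their documented priors (when the regime fit them), otherwise
#'   all free parameters.
#' @param object an `fcr_posterior`.
#' @exportS3Method
autoplot.fcr_posterior <- function(object, ...) {
  td <- tidy(object)
  ka <- grepl("^logka\\[", td$parameter)
  if (any(ka)) {
    td <- td[ka, ]
    lab <- sub("^logka\\[(.+)\\]$", "\\1", td$parameter)
    parts <- strsplit(lab, ",", fixed = TRUE)
    td$ligand <- vapply(parts, `[`, "", 1L)
    td$receptor <- vapply(parts, `[`, "", 2L)
    pr <- object$ctx
    prior <- tibble::tibble(
      ligand = rep(pr$ligands, times = length(pr$receptors)),
      receptor = rep(pr$receptors, each = length(pr$ligands)),
      mu = as.numeric(pr$mu$logka))
    ggplot(td, aes(x = .data$receptor, y = .data$median / log(10))) +
      geom_pointrange(aes(ymin = .data$q25 / log(10),
                          ymax = .data$q75 / log(10))) +
      geom_point(data = prior, aes(y = .data$mu / log(10)),
                 colour = "grey50", shape = 4) +
      facet_wrap(~ ligand) +
      labs(y = "log10 Ka (posterior median, IQR; x = prior mean)",
           x = NULL) +
      theme(axis.text.x = element_text(angle = 45, hjust = 1))
  } else {
    ggplot(td, aes(x = .data$parameter, y = .data$median)) +
      geom_pointrange(aes(ymin = .data$q25, ymax = .data$q75)) +
      coord_flip() +
      labs(x = NULL, y = "posterior (log scale)")
  }
}

#' @describeIn fit_depletion_weights Per-(treatment, cell type) effect plot,
#'   posterior medians with interquartile bars.
#' @param object an `fcr_depletion_fit`.
#' @exportS3Method
autoplot.fcr_depletion_fit <- function(object, ...) {
  eff <- cell_type_effects(object)
  ggplot(eff, aes(x = .data$treatment, y = .data$effect_median,
                  fill = .data$cell)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$effect_lo, ymax = .data$effect_hi),
                  position = position_dodge(width = 0.8), width = 0.25) +
    labs(x = NULL, y = "cell type effect (w x activity)")
}

#' @describeIn validate_with_fixed_affinities Measured versus predicted
#'   binding on log axes.
#' @param object an `fcr_validation`.
#' @exportS3Method
autoplot.fcr_validation <- function(object, ...) {
  ggplot(object$predictions, aes(x = .data$pred, y = .data$rfu)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point(alpha = 0.6) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "predicted binding", y = "measured RFU",
         subtitle = sprintf("log-scale Pearson r = %.3f", object$concordance))
}
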