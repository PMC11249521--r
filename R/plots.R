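# ggplot2 displays for the main result types.

#' Volcano-style display of the metabolite screen
#'
#' @param results Screen results from [screen_metabolites()].
#' @param eff Optional [effective_tests()] object; adds the adjusted
#'   significance threshold line.
#' @return A ggplot object.
#' @export
plot_screen <- function(results, eff = NULL) {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = .data$beta,
                                    y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "Smoking effect (SD units)",
                  y = expression(-log[10](p)),
                  title = unique(results$contrast))
  if (!is.null(eff)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(eff$alpha_adjusted),
                                 linetype = "dashed")
  }
  p
}

#' @export
autoplot.signature_model <- function(object, ...) {
  df <- tibble(metabolite = names(object$weights),
               weight = unname(object$weights)) %>%
    arrange(.data$weight) %>%
    mutate(metabolite = factor(.data$metabolite, levels = .data$metabolite))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$metabolite)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Elastic-net weight", y = NULL,
                  title = "Metabolic signature weights")
}

#' @export
autoplot.mediation_fit <- function(object, ...) {
  df <- tidy(object) %>% filter(.data$quantity != "proportion_mediated")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$quantity)) +
    ggplot2::geom_point() +
    { if ("ci_low" %in% names(df))
        ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                             xmax = .data$ci_high),
                                height = 0.15) } +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio", y = NULL,
                  title = "Natural effects decomposition")
}

#' @export
autoplot.interaction_fit <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(cell = paste(.data$grs_category, .data$signature_level, sep = "/"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr, y = .data$cell)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.15) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (vs low/low)", y = "GRS / signature",
                  title = "Joint genetic risk x metabolic signature")
}
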