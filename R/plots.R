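#' Plot a per-frame RMSD profile
#'
#' One trace per run of the C-alpha RMSD against the chosen reference
#' structure; flat low traces indicate a rigid loop.
#'
#' @param object A [rmsd_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rigidity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$rmsd,
                                       colour = factor(.data$run))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(
      x = "Frame", y = "Cα RMSD (Å)", colour = "Run",
      title = sprintf("RMSD vs %s structure, chain %s",
                      attr(object, "reference"), attr(object, "chain_id"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a hydrogen-bond network summary
#'
#' Replicate-mean per-frame bond counts by class with SEM error bars.
#'
#' @param object A [summarize_hbonds()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hbond_summary <- function(object, ...) {
  cs <- dplyr::filter(object$class_summary,
                      .data$bond_class != "other" | .data$mean_count > 0)
  ggplot2::ggplot(cs, ggplot2::aes(x = .data$bond_class,
                                   y = .data$mean_count)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_count - .data$sem_count,
                   ymax = .data$mean_count + .data$sem_count),
      width = 0.15, na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = "Mean bonds per frame (± SEM)") +
    ggplot2::theme_minimal()
}

#' Plot the rigidity-potency relationship of a screen
#'
#' Mean internal, intermolecular and total hydrogen-bond counts of each
#' assayed variant against its inhibition constant (log scale).
#'
#' @param object A [build_screen_report()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_report <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$ki_nM)) |>
    dplyr::mutate(total = .data$internal_mean + .data$intermolecular_mean) |>
    tidyr::pivot_longer(c("internal_mean", "intermolecular_mean", "total"),
                        names_to = "measure", values_to = "bonds") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
                                          internal_mean = "internal",
                                          intermolecular_mean = "intermolecular"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ki_nM, y = .data$bonds,
                                   shape = .data$measure)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(K[i] ~ "(nM)"),
                  y = "Mean hydrogen bonds per frame", shape = NULL) +
    ggplot2::theme_minimal()
}
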