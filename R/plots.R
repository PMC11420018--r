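#' Centrality plot (strength and bridge strength)
#'
#' Dot plot of z-scored strength and bridge strength per node, grouped by
#' node group, in the style of the usual psychometric-network centrality
#' figure.
#'
#' @param centrality a data.frame from [centrality_table()].
#' @return A ggplot object.
#' @export
plot_centrality <- function(centrality) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  long <- rbind(
    data.frame(node_id = centrality$node_id, group = centrality$group,
               measure = "strength", value = centrality$strength_z),
    data.frame(node_id = centrality$node_id, group = centrality$group,
               measure = "bridge strength", value = centrality$bridge_strength_z))
  long$node_id <- factor(long$node_id,
                         levels = centrality$node_id[order(centrality$strength)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$node_id,
                                     colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(ggplot2::aes(group = .data$node_id), colour = "grey70") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "z-score", y = NULL) +
    ggplot2::theme_minimal()
}

#' ESA profile plot (three-scenario panels)
#'
#' One panel per scenario; each line traces a strategy's expected symptom
#' activity over its clamped sum-score range, with the baseline as a
#' horizontal reference.
#'
#' @param profiles list of `esa_profile`s (e.g. `bundle$esa_profiles`).
#' @return A ggplot object.
#' @export
plot_esa_profiles <- function(profiles) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tab <- esa_profiles_table(profiles)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$sum_score, y = .data$esa,
                                    colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$baseline),
                        colour = "grey50", linetype = "dashed") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "conditioned sum-score", y = "expected symptom activity") +
    ggplot2::theme_minimal()
}
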