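#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text
#'   scale_fill_gradient scale_fill_gradient2 labs theme_minimal
#'   geom_col coord_flip
NULL

#' @export
ggplot2::autoplot

#' Heatmap of pairwise head-domain identities
#'
#' @param object An `identity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot identity_matrix
#' @export
autoplot.identity_matrix <- function(object, ...) {
  long <- tidyr::expand_grid(id_a = object$ids, id_b = object$ids) |>
    mutate(identity_pct = as.vector(object$identity))
  ggplot(long, aes(x = .data$id_a, y = .data$id_b, fill = .data$identity_pct)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "steelblue4",
                        limits = c(0, 100), name = "identity %") +
    labs(x = NULL, y = NULL, title = "Pairwise head-domain identity") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Group sizes of an RBP classification
#'
#' @param object An `rbp_grouping`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rbp_grouping
#' @export
autoplot.rbp_grouping <- function(object, ...) {
  counts <- object$assignment |>
    dplyr::count(.data$group, name = "size") |>
    arrange(dplyr::desc(.data$size))
  ggplot(counts, aes(x = stats::reorder(.data$group, .data$size),
                     y = .data$size)) +
    geom_col(fill = "steelblue4") +
    coord_flip() +
    labs(x = "RBP group", y = "members",
         title = "RBP group sizes") +
    theme_minimal()
}

#' Relative binding-affinity heatmap
#'
#' One tile per (RBP, strain); the optimal host of each RBP scores 100.
#'
#' @param object A `binding_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binding_matrix
#' @export
autoplot.binding_matrix <- function(object, ...) {
  ggplot(object$scores,
         aes(x = .data$strain_id, y = .data$rbp_id,
             fill = .data$relative_score_pct)) +
    geom_tile() +
    geom_text(aes(label = ifelse(.data$optimal_host, "*", "")), size = 6) +
    scale_fill_gradient(low = "white", high = "darkgreen",
                        limits = c(0, 100), name = "score %",
                        na.value = "grey85") +
    labs(x = "strain", y = "GFP-RBP fusion",
         title = "Relative binding-affinity scores",
         subtitle = "* optimal host (score 100)") +
    theme_minimal()
}

#' Relative abundance bar plot
#'
#' @param tab The tibble returned by [relative_abundance()].
#' @return A ggplot object.
#' @export
plot_abundance <- function(tab) {
  ggplot(tab, aes(x = stats::reorder(.data$category,
                                     .data$relative_abundance_pct),
                  y = .data$relative_abundance_pct)) +
    geom_col(fill = "steelblue4") +
    coord_flip() +
    labs(x = NULL, y = "relative abundance (%)",
         title = "Filtered read-mapping relative abundance") +
    theme_minimal()
}
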