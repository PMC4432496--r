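# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_rect geom_text geom_col
#'   geom_segment geom_point geom_hline facet_wrap labs theme_minimal
#'   scale_fill_brewer coord_cartesian
NULL

#' Plot a repeat schema as a token track
#'
#' One horizontal track per element; tokens drawn as tiles along the
#' sequence, labelled with their RU code and shaded by type.
#'
#' @param object A `vntr_schema`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vntr_schema
#' @export
autoplot.vntr_schema <- function(object, ...) {
  tb <- as_tibble(object) |>
    mutate(label = token_label(.data$type_code, .data$variant_tag))
  ggplot(tb, aes(xmin = .data$start, xmax = .data$end,
                 ymin = 0, ymax = 1, fill = .data$type_code)) +
    geom_rect(colour = "grey30", linewidth = 0.2) +
    geom_text(aes(x = (.data$start + .data$end) / 2, y = 0.5,
                  label = .data$label), size = 2.6) +
    facet_wrap(~element_id, ncol = 1, strip.position = "left") +
    labs(x = "position (bp)", y = NULL, fill = "RU type") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
}

#' Plot conserved-array support
#'
#' Per-position support of the derived 5' and 3' arrays against the
#' conservation threshold.
#'
#' @param object An `array_consensus`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot array_consensus
#' @export
autoplot.array_consensus <- function(object, ...) {
  tb <- bind_rows(
    object$prefix |> mutate(side = "5' array"),
    object$suffix |> mutate(side = "3' array")
  )
  if (!nrow(tb)) abort("no conserved array to plot")
  tb <- tb |>
    mutate(label = token_label(.data$type_code, .data$variant_tag),
           slot = seq_len(dplyr::n()))
  ggplot(tb, aes(x = factor(.data$position), y = .data$support)) +
    geom_col(fill = "grey70", colour = "grey30") +
    geom_text(aes(label = .data$label, y = .data$support / 2), size = 3) +
    geom_hline(yintercept = object$theta, linetype = 2) +
    facet_wrap(~side, scales = "free_x") +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "array position", y = "support",
         title = paste0(object$subfamily, " conserved RU arrays")) +
    theme_minimal()
}

#' Plot called indel events along the pair
#'
#' Event segments on the carrier sequence, with point size showing the
#' relaxed breakpoint microhomology.
#'
#' @param object A `vntr_events` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vntr_events
#' @export
autoplot.vntr_events <- function(object, ...) {
  tb <- as_tibble(object)
  if (!nrow(tb)) abort("no events to plot")
  tb$label <- map_chr(tb$labels, paste, collapse = "\n")
  ggplot(tb, aes(y = .data$carrier)) +
    geom_segment(aes(x = .data$start, xend = .data$end,
                     yend = .data$carrier), linewidth = 3,
                 colour = "grey40") +
    geom_point(aes(x = .data$start, size = .data$mh_relaxed),
               colour = "black") +
    geom_text(aes(x = (.data$start + .data$end) / 2, label = .data$label),
              vjust = -0.8, size = 2.6) +
    labs(x = "position on carrier (bp)", y = NULL,
         size = "microhomology (bp)") +
    theme_minimal()
}

#' @rdname autoplot.vntr_schema
#' @param schema A `vntr_schema`.
#' @export
plot_schema <- function(schema, ...) autoplot.vntr_schema(schema, ...)

#' @rdname autoplot.array_consensus
#' @param consensus An `array_consensus`.
#' @export
plot_arrays <- function(consensus, ...) {
  autoplot.array_consensus(consensus, ...)
}

#' @rdname autoplot.vntr_events
#' @param events A `vntr_events` tibble.
#' @export
plot_events <- function(events, ...) autoplot.vntr_events(events, ...)
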