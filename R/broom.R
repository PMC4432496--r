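# broom-style summaries of the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an RU library into one row per entry
#'
#' @param x An `ru_library`.
#' @param ... Unused.
#' @return A tibble with `code`, `tag`, `kind` (base/variant), `length`,
#'   `consensus`, `family_scope`, `parents`.
#' @method tidy ru_library
#' @export
tidy.ru_library <- function(x, ...) {
  bind_rows(
    tibble(code = x$units$code, tag = "", kind = "base",
           length = x$units$length, consensus = x$units$consensus,
           family_scope = x$units$family_scope,
           parents = map_chr(x$units$parents, paste, collapse = ",")),
    tibble(code = x$variants$base_code, tag = x$variants$tag,
           kind = "variant", length = x$variants$length,
           consensus = x$variants$consensus,
           family_scope = x$units$family_scope[
             match(x$variants$base_code, x$units$code)],
           parents = "")
  )
}

#' @rdname tidy.ru_library
#' @method glance ru_library
#' @export
glance.ru_library <- function(x, ...) {
  tibble(
    name = x$name,
    n_types = nrow(x$units),
    n_variants = nrow(x$variants),
    min_length = min(x$units$length),
    max_length = max(x$units$length)
  )
}

#' Tidy an array consensus into one row per conserved position
#'
#' @param x An `array_consensus`.
#' @param ... Unused.
#' @return A tibble with `side`, `position`, `type_code`, `variant_tag`,
#'   `support`.
#' @method tidy array_consensus
#' @export
tidy.array_consensus <- function(x, ...) {
  bind_rows(
    x$prefix |> mutate(side = "prefix"),
    x$suffix |> mutate(side = "suffix"),
    x$alt_prefix |> mutate(side = "alt_prefix")
  ) |>
    select("side", "position", "type_code", "variant_tag", "support")
}

#' @rdname tidy.array_consensus
#' @method glance array_consensus
#' @export
glance.array_consensus <- function(x, ...) {
  tibble(
    subfamily = x$subfamily,
    n_elements = x$n_elements,
    theta = x$theta,
    prefix_length = nrow(x$prefix),
    suffix_length = nrow(x$suffix),
    prefix_code = render_array(x, "prefix"),
    suffix_code = render_array(x, "suffix"),
    n_alt = x$n_alt
  )
}

#' Summarise a schema table
#'
#' @param x A `vntr_schema`.
#' @param ... Unused.
#' @return One row per element: token count, unclassified fraction, mean
#'   identity, total length.
#' @method glance vntr_schema
#' @export
glance.vntr_schema <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$element_id) |>
    summarise(
      n_tokens = dplyr::n(),
      frac_unclassified = mean(.data$type_code == "X"),
      mean_identity = mean(.data$identity),
      length_bp = max(.data$end),
      .groups = "drop"
    )
}

#' Summarise called events for a pair
#'
#' @param x A `vntr_events` tibble.
#' @param ... Unused.
#' @return One row: event count, length and microhomology ranges, label
#'   tallies.
#' @method glance vntr_events
#' @export
glance.vntr_events <- function(x, ...) {
  tb <- as_tibble(x)
  labs <- unlist(tb$labels)
  tibble(
    n_events = nrow(tb),
    min_length = if (nrow(tb)) min(tb$length) else NA_integer_,
    max_length = if (nrow(tb)) max(tb$length) else NA_integer_,
    min_mh = if (nrow(tb)) min(tb$mh_relaxed) else NA_integer_,
    max_mh = if (nrow(tb)) max(tb$mh_relaxed) else NA_integer_,
    n_mh_mediated = sum(labs == "mh_mediated"),
    n_precise_ru = sum(labs == "precise_ru_indel"),
    n_slippage_compatible = sum(labs == "slippage_compatible"),
    n_nahr_compatible = sum(labs == "nahr_compatible")
  )
}
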