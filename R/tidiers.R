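#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a split-read signature
#'
#' @param x An `sv_signature`.
#' @param ... Unused.
#' @return The junction-pattern tibble (one row per orientation-invariant
#'   pattern with representative coordinates and read support).
#' @export
tidy.sv_signature <- function(x, ...) {
  x$patterns
}

#' @rdname tidy.sv_signature
#' @export
glance.sv_signature <- function(x, ...) {
  tibble(
    n_patterns = nrow(x$patterns),
    n_patterns_used = sum(x$patterns$used),
    n_columns = x$n_columns,
    n_reads_used = x$n_reads_used,
    n_reads_excluded = x$n_reads_excluded,
    window = x$window
  )
}

#' Tidy a column set
#'
#' @param x An `sv_columns` object.
#' @param ... Unused.
#' @return The column tibble.
#' @export
tidy.sv_columns <- function(x, ...) {
  x$columns
}

#' @rdname tidy.sv_columns
#' @export
glance.sv_columns <- function(x, ...) {
  tibble(
    n_columns = nrow(x$columns),
    n_clusters = nrow(x$clusters),
    n_pairings = nrow(x$pairing),
    total_support = sum(x$columns$support)
  )
}

#' Tidy calls
#'
#' @param x An `sv_calls` tibble.
#' @param ... Unused.
#' @return A plain tibble with alternatives flattened to a comma-separated
#'   string.
#' @export
tidy.sv_calls <- function(x, ...) {
  tibble::as_tibble(x) %>%
    mutate(alternatives = map_chr(.data$alternatives,
                                  function(a) paste(a, collapse = ",")))
}

#' @rdname tidy.sv_calls
#' @export
glance.sv_calls <- function(x, ...) {
  tibble(
    n_calls = nrow(x),
    types = paste(unique(x$type), collapse = ","),
    total_support = sum(x$support, na.rm = TRUE),
    n_ambiguous = sum(lengths(x$alternatives) > 0)
  )
}
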