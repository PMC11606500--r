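#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a neighbor-enrichment result
#'
#' @param x A `tcr_enrichment` tibble.
#' @param ... Ignored.
#' @return A plain tibble, one row per tested clone.
#' @method tidy tcr_enrichment
#' @export
tidy.tcr_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a neighbor-enrichment run
#'
#' @param x A `tcr_enrichment` tibble.
#' @param ... Ignored.
#' @return A tibble with the run scope and the number of enriched clones.
#' @method glance tcr_enrichment
#' @export
glance.tcr_enrichment <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_clones = p$n_clones, n_background = p$n_background,
         radius = p$radius, alpha = p$alpha,
         n_significant = sum(x$significant),
         frac_significant = mean(x$significant))
}

#' Tidy a clone-dynamics result
#'
#' @param x A `tcr_dynamics` tibble.
#' @param ... Ignored.
#' @return A plain tibble, one row per clone in either sample.
#' @method tidy tcr_dynamics
#' @export
tidy.tcr_dynamics <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of paired clone dynamics
#'
#' @param x A `tcr_dynamics` tibble.
#' @param ... Ignored.
#' @return A tibble with clone totals and selection counts.
#' @method glance tcr_dynamics
#' @export
glance.tcr_dynamics <- function(x, ...) {
  f <- attr(x, "filters")
  tibble(n_clones = nrow(x), n_selected = sum(x$selected),
         n_expanded = sum(x$selected & x$direction == "expanded"),
         n_contracted = sum(x$selected & x$direction == "contracted"),
         min_freq = f$min_freq, min_fold = f$min_fold)
}

#' Tidy a cluster table
#'
#' @param x A `tcr_clusters` tibble.
#' @param ... Ignored.
#' @return The cluster table without the list-columns.
#' @method tidy tcr_clusters
#' @export
tidy.tcr_clusters <- function(x, ...) {
  out <- as_tibble(x) %>% select(-"motif", -"members")
  class(out) <- class(tibble())
  out
}

#' One-row summary of a clustering run
#'
#' @param x A `tcr_clusters` tibble.
#' @param ... Ignored.
#' @return A tibble with cluster counts and sizes.
#' @method glance tcr_clusters
#' @export
glance.tcr_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         n_clustered_items = sum(x$n_members),
         n_singletons = length(attr(x, "singletons") %||% integer()),
         largest = if (nrow(x) > 0) max(x$n_members) else 0L)
}
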