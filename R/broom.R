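#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the node table of a genealogy
#'
#' @param x A [gen_tables] object.
#' @param ... Ignored.
#' @return The annotated node tibble of [nodes_table()].
#' @export
tidy.gen_tables <- function(x, ...) nodes_table(x)

#' One-row summary of a genealogy
#'
#' @param x A [gen_tables] object.
#' @param ... Ignored.
#' @return A one-row tibble: node/sample/edge/site counts, number of
#'   marginal trees, and sequence length.
#' @export
glance.gen_tables <- function(x, ...) {
  n_trees <- length(unique(c(0, x$edges$left, x$edges$right, x$L))) - 1L
  tibble::tibble(nodes = nrow(x$nodes), samples = sum(x$nodes$sample),
                 individuals = nrow(x$individuals), edges = nrow(x$edges),
                 sites = nrow(x$sites), trees = n_trees, L = x$L)
}

#' Tidy the final state of a simulation
#'
#' @param x A `popscape_sim` result.
#' @param ... Ignored.
#' @return Tibble of individuals alive at the end (population, location,
#'   tracked ancestry).
#' @export
tidy.popscape_sim <- function(x, ...) x$state

#' One-row summary of a simulation run
#'
#' @param x A `popscape_sim` result.
#' @param ... Ignored.
#' @export
glance.popscape_sim <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(generations = x$final_gen, seed = x$seed %||% NA_integer_,
                   dispersal_rejections = x$dispersal_rejections),
    glance.gen_tables(x$tables))
}
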