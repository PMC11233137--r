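#' Plot a world and its habitable regions
#'
#' @param object A [world()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.popscape_world <- function(object, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::annotate("rect", xmin = object$xmin, xmax = object$xmax,
                      ymin = object$ymin, ymax = object$ymax,
                      fill = "grey95", colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (map units)", y = "y (map units)") +
    ggplot2::theme_minimal()
  for (r in object$habitable) {
    df <- data.frame(x = r$coords[, 1], y = r$coords[, 2], name = r$name)
    p <- p + ggplot2::geom_polygon(data = df,
                                   ggplot2::aes(x = .data$x, y = .data$y),
                                   fill = "lightsteelblue", colour = "steelblue",
                                   alpha = 0.6)
  }
  p
}

#' Plot the demographic structure of a compiled model
#'
#' Populations are drawn as vertical lifespan bars over time with split
#' edges to their parents and arrows for gene-flow events.
#'
#' @param object A compiled `popscape_model`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.popscape_model <- function(object, ...) {
  pops <- object$pops
  pos <- stats::setNames(seq_len(nrow(pops)), pops$name)
  df <- tibble::tibble(
    pop = pops$name, x = pos[pops$name],
    t0 = from_generations(object, pops$start_gen),
    t1 = from_generations(object, pops$end_gen))
  splits <- dplyr::filter(df, !is.na(pops$parent))
  splits$xend <- pos[pops$parent[!is.na(pops$parent)]]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = df,
      ggplot2::aes(x = .data$x, xend = .data$x, y = .data$t0, yend = .data$t1,
                   colour = .data$pop), linewidth = 2) +
    ggplot2::geom_segment(data = splits,
      ggplot2::aes(x = .data$xend, xend = .data$x, y = .data$t0, yend = .data$t0),
      linetype = "dashed", colour = "grey40")
  if (nrow(object$geneflow) > 0) {
    gf <- object$geneflow
    gdf <- tibble::tibble(
      x = pos[gf$from], xend = pos[gf$to],
      y = from_generations(object, as.integer((gf$start_gen + gf$end_gen) / 2)),
      rate = gf$rate)
    p <- p + ggplot2::geom_segment(data = gdf,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt")), colour = "red3")
  }
  p +
    ggplot2::scale_x_continuous(breaks = pos, labels = names(pos)) +
    {if (object$direction == "backward") ggplot2::scale_y_reverse()} +
    ggplot2::labs(x = NULL, y = sprintf("time (%s)", object$direction),
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' Map of population ranges at a given time
#'
#' @param model A compiled spatial `popscape_model`.
#' @param time Time in user units (default: the model start).
#' @return A ggplot object.
#' @export
plot_map <- function(model, time = NULL) {
  if (is.null(model$world)) stop("plot_map needs a spatial model", call. = FALSE)
  gen <- if (is.null(time)) 1L else to_generations(model, time)
  p <- autoplot.popscape_world(model$world)
  for (pop in model$pops$name) {
    if (gen < model$pops$start_gen[match(pop, model$pops$name)]) next
    r <- range_at(model, pop, gen)
    if (is.null(r)) next
    df <- data.frame(x = r$coords[, 1], y = r$coords[, 2], pop = pop)
    p <- p + ggplot2::geom_polygon(data = df,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$pop),
      alpha = 0.4, colour = "grey20")
  }
  p + ggplot2::labs(fill = "population")
}

#' Plot the final spatial state of a simulation
#'
#' @param object A `popscape_sim` result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.popscape_sim <- function(object, ...) {
  if (all(is.na(object$state$x)))
    stop("autoplot of a non-spatial simulation has nothing to draw", call. = FALSE)
  autoplot.popscape_world(object$model$world) +
    ggplot2::geom_point(data = object$state,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$pop),
      size = 0.8, alpha = 0.8) +
    ggplot2::labs(colour = "population")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
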