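#' Spatial interaction and dispersal parameters
#'
#' Per-population parameters of the continuous-space engine, all in map units:
#'
#' * `competition`: maximum distance at which individuals compete for space.
#'   Neighbor counts within this radius reduce reproductive weight; `0`
#'   disables density dependence.
#' * `mating`: maximum distance at which a parent looks for a mate.
#' * `dispersal`: scale of the offspring dispersal kernel (how far an
#'   offspring can end up from its parent).
#' * `dispersal_fun`: kernel family, one of `"normal"` (default),
#'   `"uniform"`, `"cauchy"`, `"exponential"`, or `"brownian"`.
#'
#' Unset fields (`NULL`) are filled with defaults at [compile_model()] time.
#'
#' @param competition,mating,dispersal Distances in map units.
#' @param dispersal_fun Kernel name.
#' @return An object of class `popscape_spatial_params`.
#' @export
spatial_params <- function(competition = NULL, mating = NULL,
                           dispersal = NULL, dispersal_fun = NULL) {
  if (!is.null(dispersal_fun) && !dispersal_fun %in% KERNELS)
    stop("unknown dispersal kernel '", dispersal_fun, "'; must be one of: ",
         paste(KERNELS, collapse = ", "), call. = FALSE)
  if (!is.null(competition) && competition < 0)
    stop("competition distance must be >= 0", call. = FALSE)
  if (!is.null(mating) && mating <= 0)
    stop("mating distance must be > 0", call. = FALSE)
  if (!is.null(dispersal) && dispersal <= 0)
    stop("dispersal scale must be > 0", call. = FALSE)
  structure(list(competition = competition, mating = mating,
                 dispersal = dispersal, dispersal_fun = dispersal_fun),
            class = "popscape_spatial_params")
}

#' Declare a population
#'
#' Creates the declarative configuration of a population: its name, the time
#' at which it appears (in the user's own time units), its diploid size, an
#' optional parent population (the new population's founders are drawn from
#' the parent at the split time), and, for spatial models, its initial range
#' and spatial interaction parameters.
#'
#' @param name Population name (`[A-Za-z0-9_]+`).
#' @param time Time of appearance in user time units.
#' @param N Diploid population size (> 0).
#' @param parent Optional parent population (object or name) for a split.
#' @param range Optional [region()] giving the initial spatial range.
#' @param competition,mating,dispersal,dispersal_fun Optional spatial
#'   parameters, see [spatial_params()].
#' @param remove Optional time at which the population is removed.
#' @return An object of class `popscape_population`.
#' @examples
#' anc <- population("anc", time = 1, N = 100)
#' daughter <- population("d1", time = 500, N = 50, parent = anc)
#' @export
population <- function(name, time, N, parent = NULL, range = NULL,
                       competition = NULL, mating = NULL, dispersal = NULL,
                       dispersal_fun = NULL, remove = NULL) {
  if (!grepl("^[A-Za-z0-9_]+$", name))
    stop("population name '", name, "' must match [A-Za-z0-9_]+", call. = FALSE)
  if (N < 1) stop("population '", name, "' must have N >= 1", call. = FALSE)
  if (!is.null(range) && !inherits(range, "popscape_region"))
    stop("range must be a region object", call. = FALSE)
  structure(list(
    name = name, time = time, N = as.integer(round(N)),
    parent = if (is.null(parent)) NULL else pop_name(parent),
    range = range,
    spatial = spatial_params(competition, mating, dispersal, dispersal_fun),
    remove = remove
  ), class = "popscape_population")
}

#' @export
print.popscape_population <- function(x, ...) {
  cat(sprintf("<population '%s'> time %g, N %d%s%s\n", x$name, x$time, x$N,
              if (!is.null(x$parent)) paste0(", parent '", x$parent, "'") else "",
              if (!is.null(x$range)) ", spatial" else ""))
  invisible(x)
}

new_event <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = c(paste0("popscape_", kind), "popscape_event"))
}

#' Schedule a gene-flow event
#'
#' Transfers a total expected ancestry proportion `rate` from `from` into
#' `to` over the time window. At compile time the total rate is converted to
#' a per-generation probability `m = 1 - (1 - rate)^(1/T)` over the `T`
#' generations of the window.
#'
#' @param from,to Source and target populations (objects or names).
#' @param rate Total ancestry proportion in `[0, 1]`.
#' @param start,end Window bounds in user time units.
#' @param overlap For spatial models, require the mate to be found within
#'   the mating radius of the first parent (ranges must overlap).
#' @return A gene-flow event.
#' @export
gene_flow <- function(from, to, rate, start, end, overlap = TRUE) {
  if (rate < 0 || rate > 1) stop("gene-flow rate must be in [0, 1]", call. = FALSE)
  if (start == end) stop("gene-flow window is empty", call. = FALSE)
  new_event("geneflow", list(from = pop_name(from), to = pop_name(to),
                             rate = rate, start = start, end = end,
                             overlap = isTRUE(overlap)))
}

#' Schedule a population resize
#'
#' @param pop Population (object or name).
#' @param time Time at which the resize starts.
#' @param N New diploid size.
#' @param how `"step"` (instantaneous) or `"exponential"` (the size follows
#'   `round(N0 * (N/N0)^(k/T))` over the `T` generations to `end`).
#' @param end End time for an exponential resize.
#' @export
resize <- function(pop, time, N, how = c("step", "exponential"), end = NULL) {
  how <- match.arg(how)
  if (N < 1) stop("resize to N < 1", call. = FALSE)
  if (how == "exponential" && is.null(end))
    stop("exponential resize needs an end time", call. = FALSE)
  new_event("resize", list(pop = pop_name(pop), time = time,
                           N = as.integer(round(N)), how = how, end = end))
}

#' Schedule a population range movement
#'
#' The range centroid follows the piecewise-linear path from its current
#' position through the waypoints at constant speed along the path's arc
#' length; one translated range snapshot is produced per generation of the
#' window, clipped to the habitable area.
#'
#' @param pop Population (object or name).
#' @param trajectory Two-column matrix of waypoint coordinates (>= 1 row).
#' @param start,end Window bounds in user time units.
#' @export
move <- function(pop, trajectory, start, end) {
  trajectory <- to_points(trajectory)
  if (nrow(trajectory) < 1) stop("move needs at least one waypoint", call. = FALSE)
  if (start == end) stop("move window is empty", call. = FALSE)
  new_event("move", list(pop = pop_name(pop), trajectory = trajectory,
                         start = start, end = end))
}

#' Schedule a range expansion or contraction
#'
#' The range is buffered by `by * k/T` at generation `k` of the `T`-generation
#' window (negative `by` contracts), clipped to the habitable area.
#'
#' @param pop Population (object or name).
#' @param by Total offset distance in map units (negative contracts).
#' @param start,end Window bounds in user time units.
#' @export
expand_range <- function(pop, by, start, end) {
  if (start == end) stop("expand_range window is empty", call. = FALSE)
  new_event("expand", list(pop = pop_name(pop), by = by, start = start, end = end))
}

#' Schedule a change of spatial interaction parameters
#'
#' From the given time onward the stated fields override the population's
#' previous values; unstated fields are left unchanged.
#'
#' @inheritParams spatial_params
#' @param pop Population (object or name).
#' @param time Time of the change in user time units.
#' @export
set_dispersal <- function(pop, time, competition = NULL, mating = NULL,
                          dispersal = NULL, dispersal_fun = NULL) {
  new_event("dispersal", list(pop = pop_name(pop), time = time,
                              params = spatial_params(competition, mating,
                                                      dispersal, dispersal_fun)))
}

#' @export
print.popscape_event <- function(x, ...) {
  cat(sprintf("<event %s>\n", x$kind))
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Infer the direction of time of a model
#'
#' The direction is detected from the numerical ordering of split times along
#' parent-child chains and of windowed event bounds: increasing numbers mean
#' time runs forward, decreasing numbers mean times are given as e.g. "years
#' before present". Mixed signals (or no signal at all) are an error; supply
#' an explicit `direction` to [compile_model()] in that case.
#'
#' @param populations List of [population()] configurations.
#' @param events List of events.
#' @return `"forward"` or `"backward"`.
#' @export
infer_direction <- function(populations, events = list()) {
  by_name <- stats::setNames(populations, vapply(populations, `[[`, "", "name"))
  signs <- integer(0)
  for (p in populations) {
    if (!is.null(p$parent) && !is.null(by_name[[p$parent]])) {
      d <- p$time - by_name[[p$parent]]$time
      if (d != 0) signs <- c(signs, sign(d))
    }
  }
  for (e in events) {
    if (!is.null(e$start) && !is.null(e$end) && e$end != e$start)
      signs <- c(signs, sign(e$end - e$start))
  }
  if (length(signs) == 0)
    stop("cannot infer the direction of time; pass direction = \"forward\" or \"backward\"",
         call. = FALSE)
  if (all(signs > 0)) return("forward")
  if (all(signs < 0)) return("backward")
  stop("ambiguous time direction (some times increase, some decrease); ",
       "pass an explicit direction", call. = FALSE)
}
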