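#' Built-in toy worlds and demographic models
#'
#' Ready-made model generators used throughout the documentation and tests:
#'
#' * `toy_world()`: a featureless circular landscape (a disk-shaped
#'   habitable region centered in a square extent).
#' * `example1_model()`: the classic six-population admixture teaching
#'   model — an outgroup `o`; `c` splitting from it; `a` from `c` and `b`
#'   from `a`; recipients `x1` (from `c`) and `x2` (from `x1`) — with a
#'   single gene-flow pulse from `b` into `x1` at a total rate of 10%.
#'   Because `x2` splits off before the gene-flow window, it receives no
#'   `b` ancestry: the f4-ratio estimate is ~10% for `x1` and ~0% for `x2`.
#' * `example2_model()`: independent populations sharing the circular world,
#'   identical except for their spatial competition radius, for studying
#'   how density-dependent competition reorganizes individuals in space.
#' * `example3_like_model()`: a small spatio-temporal model on an abstract
#'   continent with a range move, a range expansion, and one gene-flow
#'   event, specified backward in time in years with a 30-year generation.
#'
#' @param radius Disk radius of the circular world, map units.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
toy_world <- function(radius = 500) {
  world(xrange = c(-radius, radius), yrange = c(-radius, radius),
        regions = region_circle("disk", c(0, 0), radius))
}

#' @rdname fixtures
#' @param N_ref,N_x Diploid sizes of the drift-reference population `a`
#'   (small, to give the f4-ratio denominator strong drift signal) and of
#'   all other populations.
#' @param scale Multiplier applied to all times of the six-population model
#'   (1 keeps the default ~800-generation schedule).
#' @export
example1_model <- function(N_ref = 100, N_x = 1000, scale = 1) {
  s <- function(t) round(t * scale)
  o <- population("o", time = s(1), N = N_x)
  c_ <- population("c", time = s(300), N = N_x, parent = o)
  # a is the estimator's drift reference: its long branch shared with b's
  # lineage is the f4-ratio denominator's signal, so it stays small while
  # every other population is large to suppress nuisance drift
  a <- population("a", time = s(380), N = N_ref, parent = c_)
  b <- population("b", time = s(660), N = N_x, parent = a)
  x1 <- population("x1", time = s(480), N = N_x, parent = c_)
  x2 <- population("x2", time = s(520), N = N_x, parent = x1)
  gf <- gene_flow(from = b, to = x1, rate = 0.1, start = s(730), end = s(770))
  compile_model(populations = list(o, c_, a, b, x1, x2), events = gf,
                generation_time = 1, simulation_length = s(800) - s(1))
}

#' @rdname fixtures
#' @param competition Vector of competition radii, one population each.
#' @param N Diploid size of every population.
#' @param length Number of generations to simulate.
#' @param mating,dispersal Shared mating radius and dispersal scale.
#' @export
example2_model <- function(competition = c(0, 5, 10, 20, 40, 60, 80, 120),
                           N = 200, length = 200, radius = 300,
                           mating = 10, dispersal = 5) {
  w <- toy_world(radius)
  rng <- region_circle("range", c(0, 0), radius * 0.95)
  dispersal <- rep_len(dispersal, length(competition))
  mating <- rep_len(mating, length(competition))
  pops <- lapply(seq_along(competition), function(i)
    population(sprintf("pop%d", i), time = 1, N = N, range = rng,
               competition = competition[i], mating = mating[i],
               dispersal = dispersal[i]))
  compile_model(populations = pops, generation_time = 1,
                direction = "forward", simulation_length = length, world = w)
}

#' @rdname fixtures
#' @export
example3_like_model <- function() {
  w <- world(xrange = c(0, 1000), yrange = c(0, 600),
             regions = region("continent",
                              cbind(c(20, 980, 980, 520, 20),
                                    c(20, 20, 580, 580, 300))))
  anc <- population("anc", time = 30000, N = 200,
                    range = region_circle("anc", c(250, 180), 120))
  east <- population("east", time = 21000, N = 200, parent = anc,
                     range = region_circle("east", c(750, 150), 110))
  north <- population("north", time = 15000, N = 150, parent = anc,
                      range = region_circle("north", c(280, 420), 90))
  evs <- list(
    move("east", trajectory = cbind(650, 420), start = 12000, end = 9000),
    expand_range("north", by = 120, start = 8000, end = 5000),
    gene_flow("east", "north", rate = 0.2, start = 4000, end = 2000))
  compile_model(populations = list(anc, east, north), events = evs,
                generation_time = 30, world = w)
}
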