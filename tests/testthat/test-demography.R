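simple_forward <- function(len = 99) {
  a <- population("a", time = 1, N = 100)
  b <- population("b", time = 20, N = 50, parent = a)
  compile_model(list(a, b), generation_time = 1, simulation_length = len)
}

test_that("population configs validate their inputs", {
  expect_s3_class(population("a", time = 1, N = 100), "popscape_population")
  expect_error(population("bad name", time = 1, N = 10), "A-Za-z0-9_")
  expect_error(population("a", time = 1, N = 0), "N >= 1")
  expect_error(population("a", time = 1, N = 10, range = "nope"), "region")
  expect_error(spatial_params(dispersal_fun = "levy"), "unknown dispersal kernel")
})

test_that("splits record the parent edge and invalid orderings fail at compile", {
  m <- simple_forward()
  expect_identical(unname(m$pops$parent[m$pops$name == "b"]), "a")
  expect_identical(unname(m$pops$start_gen[m$pops$name == "b"]), 20L)
  # child starting before (or with) its parent
  a <- population("a", time = 10, N = 10)
  bad <- population("b", time = 5, N = 10, parent = a)
  expect_error(compile_model(list(a, bad), generation_time = 1,
                             direction = "forward", simulation_length = 50),
               "must start strictly after")
  expect_error(compile_model(list(a, population("b", time = 10, N = 5, parent = a)),
                             generation_time = 1, direction = "forward",
                             simulation_length = 50),
               "must start strictly after")
  # duplicate names
  expect_error(compile_model(list(a, population("a", time = 20, N = 5)),
                             generation_time = 1, direction = "forward",
                             simulation_length = 50),
               "duplicate")
})

test_that("time direction is inferred from splits and event windows", {
  a <- population("a", time = 50000, N = 10)
  b <- population("b", time = 40000, N = 10, parent = a)
  c_ <- population("c", time = 30000, N = 10, parent = b)
  expect_identical(infer_direction(list(a, b, c_)), "backward")

  f1 <- population("a", time = 1, N = 10)
  f2 <- population("b", time = 100, N = 10, parent = f1)
  f3 <- population("c", time = 200, N = 10, parent = f2)
  expect_identical(infer_direction(list(f1, f2, f3)), "forward")

  # a single population with no events is ambiguous
  expect_error(infer_direction(list(f1)), "cannot infer")
  # mixed signals
  gf <- gene_flow("a", "b", rate = 0.1, start = 10, end = 20)
  expect_error(infer_direction(list(a, b), list(gf)), "ambiguous")
})

test_that("generation mapping follows the stated arithmetic and round-trips", {
  a <- population("p", time = 50000, N = 10)
  b <- population("q", time = 40000, N = 10, parent = a)
  m <- compile_model(list(a, b), generation_time = 30)
  expect_identical(to_generations(m, 50000), 1L)
  expect_identical(to_generations(m, 49970), 2L)
  expect_identical(m$G, as.integer(round(50000 / 30)) + 1L)
  set.seed(1)
  ts <- runif(100, 0, 50000)
  for (t in ts)
    expect_lte(abs(t - from_generations(m, to_generations(m, t))), 30 / 2)
  expect_error(to_generations(m, 60000), "outside the model span")
})

test_that("gene-flow conversion matches the closed form to 1e-12", {
  a <- population("a", time = 1, N = 10)
  b <- population("b", time = 2, N = 10, parent = a)
  gf <- gene_flow("a", "b", rate = 0.1, start = 10, end = 20)
  m <- compile_model(list(a, b), list(gf), generation_time = 1,
                     simulation_length = 30)
  T_ <- m$geneflow$end_gen - m$geneflow$start_gen
  expect_identical(T_, 10L)
  expect_equal(m$geneflow$m, 1 - 0.9^(1 / 10), tolerance = 1e-15)
  expect_equal(m$geneflow$m, 0.010481, tolerance = 1e-4)
  # the conversion inverts exactly: 1 - (1 - m)^T = r
  expect_equal(1 - (1 - m$geneflow$m)^T_, 0.1, tolerance = 1e-12)
  # the engine-facing mate probability carries the factor-of-2 compensation
  expect_equal(m$geneflow$q, 2 * m$geneflow$m)

  # r = 0 is a no-op rate
  m0 <- compile_model(list(a, b), list(gene_flow("a", "b", 0, 10, 20)),
                      generation_time = 1, simulation_length = 30)
  expect_identical(m0$geneflow$m, 0)
  # rate domain and empty windows
  expect_error(gene_flow("a", "b", rate = 1.2, start = 1, end = 2), "\\[0, 1\\]")
  expect_error(gene_flow("a", "b", rate = 0.5, start = 5, end = 5), "empty")
  # window before the source exists
  expect_error(compile_model(list(a, b), list(gene_flow("b", "a", 0.1, 1, 5)),
                             generation_time = 1, simulation_length = 30),
               "would not yet exist")
})

test_that("range moves interpolate the centroid at constant speed", {
  w <- world(xrange = c(0, 100), yrange = c(0, 100))
  rng <- region_circle("r", c(20, 20), 5)
  p <- population("p", time = 1, N = 10, range = rng)
  # single waypoint equal to the current centroid: all snapshots identical
  ev0 <- move("p", trajectory = cbind(20, 20), start = 2, end = 12)
  m0 <- compile_model(p, list(ev0), generation_time = 1,
                      simulation_length = 20, world = w)
  areas <- vapply(m0$ranges$p, function(s) region_area(s$region), 1.0)
  cents <- t(vapply(m0$ranges$p, function(s) region_centroid(s$region), c(1, 1)))
  expect_equal(max(dist(cents)), 0, tolerance = 1e-9)

  # one waypoint at distance 10 over 10 generations: 1 unit per generation
  ev1 <- move("p", trajectory = cbind(30, 20), start = 2, end = 12)
  m1 <- compile_model(p, list(ev1), generation_time = 1,
                      simulation_length = 20, world = w)
  cents <- t(vapply(m1$ranges$p, function(s) region_centroid(s$region), c(1, 1)))
  steps <- diff(cents[, 1])
  expect_equal(steps, rep(1, 10), tolerance = 1e-9)

  # two waypoints with arc lengths 3 and 7 over 10 generations: the
  # centroid turns the corner after exactly 3 generations
  ev2 <- move("p", trajectory = rbind(c(23, 20), c(23, 27)), start = 2, end = 12)
  m2 <- compile_model(p, list(ev2), generation_time = 1,
                      simulation_length = 20, world = w)
  cents <- t(vapply(m2$ranges$p, function(s) region_centroid(s$region), c(1, 1)))
  # snapshots: initial + 10 per-generation positions
  expect_equal(cents[4, ], c(23, 20), tolerance = 1e-9)   # after 3 generations
  expect_equal(cents[10, ], c(23, 26), tolerance = 1e-9)  # 6 of 7 up the leg
  expect_equal(cents[11, ], c(23, 27), tolerance = 1e-9)
})

test_that("range expansion buffers by the per-generation fraction", {
  w <- world(xrange = c(-100, 100), yrange = c(-100, 100))
  rng <- region_circle("r", c(0, 0), 5)
  p <- population("p", time = 1, N = 10, range = rng)
  ev <- expand_range("p", by = 5, start = 2, end = 12)
  m <- compile_model(p, list(ev), generation_time = 1,
                     simulation_length = 20, world = w)
  areas <- vapply(m$ranges$p, function(s) region_area(s$region), 1.0)
  expect_equal(areas[length(areas)] / areas[1], 4, tolerance = 0.02)
  expect_true(all(diff(areas) > 0))
  # by = 0 leaves snapshots identical
  m0 <- compile_model(p, list(expand_range("p", 0, 2, 12)), generation_time = 1,
                      simulation_length = 20, world = w)
  a0 <- vapply(m0$ranges$p, function(s) region_area(s$region), 1.0)
  expect_equal(max(a0) - min(a0), 0, tolerance = 1e-9)
  # expansion beyond the world edge is clipped below the unclipped area
  rng_edge <- region_circle("r", c(95, 0), 4)
  pe <- population("p", time = 1, N = 10, range = rng_edge)
  me <- compile_model(pe, list(expand_range("p", 8, 2, 10)), generation_time = 1,
                      simulation_length = 20, world = w)
  ae <- vapply(me$ranges$p, function(s) region_area(s$region), 1.0)
  unclipped <- pi * 12^2
  expect_lt(ae[length(ae)], unclipped)
  # contraction that annihilates the range errors at compile
  expect_error(compile_model(p, list(expand_range("p", -6, 2, 12)),
                             generation_time = 1, simulation_length = 20,
                             world = w),
               "zero area")
})

test_that("dispersal changes are partial updates with later-declared wins", {
  w <- world(xrange = c(0, 100), yrange = c(0, 100))
  p <- population("p", time = 1, N = 10, range = region_circle("r", c(50, 50), 10),
                  competition = 3, mating = 7, dispersal = 2)
  ev <- set_dispersal("p", time = 10, mating = 12)
  m <- compile_model(p, list(ev), generation_time = 1, direction = "forward",
                     simulation_length = 20, world = w)
  before <- popscape:::spatial_at(m, "p", 5)
  after <- popscape:::spatial_at(m, "p", 15)
  expect_equal(before$mating, 7)
  expect_equal(after$mating, 12)
  expect_equal(after$competition, before$competition)
  expect_equal(after$dispersal, before$dispersal)
  expect_identical(after$dispersal_fun, before$dispersal_fun)

  # two changes at one generation: the later-declared one wins, with warning
  evs <- list(set_dispersal("p", 10, dispersal = 5),
              set_dispersal("p", 10, dispersal = 9))
  expect_warning(
    m2 <- compile_model(p, evs, generation_time = 1, direction = "forward",
                        simulation_length = 20, world = w),
    "later-declared")
  expect_equal(popscape:::spatial_at(m2, "p", 15)$dispersal, 9)

  # change scheduled when the population is gone
  pr <- population("p", time = 1, N = 10, remove = 5,
                   range = region_circle("r", c(50, 50), 10))
  expect_error(compile_model(pr, list(set_dispersal("p", 10, mating = 1)),
                             generation_time = 1, direction = "forward",
                             simulation_length = 20, world = w),
               "does not exist")
})

test_that("resize schedules follow step and exponential trajectories", {
  a <- population("a", time = 1, N = 100)
  m <- compile_model(a, list(resize("a", time = 20, N = 50)),
                     generation_time = 1, direction = "forward",
                     simulation_length = 40)
  expect_identical(m$N$a[19], 100L)
  expect_identical(m$N$a[20], 50L)
  me <- compile_model(a, list(resize("a", time = 20, N = 200,
                                     how = "exponential", end = 30)),
                      generation_time = 1, direction = "forward",
                      simulation_length = 40)
  k <- 0:10
  expect_identical(me$N$a[20 + k], as.integer(round(100 * 2^(k / 10))))
  expect_true(all(diff(me$N$a[20:41]) >= 0))
  # events for unknown populations are named in the error
  expect_error(compile_model(a, list(resize("ghost", time = 5, N = 10)),
                             generation_time = 1, direction = "forward",
                             simulation_length = 40),
               "ghost")
})

test_that("compilation is pure and bundles round-trip field by field", {
  m1 <- example1_model()
  m2 <- example1_model()
  expect_identical(m1$hash, m2$hash)
  expect_equal(m1[setdiff(names(m1), "populations")],
               m2[setdiff(names(m2), "populations")])

  d <- withr::local_tempdir()
  write_bundle(m1, d)
  m3 <- read_bundle(d)
  expect_identical(m3$hash, m1$hash)
  expect_equal(m3$N, m1$N)
  expect_equal(m3$geneflow, m1$geneflow)
  expect_true(file.exists(file.path(d, "manifest.yaml")))
  expect_true(file.exists(file.path(d, "populations.tsv")))

  # spatial bundle includes per-snapshot WKT ranges
  ms <- example3_like_model()
  ds <- withr::local_tempdir()
  write_bundle(ms, ds)
  expect_true(file.exists(file.path(ds, "ranges", "north_501.wkt")))
  ms2 <- read_bundle(ds)
  expect_identical(ms2$hash, ms$hash)
  expect_equal(ms2$ranges$north[[50]]$region$coords,
               ms$ranges$north[[50]]$region$coords)
})

test_that("every active generation has exactly one size, range and parameter set", {
  m <- example3_like_model()
  for (p in m$pops$name) {
    i <- match(p, m$pops$name)
    gens <- m$pops$start_gen[i]:m$pops$end_gen[i]
    expect_false(anyNA(m$N[[p]][gens]))
    expect_true(all(is.na(m$N[[p]][-gens])))
    for (g in sample(gens, 20)) {
      expect_s3_class(popscape:::range_at(m, p, g), "popscape_region")
      expect_true(is.list(popscape:::spatial_at(m, p, g)))
    }
  }
})

test_that("sampling schedules validate times, sizes and locations", {
  m <- example3_like_model()
  s <- schedule_sampling(m, times = c(10000, 5000), pop = "north", n = 3)
  expect_identical(nrow(s), 2L)
  expect_identical(s$gen, sort(to_generations(m, c(10000, 5000))))
  expect_error(schedule_sampling(m, times = 20000, pop = "north", n = 2),
               "does not exist")
  expect_error(schedule_sampling(m, times = 5000, pop = "north", n = 2,
                                 location = c(5000, 5000)),
               "outside the world extent")
  sl <- schedule_sampling(m, times = 5000, pop = "north", n = 2,
                          location = c(300, 420))
  expect_equal(sl$x, 300)
})
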