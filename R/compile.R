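#' Convert user time units to generation indices (and back)
#'
#' The oldest time in the model maps to generation 1 and the simulation ends
#' at generation `G = round(|T1 - T0| / generation_time) + 1`, regardless of
#' whether the user specified times forwards or backwards. Node times in all
#' outputs are reported back in the user's own units via the inverse mapping.
#'
#' @param model A compiled model.
#' @param t Time(s) in user units.
#' @param gen Generation index(es) in `[1, G]`.
#' @return Generation indices (`to_generations`) or user times
#'   (`from_generations`).
#' @export
to_generations <- function(model, t) {
  lo <- min(model$T0, model$T1); hi <- max(model$T0, model$T1)
  if (any(t < lo - model$generation_time / 2 | t > hi + model$generation_time / 2))
    stop("time outside the model span [", model$T0, ", ", model$T1, "]", call. = FALSE)
  if (model$direction == "forward")
    as.integer(round((t - model$T0) / model$generation_time)) + 1L
  else
    as.integer(round((model$T0 - t) / model$generation_time)) + 1L
}

#' @rdname to_generations
#' @export
from_generations <- function(model, gen) {
  if (model$direction == "forward")
    model$T0 + (gen - 1) * model$generation_time
  else
    model$T0 - (gen - 1) * model$generation_time
}

resolve_spatial <- function(sp, world) {
  diag <- world_diagonal(world)
  list(competition = sp$competition %||% 0,
       mating = sp$mating %||% diag,
       dispersal = sp$dispersal %||% (diag / 50),
       dispersal_fun = sp$dispersal_fun %||% "normal")
}

merge_spatial <- function(base, partial) {
  for (f in c("competition", "mating", "dispersal", "dispersal_fun"))
    if (!is.null(partial[[f]])) base[[f]] <- partial[[f]]
  base
}

#' Compile a demographic model
#'
#' Validates the declarative model (populations, scheduled events, optional
#' sampling schedule), converts all times to generations, precomputes the
#' per-generation population-size schedule, range snapshots and spatial
#' parameters, and converts windowed gene-flow rates to per-generation
#' probabilities. Compilation is pure: the same inputs always produce an
#' identical compiled model.
#'
#' @param populations List of [population()] configurations.
#' @param events List of events ([gene_flow()], [resize()], [move()],
#'   [expand_range()], [set_dispersal()]); a single event may be passed bare.
#' @param generation_time User time units per generation.
#' @param direction `"forward"` or `"backward"`; inferred from the event
#'   times when `NULL`.
#' @param simulation_length Model span in user units from the oldest time.
#'   Required for forward models; backward models default to ending at
#'   time 0 ("the present").
#' @param world Optional [world()]; required iff populations have ranges.
#' @param sampling Optional sampling schedule: a data frame with columns
#'   `time`, `pop`, `n` and optionally `x`, `y` (see [schedule_sampling()]).
#' @param path Optional directory: when given, the compiled model is also
#'   serialized there as a self-contained bundle (see [write_bundle()]).
#' @return An object of class `popscape_model`.
#' @seealso [run_simulation()], [write_bundle()], [read_bundle()]
#' @export
compile_model <- function(populations, events = list(), generation_time = 1,
                          direction = NULL, simulation_length = NULL,
                          world = NULL, sampling = NULL, path = NULL) {
  if (inherits(populations, "popscape_population")) populations <- list(populations)
  if (inherits(events, "popscape_event")) events <- list(events)
  nm <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate population names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "),
         call. = FALSE)
  names(populations) <- nm

  direction <- direction %||% infer_direction(populations, events)
  if (!direction %in% c("forward", "backward"))
    stop("direction must be \"forward\" or \"backward\"", call. = FALSE)

  times_mentioned <- c(vapply(populations, `[[`, 0, "time"),
                       unlist(lapply(populations, `[[`, "remove")),
                       unlist(lapply(events, function(e)
                         c(e$time, e$start, e$end))))
  T0 <- if (direction == "forward") min(times_mentioned) else max(times_mentioned)
  if (direction == "forward") {
    if (is.null(simulation_length))
      stop("forward models need an explicit simulation_length", call. = FALSE)
    T1 <- T0 + simulation_length
  } else {
    T1 <- if (is.null(simulation_length)) 0 else T0 - simulation_length
  }
  g <- generation_time
  G <- as.integer(round(abs(T1 - T0) / g)) + 1L

  model <- structure(list(world = world, direction = direction,
                          generation_time = g, T0 = T0, T1 = T1, G = G,
                          populations = populations, events = events),
                     class = "popscape_model")

  # spatial consistency
  has_range <- vapply(populations, function(p) !is.null(p$range), FALSE)
  if (any(has_range) && is.null(world))
    stop("populations with spatial ranges need a world", call. = FALSE)
  spatial <- !is.null(world)
  if (spatial && !all(has_range))
    stop("in a spatial model every population needs a range (missing: ",
         paste(nm[!has_range], collapse = ", "), ")", call. = FALSE)

  # population lifespans in generations
  pops <- tibble::tibble(
    name = nm, id = seq_along(nm) - 1L,
    parent = vapply(populations, function(p) p$parent %||% NA_character_, ""),
    start_gen = vapply(populations, function(p) to_generations(model, p$time), 1L),
    end_gen = vapply(populations, function(p)
      if (is.null(p$remove)) G else to_generations(model, p$remove), 1L)
  )
  for (i in seq_len(nrow(pops))) {
    p <- pops[i, ]
    if (p$end_gen < p$start_gen)
      stop("population '", p$name, "' is removed before it appears", call. = FALSE)
    if (!is.na(p$parent)) {
      if (!p$parent %in% nm)
        stop("population '", p$name, "' has unknown parent '", p$parent, "'", call. = FALSE)
      pg <- pops$start_gen[pops$name == p$parent]
      if (p$start_gen <= pg)
        stop("population '", p$name, "' (", from_generations(model, p$start_gen),
             ", generation ", p$start_gen, ") must start strictly after its parent '",
             p$parent, "' (", from_generations(model, pg), ", generation ", pg, ")",
             call. = FALSE)
      pe <- pops$end_gen[pops$name == p$parent]
      if (p$start_gen > pe)
        stop("parent '", p$parent, "' of population '", p$name,
             "' is already removed at the split time", call. = FALSE)
    }
  }

  alive <- function(pop, gen) {
    i <- match(pop, pops$name)
    gen >= pops$start_gen[i] & gen <= pops$end_gen[i]
  }
  event_pop <- function(e, who) {
    if (!who %in% nm)
      stop("event '", e$kind, "' refers to unknown population '", who, "'", call. = FALSE)
    who
  }

  # N schedules
  Nsched <- lapply(nm, function(x) rep(NA_integer_, G))
  names(Nsched) <- nm
  for (i in seq_len(nrow(pops)))
    Nsched[[i]][pops$start_gen[i]:pops$end_gen[i]] <- populations[[i]]$N

  resizes <- Filter(function(e) e$kind == "resize", events)
  rs_gens <- vapply(resizes, function(e) to_generations(model, e$time), 1L)
  for (e in resizes[order(rs_gens)]) {
    p <- event_pop(e, e$pop)
    gs <- to_generations(model, e$time)
    if (!alive(p, gs))
      stop("resize of '", p, "' at time ", e$time, " (generation ", gs,
           "): population does not exist then", call. = FALSE)
    i <- match(p, pops$name)
    if (e$how == "step") {
      Nsched[[i]][gs:pops$end_gen[i]] <- e$N
    } else {
      ge <- to_generations(model, e$end)
      if (ge <= gs)
        stop("exponential resize of '", p, "' has an empty window", call. = FALSE)
      if (!alive(p, ge))
        stop("exponential resize of '", p, "' extends past its lifespan", call. = FALSE)
      N0 <- Nsched[[i]][gs]
      T <- ge - gs
      k <- seq_len(T)
      Nsched[[i]][gs + k] <- as.integer(round(N0 * (e$N / N0)^(k / T)))
      if (ge < pops$end_gen[i]) Nsched[[i]][(ge + 1):pops$end_gen[i]] <- e$N
    }
  }

  # spatial parameter timelines
  spat <- NULL
  if (spatial) {
    spat <- lapply(populations, function(p)
      list(list(gen = pops$start_gen[match(p$name, nm)],
                params = resolve_spatial(p$spatial, world))))
    names(spat) <- nm
    disp_events <- Filter(function(e) e$kind == "dispersal", events)
    dp_gens <- vapply(disp_events, function(e) to_generations(model, e$time), 1L)
    ord <- order(dp_gens, seq_along(disp_events))  # stable: later-declared wins on ties
    seen <- character(0)
    for (e in disp_events[ord]) {
      p <- event_pop(e, e$pop)
      gs <- to_generations(model, e$time)
      if (!alive(p, gs))
        stop("set_dispersal for '", p, "' at time ", e$time, " (generation ", gs,
             "): population does not exist then", call. = FALSE)
      key <- paste(p, gs)
      if (key %in% seen)
        warning("multiple dispersal changes for '", p, "' at generation ", gs,
                "; the later-declared one wins", call. = FALSE)
      seen <- c(seen, key)
      tl <- spat[[p]]
      cur <- tl[[length(tl)]]$params
      upd <- merge_spatial(cur, e$params)
      if (tl[[length(tl)]]$gen == gs) tl[[length(tl)]]$params <- upd
      else tl[[length(tl) + 1]] <- list(gen = gs, params = upd)
      spat[[p]] <- tl
    }
  }

  # range snapshot timelines
  ranges <- NULL
  if (spatial) {
    ranges <- lapply(nm, function(x) list())
    names(ranges) <- nm
    clip_range <- function(reg, who, gen) {
      coords <- clip_polygon_rect(reg$coords, world$xmin, world$xmax,
                                  world$ymin, world$ymax)
      if (is.null(coords))
        stop("range of '", who, "' at generation ", gen,
             " lies outside the world extent", call. = FALSE)
      out <- region(reg$name, coords)
      if (!has_habitable_area(world, out))
        stop("range of '", who, "' at time ", from_generations(model, gen),
             " (generation ", gen, ") has no habitable area", call. = FALSE)
      out
    }
    for (i in seq_len(nrow(pops))) {
      r0 <- populations[[i]]$range
      r0$name <- nm[i]
      ranges[[i]] <- list(list(gen = pops$start_gen[i],
                               region = clip_range(r0, nm[i], pops$start_gen[i])))
    }
    range_events <- Filter(function(e) e$kind %in% c("move", "expand"), events)
    re_gens <- vapply(range_events, function(e) to_generations(model, e$start), 1L)
    for (e in range_events[order(re_gens)]) {
      p <- event_pop(e, e$pop)
      i <- match(p, nm)
      gs <- to_generations(model, e$start)
      ge <- to_generations(model, e$end)
      if (ge <= gs)
        stop(e$kind, " window for '", p, "' is empty", call. = FALSE)
      if (!alive(p, gs) || !alive(p, ge))
        stop("a population cannot be moved or participate in a range event at a time ",
             "when it would not yet exist ('", p, "', generations ", gs, "-", ge, ")",
             call. = FALSE)
      tl <- ranges[[i]]
      base <- tl[[length(tl)]]$region
      T <- ge - gs
      if (e$kind == "move") {
        c0 <- region_centroid(base)
        wp <- rbind(c0, e$trajectory)
        seglen <- sqrt(rowSums((wp[-1, , drop = FALSE] -
                                wp[-nrow(wp), , drop = FALSE])^2))
        cum <- c(0, cumsum(seglen))
        total <- cum[length(cum)]
        for (k in seq_len(T)) {
          s <- total * k / T
          j <- findInterval(s, cum, rightmost.closed = TRUE)
          j <- min(j, length(seglen))
          frac <- if (seglen[j] > 0) (s - cum[j]) / seglen[j] else 0
          pos <- wp[j, ] + frac * (wp[j + 1, ] - wp[j, ])
          snap <- translate_region(base, pos[1] - c0[1], pos[2] - c0[2])
          tl[[length(tl) + 1]] <- list(gen = gs + k, region = clip_range(snap, p, gs + k))
        }
      } else {
        for (k in seq_len(T)) {
          snap <- tryCatch(buffer_region(base, e$by * k / T, world),
                           error = function(err)
                             stop("expand_range for '", p, "' at generation ", gs + k,
                                  ": ", conditionMessage(err), call. = FALSE))
          tl[[length(tl) + 1]] <- list(gen = gs + k, region = clip_range(snap, p, gs + k))
        }
      }
      ranges[[i]] <- tl
    }
  }

  # gene-flow schedule: total rate r over T generations -> per-generation
  # probability m = 1 - (1-r)^(1/T); the engine applies the gene flow on the
  # mate side only (half the offspring's ancestry), so the mate-draw
  # probability is q = min(1, 2m), keeping r's total-ancestry meaning.
  gfs <- Filter(function(e) e$kind == "geneflow", events)
  geneflow <- tibble::tibble(
    from = character(0), to = character(0), start_gen = integer(0),
    end_gen = integer(0), rate = numeric(0), m = numeric(0), q = numeric(0),
    overlap = logical(0))
  for (e in gfs) {
    from <- event_pop(e, e$from); to <- event_pop(e, e$to)
    gs <- to_generations(model, e$start); ge <- to_generations(model, e$end)
    if (ge <= gs) stop("gene-flow window from '", from, "' to '", to, "' is empty",
                       call. = FALSE)
    win <- gs:ge
    if (!all(alive(from, win)) || !all(alive(to, win)))
      stop("a population cannot participate in a gene-flow event at a time when ",
           "it would not yet exist: '", from, "' -> '", to, "' during [",
           e$start, ", ", e$end, "] (generations ", gs, "-", ge, ")", call. = FALSE)
    T <- ge - gs
    m <- 1 - (1 - e$rate)^(1 / T)
    geneflow <- dplyr::bind_rows(geneflow, tibble::tibble(
      from = from, to = to, start_gen = gs, end_gen = ge, rate = e$rate,
      m = m, q = min(1, 2 * m), overlap = e$overlap))
  }

  # sampling schedule
  samp <- tibble::tibble(gen = integer(0), time = numeric(0), pop = character(0),
                         n = integer(0), x = numeric(0), y = numeric(0))
  if (!is.null(sampling) && nrow(sampling) > 0) {
    sampling <- tibble::as_tibble(sampling)
    if (!all(c("time", "pop", "n") %in% names(sampling)))
      stop("sampling needs columns time, pop, n", call. = FALSE)
    if (!"x" %in% names(sampling)) sampling$x <- NA_real_
    if (!"y" %in% names(sampling)) sampling$y <- NA_real_
    for (i in seq_len(nrow(sampling))) {
      s <- sampling[i, ]
      event_pop(list(kind = "sampling"), s$pop)
      gs <- to_generations(model, s$time)
      if (!alive(s$pop, gs))
        stop("sampling of '", s$pop, "' at time ", s$time, " (generation ", gs,
             "): population does not exist then", call. = FALSE)
      if (s$n < 1) stop("sampling n must be >= 1", call. = FALSE)
      if (!is.na(s$x)) {
        if (is.null(world)) stop("sampling location given for a non-spatial model",
                                 call. = FALSE)
        if (s$x < world$xmin || s$x > world$xmax || s$y < world$ymin || s$y > world$ymax)
          stop("sampling location (", s$x, ", ", s$y, ") outside the world extent",
               call. = FALSE)
      }
      samp <- dplyr::bind_rows(samp, tibble::tibble(
        gen = gs, time = s$time, pop = s$pop, n = as.integer(s$n), x = s$x, y = s$y))
    }
    samp <- dplyr::arrange(samp, .data$gen, .data$pop)
  }

  model$pops <- pops
  model$N <- Nsched
  model$spatial <- spat
  model$ranges <- ranges
  model$geneflow <- geneflow
  model$sampling <- samp
  model$hash <- model_hash(model)

  if (!is.null(path)) write_bundle(model, path)
  model
}

#' @export
print.popscape_model <- function(x, ...) {
  cat(sprintf("<popscape model> %d population(s), %s time, %d generation(s)%s\n",
              nrow(x$pops), x$direction, x$G,
              if (!is.null(x$world)) ", spatial" else ""))
  cat(sprintf("  span: %g to %g (generation time %g)\n", x$T0, x$T1, x$generation_time))
  if (nrow(x$geneflow) > 0)
    cat(sprintf("  gene flow: %s\n",
                paste(sprintf("%s->%s r=%g", x$geneflow$from, x$geneflow$to,
                              x$geneflow$rate), collapse = "; ")))
  invisible(x)
}

# schedule lookups ------------------------------------------------------

N_at <- function(model, pop, gen) model$N[[pop]][gen]

timeline_at <- function(tl, gen) {
  gens <- vapply(tl, `[[`, 1L, "gen")
  i <- findInterval(gen, gens)
  if (i < 1) return(NULL)
  tl[[i]]
}

range_at <- function(model, pop, gen) {
  if (is.null(model$ranges)) return(NULL)
  timeline_at(model$ranges[[pop]], gen)$region
}

spatial_at <- function(model, pop, gen) {
  if (is.null(model$spatial)) return(NULL)
  timeline_at(model$spatial[[pop]], gen)$params
}

#' Schedule sampling events for a compiled model
#'
#' Creates a sampling schedule: at each given time, `n` individuals of the
#' population are permanently recorded ("remembered") in the genealogy
#' tables and assigned names `"{POP}_{k}"`. With a location, the engine
#' records the `n` living individuals nearest to it; otherwise individuals
#' are drawn uniformly without replacement. Without any schedule, all
#' individuals alive at the end of the simulation are recorded.
#'
#' @param model A compiled model.
#' @param times Sampling times in user units (vectorized).
#' @param pop Population name(s) (recycled across times).
#' @param n Individuals per sampling event (recycled).
#' @param location Optional `c(x, y)` sampling location.
#' @return A tibble with columns `gen`, `time`, `pop`, `n`, `x`, `y`; pass it
#'   to [run_simulation()] (multiple schedules can be row-bound).
#' @export
schedule_sampling <- function(model, times, pop, n = 1, location = NULL) {
  pop <- vapply(as.list(pop), pop_name, "")
  df <- tidyr::expand_grid(time = times, pop = pop)
  df$n <- as.integer(n)
  df$x <- if (is.null(location)) NA_real_ else location[1]
  df$y <- if (is.null(location)) NA_real_ else location[2]
  # validate through the compile-time path
  dummy <- model
  out <- tibble::tibble(gen = integer(0), time = numeric(0), pop = character(0),
                        n = integer(0), x = numeric(0), y = numeric(0))
  for (i in seq_len(nrow(df))) {
    s <- df[i, ]
    gs <- to_generations(model, s$time)
    row <- pops_row(model, s$pop)
    if (gs < row$start_gen || gs > row$end_gen)
      stop("sampling of '", s$pop, "' at time ", s$time, " (generation ", gs,
           "): population does not exist then", call. = FALSE)
    if (!is.na(s$x) && !is.null(model$world)) {
      w <- model$world
      if (s$x < w$xmin || s$x > w$xmax || s$y < w$ymin || s$y > w$ymax)
        stop("sampling location outside the world extent", call. = FALSE)
    } else if (!is.na(s$x) && is.null(model$world)) {
      stop("sampling location given for a non-spatial model", call. = FALSE)
    }
    out <- dplyr::bind_rows(out, tibble::tibble(gen = gs, time = s$time, pop = s$pop,
                                                n = s$n, x = s$x, y = s$y))
  }
  dplyr::arrange(out, .data$gen, .data$pop)
}

pops_row <- function(model, pop) {
  i <- match(pop, model$pops$name)
  if (is.na(i)) stop("unknown population '", pop, "'", call. = FALSE)
  model$pops[i, ]
}

# canonical serialization + hash ---------------------------------------

model_canonical <- function(model) {
  fmt <- function(x) paste(format(x, digits = 15, trim = TRUE), collapse = ",")
  parts <- c(model$direction, fmt(model$generation_time), fmt(model$T0),
             fmt(model$T1), fmt(model$G))
  for (i in seq_len(nrow(model$pops))) {
    p <- model$pops[i, ]
    parts <- c(parts, paste(p$name, p$parent, p$start_gen, p$end_gen,
                            fmt(model$N[[p$name]][!is.na(model$N[[p$name]])])))
    if (!is.null(model$ranges)) {
      for (sn in model$ranges[[p$name]])
        parts <- c(parts, paste(sn$gen, region_to_wkt(sn$region)))
      for (sp in model$spatial[[p$name]])
        parts <- c(parts, paste(sp$gen, fmt(unlist(sp$params[1:3])), sp$params$dispersal_fun))
    }
  }
  if (nrow(model$geneflow) > 0)
    parts <- c(parts, apply(model$geneflow, 1, paste, collapse = " "))
  if (nrow(model$sampling) > 0)
    parts <- c(parts, apply(model$sampling, 1, paste, collapse = " "))
  paste(parts, collapse = "\n")
}

model_hash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(model_canonical(model), f)
  unname(tools::md5sum(f))
}
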