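#' Density-dependent reproductive weights
#'
#' Each individual's weight is `1 / (1 + n)` where `n` is the number of
#' same-population neighbors within the competition radius (self excluded):
#' crowded individuals are proportionally less likely to be drawn as the
#' first parent of an offspring. A radius of 0 disables density dependence
#' (all weights 1).
#'
#' @param loc Two-column matrix of individual locations.
#' @param competition Competition radius in map units.
#' @return Numeric vector of weights.
#' @export
fitness_weights <- function(loc, competition) {
  n <- nrow(loc)
  if (competition <= 0) return(rep(1, n))
  counts <- neighbor_counts_cpp(loc[, 1], loc[, 2], competition)
  1 / (1 + counts)
}

#' Mate choice within a mating radius
#'
#' For each first parent, a mate is drawn uniformly among same-population
#' individuals within the mating radius (selfing excluded); when no candidate
#' is in range, the nearest individual is used as a fallback so that the
#' Wright-Fisher census sizes are always realized.
#'
#' @param parents Integer indices of the first parents (into `loc` rows).
#' @param loc Two-column matrix of candidate locations.
#' @param mating Mating radius in map units.
#' @return Integer vector of chosen mate indices.
#' @export
choose_mates <- function(parents, loc, mating) {
  if (nrow(loc) < 2) stop("cannot mate in a population of size 1", call. = FALSE)
  idx <- choose_mates_cpp(loc[parents, 1], loc[parents, 2],
                          loc[, 1], loc[, 2], parents - 1L, mating) + 1L
  idx
}

# kernel displacement draws: distance-based kernels use a non-negative
# distance with a uniform direction; "brownian" draws independent per-axis
# normals.
kernel_displacement <- function(n, sigma, fun) {
  if (fun == "brownian")
    return(cbind(stats::rnorm(n, 0, sigma), stats::rnorm(n, 0, sigma)))
  d <- switch(fun,
    normal = abs(stats::rnorm(n, 0, sigma)),
    uniform = stats::runif(n, 0, sigma),
    cauchy = abs(stats::rcauchy(n, 0, sigma)),
    exponential = stats::rexp(n, rate = 1 / sigma))
  theta <- stats::runif(n, 0, 2 * pi)
  cbind(d * cos(theta), d * sin(theta))
}

#' Offspring dispersal
#'
#' Draws offspring locations around parent locations from the population's
#' dispersal kernel, rejecting proposals that fall outside the habitable part
#' of the range. After `max_attempts` failed rounds an offspring is placed
#' uniformly on the range instead (a logged "teleport" fallback, which also
#' covers parents stranded outside a just-moved range).
#'
#' @param parent_loc Two-column matrix of parent locations.
#' @param spatial List with `dispersal` (kernel scale) and `dispersal_fun`.
#' @param range The population's current [region()].
#' @param w The [world()].
#' @param max_attempts Rejection rounds before the uniform fallback.
#' @return List with `loc` (matrix), `rejections` (total rejected proposals)
#'   and `teleported` (count).
#' @export
disperse_from <- function(parent_loc, spatial, range, w, max_attempts = 1000) {
  n <- nrow(parent_loc)
  out <- matrix(NA_real_, n, 2)
  pending <- seq_len(n)
  rejections <- 0
  for (attempt in seq_len(max_attempts)) {
    if (length(pending) == 0) break
    step <- kernel_displacement(length(pending), spatial$dispersal,
                                spatial$dispersal_fun)
    cand <- parent_loc[pending, , drop = FALSE] + step
    ok <- point_in_region(cand, range) & is_habitable(w, cand)
    out[pending[ok], ] <- cand[ok, , drop = FALSE]
    rejections <- rejections + sum(!ok)
    pending <- pending[!ok]
  }
  teleported <- length(pending)
  if (teleported > 0)
    out[pending, ] <- sample_point_uniform(w, range, teleported)
  list(loc = out, rejections = rejections, teleported = teleported)
}

# chunked append-only store for nodes and edges: appends are O(1) (a list
# slot per batch); the chunks are flattened only when simplification or
# table building needs contiguous vectors.

new_store <- function() {
  env <- new.env(parent = emptyenv())
  env$n_nodes <- 0L
  env$node_chunks <- vector("list", 256)
  env$nc <- 0L
  env$n_edges <- 0L
  env$edge_chunks <- vector("list", 256)
  env$ec <- 0L
  env
}

add_nodes <- function(st, k, gen, pop_id, x = NA_real_, y = NA_real_) {
  st$nc <- st$nc + 1L
  if (st$nc > length(st$node_chunks)) length(st$node_chunks) <- 2L * length(st$node_chunks)
  st$node_chunks[[st$nc]] <- list(time = rep(as.numeric(gen), k),
                                  pop = rep(as.integer(pop_id), k),
                                  x = rep_len(x, k), y = rep_len(y, k))
  ids <- st$n_nodes + seq_len(k)
  st$n_nodes <- st$n_nodes + as.integer(k)
  ids - 1L  # 0-based
}

add_edges <- function(st, l, r, parent, child) {
  if (length(l) == 0) return(invisible())
  st$ec <- st$ec + 1L
  if (st$ec > length(st$edge_chunks)) length(st$edge_chunks) <- 2L * length(st$edge_chunks)
  st$edge_chunks[[st$ec]] <- list(l = as.numeric(l), r = as.numeric(r),
                                  p = as.integer(parent), c = as.integer(child))
  st$n_edges <- st$n_edges + length(l)
  invisible()
}

flat_field <- function(chunks, k, field)
  unlist(lapply(chunks[seq_len(k)], `[[`, field), use.names = FALSE)

flatten_store <- function(st) {
  list(node_time = flat_field(st$node_chunks, st$nc, "time"),
       node_pop = flat_field(st$node_chunks, st$nc, "pop"),
       node_x = flat_field(st$node_chunks, st$nc, "x"),
       node_y = flat_field(st$node_chunks, st$nc, "y"),
       edge_l = flat_field(st$edge_chunks, st$ec, "l"),
       edge_r = flat_field(st$edge_chunks, st$ec, "r"),
       edge_p = flat_field(st$edge_chunks, st$ec, "p"),
       edge_c = flat_field(st$edge_chunks, st$ec, "c"))
}

# recombination: one gamete per transmission; breakpoints are integers in
# [1, L-1], Poisson in number with mean rho * L, alternating between the
# parent individual's two genome copies from a random starting copy. The
# no-crossover and single-crossover cases (the vast majority) are fully
# vectorized; k >= 2 falls back to a per-transmission loop.
record_transmissions <- function(st, parent_nodes, child_nodes, rho, L) {
  n <- length(child_nodes)
  k <- if (rho > 0) stats::rpois(n, rho * L) else integer(n)
  start <- sample.int(2L, n, replace = TRUE)
  plain <- which(k == 0)
  if (length(plain)) {
    chosen <- parent_nodes[cbind(plain, start[plain])]
    add_edges(st, rep(0, length(plain)), rep(L, length(plain)), chosen,
              child_nodes[plain])
  }
  one <- which(k == 1)
  if (length(one)) {
    b <- ceiling(stats::runif(length(one), 0, L - 1))
    n1 <- parent_nodes[cbind(one, start[one])]
    n2 <- parent_nodes[cbind(one, 3L - start[one])]
    add_edges(st, c(rep(0, length(one)), b), c(b, rep(L, length(one))),
              c(n1, n2), c(child_nodes[one], child_nodes[one]))
  }
  multi <- which(k >= 2)
  if (length(multi)) {
    kk <- k[multi]
    tid <- rep(seq_along(multi), kk)
    pos <- ceiling(stats::runif(sum(kk), 0, L - 1))
    ord <- order(tid, pos)
    tid <- tid[ord]; pos <- pos[ord]
    n <- length(pos)
    dup <- c(FALSE, tid[-1] == tid[-n] & pos[-1] == pos[-n])
    tid <- tid[!dup]; pos <- pos[!dup]
    m_g <- tabulate(tid, nbins = length(multi))      # breakpoints per gamete
    e_per <- m_g + 1L                                # edges per gamete
    total <- sum(e_per)
    starts <- cumsum(c(1L, e_per[-length(e_per)]))
    ends <- starts + e_per - 1L
    left <- right <- numeric(total)
    left[starts] <- 0; left[-starts] <- pos
    right[ends] <- L; right[-ends] <- pos
    etid <- rep(seq_along(multi), e_per)
    j_within <- sequence(e_per) - 1L
    copy <- ((start[multi][etid] - 1L) + j_within) %% 2L + 1L
    add_edges(st, left, right, parent_nodes[cbind(multi[etid], copy)],
              child_nodes[multi[etid]])
  }
  invisible()
}

run_store_simplify <- function(st, sample_nodes, L, mut_node = integer(0),
                               mut_pos = numeric(0)) {
  fl <- flatten_store(st)
  simplify_cpp(st$n_nodes, fl$node_time, fl$edge_l, fl$edge_r,
               fl$edge_p, fl$edge_c, sample_nodes, L, mut_node, mut_pos)
}

#' Run a compiled model through the forward Wright-Fisher engine
#'
#' Iterates the model generation by generation (non-overlapping generations,
#' fixed census sizes from the compiled schedule). Each offspring draws its
#' first parent proportionally to density-dependent weights
#' ([fitness_weights()]), a mate via [choose_mates()] (or, with an active
#' gene-flow window, from the source population), a location via
#' [disperse_from()], and two genomes recombined against each parent's
#' genome pair. Sampled ("remembered") individuals get permanent names
#' `"{POP}_{k}"`. The recorded genealogy is periodically and finally
#' simplified to the sampled nodes; with `mutation_rate > 0`, neutral
#' mutations are overlaid on the simplified genealogy afterwards.
#'
#' @param model A compiled `popscape_model`.
#' @param sequence_length Genome length in base pairs.
#' @param recombination_rate Per-bp, per-generation recombination rate.
#' @param mutation_rate Per-bp, per-generation mutation rate, applied post
#'   hoc via [overlay_mutations()] (0: none).
#' @param seed Optional integer seed (fixed seed: bit-identical output).
#' @param samples Optional sampling schedule from [schedule_sampling()];
#'   defaults to the schedule compiled into the model, or — if none — to
#'   sampling every individual alive at the end of the simulation.
#' @param simplify_interval Generations between periodic in-run
#'   simplifications of the recorded tables.
#' @param simplify_output Simplify the final tables to the sampled nodes.
#' @param extend_until_coalescence Keep running (up to `max_extra_factor`
#'   times the scheduled span) until every marginal tree of the final
#'   samples has a single root. Only available with default (end) sampling.
#' @param max_extra_factor Cap for `extend_until_coalescence`.
#' @param track_ancestry Optional population name; the per-individual
#'   expected ancestry proportion from that population is then propagated
#'   through the pedigree (founders of the population get 1) and reported in
#'   the final state.
#' @param max_placement_attempts Dispersal rejection rounds before teleport.
#' @param quiet Suppress per-100-generation progress lines.
#' @return An object of class `popscape_sim`: a list with `tables` (a
#'   [gen_tables] object), `state` (tibble of individuals alive at the end),
#'   and run metadata.
#' @export
run_simulation <- function(model, sequence_length, recombination_rate = 0,
                           mutation_rate = 0, seed = NULL, samples = NULL,
                           simplify_interval = 100, simplify_output = TRUE,
                           extend_until_coalescence = FALSE,
                           max_extra_factor = 10,
                           track_ancestry = NULL,
                           max_placement_attempts = 1000, quiet = TRUE) {
  stopifnot(sequence_length >= 1, recombination_rate >= 0, mutation_rate >= 0)
  L <- as.numeric(sequence_length)
  rho <- recombination_rate
  if (!is.null(seed)) set.seed(seed)
  spatial_mode <- !is.null(model$world)
  w <- model$world

  sampling <- samples %||% model$sampling
  default_sampling <- is.null(sampling) || nrow(sampling) == 0
  if (extend_until_coalescence && !default_sampling)
    stop("extend_until_coalescence requires default (end-of-run) sampling",
         call. = FALSE)

  st <- new_store()
  pops <- model$pops
  npop <- nrow(pops)
  live <- vector("list", npop)  # per pop: loc, nodes (n x 2), anc
  names(live) <- pops$name

  remembered <- new.env(parent = emptyenv())
  remembered$nodes <- integer(0)
  remembered$name <- character(0)
  remembered$pop <- character(0)
  remembered$gen <- integer(0)
  remembered$x <- numeric(0)
  remembered$y <- numeric(0)
  remembered$counter <- stats::setNames(integer(npop), pops$name)

  remember <- function(pop, idx, gen) {
    s <- live[[pop]]
    k <- length(idx)
    start <- remembered$counter[[pop]]
    remembered$counter[[pop]] <- start + k
    remembered$nodes <- c(remembered$nodes, as.vector(t(s$nodes[idx, , drop = FALSE])))
    remembered$name <- c(remembered$name, sprintf("%s_%d", pop, start + seq_len(k)))
    remembered$pop <- c(remembered$pop, rep(pop, k))
    remembered$gen <- c(remembered$gen, rep(gen, k))
    if (spatial_mode) {
      remembered$x <- c(remembered$x, s$loc[idx, 1])
      remembered$y <- c(remembered$y, s$loc[idx, 2])
    } else {
      remembered$x <- c(remembered$x, rep(NA_real_, k))
      remembered$y <- c(remembered$y, rep(NA_real_, k))
    }
  }

  remap_all <- function(map) {
    # map is 0-based input -> output (-1 dropped)
    for (i in seq_along(live)) {
      if (is.null(live[[i]])) next
      live[[i]]$nodes[] <<- map[live[[i]]$nodes + 1L]
    }
    remembered$nodes <- map[remembered$nodes + 1L]
  }

  rebuild_store <- function(fl, res) {
    inp <- res$node_input + 1L
    st2 <- new_store()
    st2$nc <- 1L
    st2$node_chunks[[1]] <- list(time = fl$node_time[inp], pop = fl$node_pop[inp],
                                 x = fl$node_x[inp], y = fl$node_y[inp])
    st2$n_nodes <- length(inp)
    add_edges(st2, res$edge_l, res$edge_r, res$edge_parent, res$edge_child)
    st2
  }

  periodic_simplify <- function() {
    live_nodes <- unlist(lapply(live, function(s)
      if (is.null(s)) NULL else as.vector(t(s$nodes))))
    keep <- unique(c(remembered$nodes, live_nodes))
    fl <- flatten_store(st)
    res <- simplify_cpp(st$n_nodes, fl$node_time, fl$edge_l, fl$edge_r,
                        fl$edge_p, fl$edge_c, keep, L, integer(0), numeric(0))
    st <<- rebuild_store(fl, res)
    remap_all(res$node_map)
  }

  total_rejections <- 0

  # gen: the running generation (node birth times); sched_gen: the generation
  # used for schedule lookups (capped at G during a coalescence extension).
  reproduce_pop <- function(i, gen, sched_gen, prev) {
    pop <- pops$name[i]
    n_new <- model$N[[pop]][sched_gen]
    founding <- pops$start_gen[i] == sched_gen && gen == sched_gen
    if (founding && is.na(pops$parent[i])) {
      # root founders: fresh nodes with no parents
      loc <- NULL
      if (spatial_mode)
        loc <- sample_point_uniform(w, range_at(model, pop, gen), n_new)
      ids <- add_nodes(st, 2L * n_new, gen, i - 1L,
                       if (spatial_mode) rep(loc[, 1], each = 2) else NA_real_,
                       if (spatial_mode) rep(loc[, 2], each = 2) else NA_real_)
      anc <- rep(if (identical(track_ancestry, pop)) 1 else 0, n_new)
      return(list(loc = loc, nodes = matrix(ids, ncol = 2, byrow = TRUE), anc = anc))
    }
    src_pop_name <- if (founding) pops$parent[i] else pop
    src <- prev[[src_pop_name]]
    if (is.null(src))
      stop("internal: population '", src_pop_name, "' has no individuals at generation ",
           gen, call. = FALSE)
    n_prev <- nrow(src$nodes)
    if (n_prev < 2)
      stop("population '", src_pop_name, "' has size 1 at generation ", gen,
           ": cannot mate", call. = FALSE)
    sp <- if (spatial_mode) spatial_at(model, src_pop_name, sched_gen) else NULL

    # first parent: density-dependent weights
    wts <- if (spatial_mode && sp$competition > 0)
      fitness_weights(src$loc, sp$competition) else NULL
    parent1 <- sample.int(n_prev, n_new, replace = TRUE, prob = wts)

    # mate source: active gene flows into this population
    mate_pop <- rep(NA_character_, n_new)
    if (!founding && gen == sched_gen && nrow(model$geneflow) > 0) {
      gf <- model$geneflow[model$geneflow$to == pop &
                           model$geneflow$start_gen < gen &
                           model$geneflow$end_gen >= gen, ]
      if (nrow(gf) > 0) {
        u <- stats::runif(n_new)
        cum <- 0
        for (j in seq_len(nrow(gf))) {
          sel <- u >= cum & u < cum + gf$q[j]
          mate_pop[sel] <- gf$from[j]
          cum <- cum + gf$q[j]
        }
      }
    }

    mate_nodes <- matrix(0L, n_new, 2)
    mate_anc <- numeric(n_new)
    same <- is.na(mate_pop)
    if (any(same)) {
      p1 <- parent1[same]
      if (spatial_mode) {
        idx <- choose_mates(p1, src$loc, sp$mating)
      } else {
        idx <- sample.int(n_prev, sum(same), replace = TRUE)
        bad <- idx == p1
        while (any(bad)) {
          idx[bad] <- sample.int(n_prev, sum(bad), replace = TRUE)
          bad <- idx == p1
        }
      }
      mate_nodes[same, ] <- src$nodes[idx, , drop = FALSE]
      mate_anc[same] <- src$anc[idx]
    }
    for (spn in unique(mate_pop[!same])) {
      sel <- which(!is.na(mate_pop) & mate_pop == spn)
      donor <- prev[[spn]]
      if (is.null(donor))
        stop("gene flow from '", spn, "' into '", pop, "' at generation ", gen,
             ": source population has no individuals", call. = FALSE)
      gf_row <- model$geneflow[model$geneflow$from == spn & model$geneflow$to == pop, ][1, ]
      if (spatial_mode && isTRUE(gf_row$overlap)) {
        idx <- choose_mates_cpp(src$loc[parent1[sel], 1], src$loc[parent1[sel], 2],
                                donor$loc[, 1], donor$loc[, 2],
                                rep(-1L, length(sel)), sp$mating) + 1L
        d <- sqrt(rowSums((donor$loc[idx, , drop = FALSE] -
                           src$loc[parent1[sel], , drop = FALSE])^2))
        fail <- d > sp$mating
        if (mean(fail) >= 0.99)
          stop("gene flow from '", spn, "' into '", pop, "' at generation ", gen,
               ": ranges do not overlap within the mating radius", call. = FALSE)
      } else {
        idx <- sample.int(nrow(donor$nodes), length(sel), replace = TRUE)
      }
      mate_nodes[sel, ] <- donor$nodes[idx, , drop = FALSE]
      mate_anc[sel] <- donor$anc[idx]
    }

    # offspring placement
    loc <- NULL
    if (spatial_mode) {
      rng <- range_at(model, pop, sched_gen)
      dsp <- if (founding) spatial_at(model, pop, sched_gen) else sp
      res <- disperse_from(src$loc[parent1, , drop = FALSE], dsp, rng, w,
                           max_placement_attempts)
      loc <- res$loc
      total_rejections <<- total_rejections + res$rejections
    }

    # record nodes and recombinant transmissions
    ids <- add_nodes(st, 2L * n_new, gen, i - 1L,
                     if (spatial_mode) rep(loc[, 1], each = 2) else NA_real_,
                     if (spatial_mode) rep(loc[, 2], each = 2) else NA_real_)
    child_nodes <- matrix(ids, ncol = 2, byrow = TRUE)
    record_transmissions(st, src$nodes[parent1, , drop = FALSE],
                         child_nodes[, 1], rho, L)
    record_transmissions(st, mate_nodes, child_nodes[, 2], rho, L)

    anc <- (src$anc[parent1] + mate_anc) / 2
    if (identical(track_ancestry, pop) && founding) anc <- rep(1, n_new)
    list(loc = loc, nodes = child_nodes, anc = anc)
  }

  run_range <- function(gen_from, gen_to) {
    for (gen in gen_from:gen_to) {
      gen_sched <- min(gen, model$G)  # schedule is held fixed past G when extending
      prev <- live
      for (i in seq_len(npop)) {
        active <- pops$start_gen[i] <= gen_sched && pops$end_gen[i] >= gen_sched
        if (gen > model$G)  # extension phase: pops alive at the end keep going
          active <- pops$end_gen[i] >= model$G
        if (!active) { live[i] <<- list(NULL); next }
        if (pops$start_gen[i] == gen_sched && gen <= model$G) {
          live[[i]] <<- reproduce_pop(i, gen, gen_sched, prev)
        } else if (!is.null(prev[[i]])) {
          live[[i]] <<- reproduce_pop(i, gen, gen_sched, prev)
        }
      }
      if (!default_sampling && nrow(sampling) > 0) {
        todo <- sampling[sampling$gen == gen, ]
        for (j in seq_len(nrow(todo))) {
          s <- todo[j, ]
          stt <- live[[s$pop]]
          n_here <- if (is.null(stt)) 0L else nrow(stt$nodes)
          if (s$n > n_here)
            stop("sampling event (pop '", s$pop, "', time ", s$time, ", n = ", s$n,
                 "): only ", n_here, " individuals alive", call. = FALSE)
          if (!is.na(s$x) && spatial_mode) {
            d <- sqrt((stt$loc[, 1] - s$x)^2 + (stt$loc[, 2] - s$y)^2)
            idx <- order(d)[seq_len(s$n)]
          } else {
            idx <- sample.int(n_here, s$n)
          }
          remember(s$pop, idx, gen)
        }
      }
      if (gen %% simplify_interval == 0 && st$n_edges > 0) periodic_simplify()
      if (!quiet && gen %% 100 == 0) {
        sizes <- vapply(seq_len(npop), function(i)
          if (is.null(live[[i]])) 0L else nrow(live[[i]]$nodes), 1L)
        message(sprintf("generation %d | N = %s | dispersal rejections so far: %d",
                        gen, paste(pops$name, sizes, sep = ":", collapse = " "),
                        total_rejections))
      }
    }
  }

  run_range(1L, model$G)
  final_gen <- model$G

  if (default_sampling) {
    for (p in pops$name)
      if (!is.null(live[[p]])) remember(p, seq_len(nrow(live[[p]]$nodes)), final_gen)
  }

  if (extend_until_coalescence) {
    chunk <- max(500L, as.integer(ceiling(model$G / 5)))
    while (final_gen < max_extra_factor * model$G) {
      periodic_simplify()
      if (all_coalesced(st, remembered$nodes, L)) break
      # forget the stale end-of-run sample registration and extend
      remembered$nodes <- integer(0); remembered$name <- character(0)
      remembered$pop <- character(0); remembered$gen <- integer(0)
      remembered$x <- numeric(0); remembered$y <- numeric(0)
      remembered$counter[] <- 0L
      run_range(final_gen + 1L, final_gen + chunk)
      final_gen <- final_gen + chunk
      for (p in pops$name)
        if (!is.null(live[[p]])) remember(p, seq_len(nrow(live[[p]]$nodes)), final_gen)
    }
  }

  # final tables
  if (simplify_output) {
    fl <- flatten_store(st)
    res <- simplify_cpp(st$n_nodes, fl$node_time, fl$edge_l, fl$edge_r,
                        fl$edge_p, fl$edge_c, remembered$nodes, L,
                        integer(0), numeric(0))
    st <- rebuild_store(fl, res)
    remap_all(res$node_map)
  }
  tables <- build_tables(st, model, remembered, L, final_gen)
  if (mutation_rate > 0) tables <- overlay_mutations(tables, mutation_rate)

  state <- dplyr::bind_rows(lapply(pops$name, function(p) {
    s <- live[[p]]
    if (is.null(s)) return(NULL)
    tibble::tibble(pop = p,
                   x = if (spatial_mode) s$loc[, 1] else NA_real_,
                   y = if (spatial_mode) s$loc[, 2] else NA_real_,
                   ancestry = s$anc)
  }))

  structure(list(tables = tables, state = state, model = model, seed = seed,
                 sequence_length = L, recombination_rate = rho,
                 mutation_rate = mutation_rate, final_gen = final_gen,
                 dispersal_rejections = total_rejections),
            class = "popscape_sim")
}

#' @export
print.popscape_sim <- function(x, ...) {
  cat(sprintf("<popscape simulation> %d generations, %d sampled individuals\n",
              x$final_gen, nrow(x$tables$individuals)))
  print(x$tables)
  invisible(x)
}

all_coalesced <- function(st, sample_nodes, L) {
  res <- run_store_simplify(st, sample_nodes, L)
  np <- length(res$node_input)
  if (np == 0) return(TRUE)
  out_samples <- res$node_map[sample_nodes + 1L]
  max_marginal_roots_cpp(np, res$edge_l, res$edge_r,
                         res$edge_parent, res$edge_child, out_samples, L) <= 1L
}

build_tables <- function(st, model, remembered, L, final_gen) {
  fl <- flatten_store(st)
  n <- st$n_nodes
  node_ids <- seq_len(n) - 1L
  sample_flag <- node_ids %in% remembered$nodes
  ind_of_node <- rep(NA_integer_, n)
  n_ind <- length(remembered$name)
  if (n_ind > 0) {
    ind_idx <- rep(seq_len(n_ind) - 1L, each = 2)
    ind_of_node[remembered$nodes + 1L] <- ind_idx
  }
  nodes <- tibble::tibble(
    id = node_ids,
    time_gen = fl$node_time,
    time = from_generations(model, fl$node_time),
    pop = model$pops$name[fl$node_pop + 1L],
    ind = ind_of_node,
    sample = sample_flag,
    x = fl$node_x,
    y = fl$node_y)
  individuals <- tibble::tibble(
    id = seq_len(n_ind) - 1L,
    name = remembered$name,
    pop = remembered$pop,
    time = from_generations(model, remembered$gen),
    x = remembered$x, y = remembered$y,
    node1 = remembered$nodes[seq(1, by = 2, length.out = n_ind)],
    node2 = remembered$nodes[seq(2, by = 2, length.out = n_ind)])
  edges <- tibble::tibble(left = fl$edge_l, right = fl$edge_r,
                          parent = fl$edge_p, child = fl$edge_c)
  new_gen_tables(nodes = nodes, individuals = individuals, edges = edges,
                 sites = empty_sites(), mutations = empty_mutations(),
                 L = L, direction = model$direction,
                 generation_time = model$generation_time, T0 = model$T0)
}
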