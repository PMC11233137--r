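#' Serialize a compiled model to a self-contained bundle directory
#'
#' The bundle contains everything needed to re-run the model: a
#' `manifest.yaml` (direction, generation time, span, world extent and
#' habitable regions as WKT, model hash), `populations.tsv`, `events.tsv`
#' (one JSON-encoded event per row), `sampling.tsv`, and per-population,
#' per-snapshot range polygons under `ranges/` as `{pop}_{gen}.wkt` (each
#' line is the region name, a TAB, and the WKT POLYGON). All tables are
#' tab-separated UTF-8 with a header row. Because compilation is pure,
#' [read_bundle()] reproduces the compiled model exactly.
#'
#' @param model A compiled model.
#' @param path Directory to create (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(model, path) {
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)

  manifest <- list(
    format = "popscape-bundle-1",
    direction = model$direction,
    generation_time = model$generation_time,
    T0 = model$T0, T1 = model$T1, G = model$G,
    hash = model$hash
  )
  if (!is.null(model$world)) {
    manifest$world <- list(
      xrange = c(model$world$xmin, model$world$xmax),
      yrange = c(model$world$ymin, model$world$ymax),
      habitable = lapply(model$world$habitable, function(r)
        list(name = r$name, wkt = region_to_wkt(r))))
  }
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))

  pops <- dplyr::bind_rows(lapply(model$populations, function(p) tibble::tibble(
    name = p$name, time = p$time, N = p$N,
    parent = p$parent %||% NA_character_,
    remove = p$remove %||% NA_real_,
    competition = p$spatial$competition %||% NA_real_,
    mating = p$spatial$mating %||% NA_real_,
    dispersal = p$spatial$dispersal %||% NA_real_,
    dispersal_fun = p$spatial$dispersal_fun %||% NA_character_,
    has_range = !is.null(p$range))))
  for (cl in names(pops))
    if (is.numeric(pops[[cl]])) pops[[cl]] <- sprintf("%.17g", pops[[cl]])
  pops[pops == "NA"] <- NA
  utils::write.table(pops, file.path(path, "populations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ev <- tibble::tibble(
    kind = vapply(model$events, `[[`, "", "kind"),
    params = vapply(model$events, function(e) {
      e <- unclass(e)
      e$kind <- NULL
      if (!is.null(e$params)) e$params <- unclass(e$params)
      if (!is.null(e$trajectory))
        e$trajectory <- apply(e$trajectory, 1, identity, simplify = FALSE)
      as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA, null = "null"))
    }, ""))
  utils::write.table(ev, file.path(path, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  utils::write.table(model$sampling[, c("time", "pop", "n", "x", "y")],
                     file.path(path, "sampling.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (!is.null(model$ranges)) {
    dir.create(file.path(path, "ranges"))
    for (p in names(model$ranges)) {
      for (sn in model$ranges[[p]]) {
        f <- file.path(path, "ranges", sprintf("%s_%d.wkt", p, sn$gen))
        writeLines(paste(sn$region$name, region_to_wkt(sn$region), sep = "\t"), f)
      }
      # the declarative (unclipped) initial range, used to rebuild the model
      r0 <- model$populations[[p]]$range
      writeLines(paste(p, region_to_wkt(r0), sep = "\t"),
                 file.path(path, "ranges", sprintf("%s_initial.wkt", p)))
    }
  }
  invisible(path)
}

read_wkt_file <- function(f) {
  line <- readLines(f, warn = FALSE)[1]
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  wkt_to_region(parts[1], parts[2])
}

#' Load a compiled model from a bundle directory
#'
#' Reconstructs the declarative model from the bundle and recompiles it;
#' compilation purity guarantees a field-by-field identical compiled model,
#' verified against the stored hash.
#'
#' @param path Bundle directory written by [write_bundle()].
#' @return A compiled `popscape_model`.
#' @export
read_bundle <- function(path) {
  if (!file.exists(file.path(path, "manifest.yaml")))
    stop("'", path, "' is not a popscape bundle (no manifest.yaml)", call. = FALSE)
  manifest <- yaml::read_yaml(file.path(path, "manifest.yaml"))
  if (!identical(manifest$format, "popscape-bundle-1"))
    stop("'", path, "' is not a popscape bundle", call. = FALSE)
  w <- NULL
  if (!is.null(manifest$world)) {
    regs <- lapply(manifest$world$habitable, function(h) wkt_to_region(h$name, h$wkt))
    w <- world(xrange = unlist(manifest$world$xrange),
               yrange = unlist(manifest$world$yrange), regions = regs)
  }
  pt <- utils::read.table(file.path(path, "populations.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  populations <- lapply(seq_len(nrow(pt)), function(i) {
    r <- pt[i, ]
    rng <- if (isTRUE(r$has_range))
      read_wkt_file(file.path(path, "ranges", sprintf("%s_initial.wkt", r$name)))
    population(r$name, time = r$time, N = r$N,
               parent = if (is.na(r$parent)) NULL else r$parent,
               range = rng,
               competition = if (is.na(r$competition)) NULL else r$competition,
               mating = if (is.na(r$mating)) NULL else r$mating,
               dispersal = if (is.na(r$dispersal)) NULL else r$dispersal,
               dispersal_fun = if (is.na(r$dispersal_fun)) NULL else r$dispersal_fun,
               remove = if (is.na(r$remove)) NULL else r$remove)
  })

  et <- utils::read.table(file.path(path, "events.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  events <- lapply(seq_len(nrow(et)), function(i) {
    fields <- jsonlite::fromJSON(et$params[i], simplifyVector = TRUE)
    if (!is.null(fields$trajectory))
      fields$trajectory <- matrix(unlist(fields$trajectory), ncol = 2, byrow = TRUE)
    if (!is.null(fields$params))
      fields$params <- do.call(spatial_params, fields$params)
    new_event(et$kind[i], fields)
  })

  st <- utils::read.table(file.path(path, "sampling.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  sampling <- if (nrow(st) > 0) tibble::as_tibble(st) else NULL

  sim_len <- abs(manifest$T1 - manifest$T0)
  model <- compile_model(populations, events,
                         generation_time = manifest$generation_time,
                         direction = manifest$direction,
                         simulation_length = sim_len,
                         world = w, sampling = sampling)
  if (!identical(model$hash, manifest$hash))
    warning("recompiled model hash differs from the bundle manifest", call. = FALSE)
  model
}
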