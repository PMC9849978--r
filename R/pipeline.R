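# End-to-end orchestration: generate or load a city, score deprivation, run
# the pattern statistics on facilities and on the deprivation classes, and
# compute multi-wave walking-access tables.

#' Bundled demonstration configuration
#'
#' A synthetic three-wave study: a jittered-grid city with clustered
#' deprivation (SAR rho 0.8), CSR facilities, and nested facility waves of
#' 29, 33 and 78 centres (1996/2006/2016) under the default walking model
#' (1 m/s, 750 m, i.e. a 12.5-minute budget).
#'
#' @param grid blocks per axis (default 40 of 150 m, a 6 x 6 km city).
#' @param pop_total total population.
#' @param seed master seed.
#' @return a configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(grid = 40L, pop_total = 250000L, seed = 42L) {
  list(
    city = list(synthetic = list(
      seed = seed, grid_nx = grid, grid_ny = grid, block_size = 150,
      road_jitter = 15, n_facilities = 78L, facility_pattern = "csr",
      pop_total = pop_total, pop_sd_log = 0.6, deprivation_rho = 0.8)),
    waves = list(list(year = 1996, n_facilities = 29L),
                 list(year = 2006, n_facilities = 33L),
                 list(year = 2016, n_facilities = 78L)),
    walk = list(speed = 1.0, radius = 750, buffer_width = 50),
    overlay = list(method = "areal", resolution = 16L),
    patterns = list(weights = "inverse_distance", permutations = 0L))
}

stage_log <- function(stage, ...) {
  kv <- c(...)
  message("stage=", stage,
          if (length(kv)) paste0(" ", paste(names(kv), kv, sep = "=",
                                            collapse = " ")) else "")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

select_wave_facilities <- function(fac, wave) {
  if (!is.null(wave$n_facilities)) {
    n <- wave$n_facilities
    if (n > nrow(fac)) stop("wave requests ", n, " facilities but only ",
                            nrow(fac), " available")
    fac[seq_len(n), , drop = FALSE]
  } else if (!is.null(wave$year) && !all(is.na(fac$year)) &&
             is.numeric(fac$year)) {
    fac[!is.na(fac$year) & fac$year <= wave$year, , drop = FALSE]
  } else fac
}

#' Run the full accessibility study
#'
#' Stages, in fixed order: city (generate from `config$city$synthetic` or load
#' from `config$city$paths`), deprivation scoring, pattern statistics
#' (facility ANN, facility-count Moran, deprivation Moran, facility and
#' population KDE), and per-wave service-area access tabulation. Every stage
#' emits one structured log line; any failure aborts with a stage-named
#' diagnostic.
#'
#' @param config nested list, e.g. from [demo_config()] or [read_config()].
#' @return Object of class `run_report`: per-wave results plus provenance
#'   (config hash, seeds, package version). Rerunning the same config yields
#'   an identical report.
#' @export
run_pipeline <- function(config) {
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- city ------------------------------------------------------------------
  city <- with_stage("city", {
    if (!is.null(config$city$synthetic)) {
      cc <- do.call(city_config, config$city$synthetic)
      ct <- generate_city(cc)
      stage_log("city", c(source = "synthetic", blocks = length(ct$blocks$block_id),
                          facilities = nrow(ct$facilities), seed = cc$seed))
      ct
    } else if (!is.null(config$city$paths)) {
      p <- config$city$paths
      ct <- list(roads = read_roads(p$roads,
                                    isTRUE(config$city$assume_planar)),
                 blocks = read_blocks(p$blocks, p$population, p$indicators,
                                      isTRUE(config$city$assume_planar)),
                 facilities = read_facilities(p$facilities,
                                              isTRUE(config$city$assume_planar)))
      stage_log("city", c(source = "files", blocks = length(ct$blocks$block_id),
                          facilities = nrow(ct$facilities)))
      ct
    } else stop("config$city needs a 'synthetic' or 'paths' entry")
  })

  # --- deprivation -----------------------------------------------------------
  poverty <- with_stage("poverty", {
    specs <- if (!is.null(config$poverty$specs))
      do.call(indicator_spec, config$poverty$specs) else {
        nm <- setdiff(names(city$blocks$indicators), "block_id")
        def <- default_indicator_specs()
        if (all(nm %in% def$name) && all(def$name %in% nm)) def else
          indicator_spec(nm, "deprivation_up")
      }
    pv <- composite_score(city$blocks, specs)
    stage_log("poverty", c(indicators = nrow(specs),
                           lower = sum(pv$class == "lower")))
    pv
  })

  # --- pattern statistics (city-level, wave-independent for deprivation) ----
  wscheme <- if (is.null(config$patterns$weights)) "inverse_distance" else
    config$patterns$weights
  n_perm <- if (is.null(config$patterns$permutations)) 0L else
    config$patterns$permutations
  w_blocks <- with_stage("weights", {
    if (wscheme == "rook") build_weights(city$blocks, "rook") else
      build_weights(block_centroids(city$blocks), wscheme,
                    k = config$patterns$k, band = config$patterns$band)
  })
  poverty_moran <- with_stage("poverty_moran", {
    v <- class_to_value(poverty, "ordinal")
    mr <- morans_i(v, w_blocks,
                   inference = if (n_perm > 0) "permutation" else "normal",
                   n_perm = max(1L, n_perm), seed = 1L)
    stage_log("poverty_moran", c(I = sprintf("%.4f", mr$I),
                                 z = sprintf("%.2f", mr$z), weights = wscheme))
    mr
  })

  # --- walking model ---------------------------------------------------------
  wm <- walk_model(speed = if (is.null(config$walk$speed)) 1.0 else config$walk$speed,
                   radius = if (is.null(config$walk$radius)) 750 else config$walk$radius)
  buffer_width <- if (is.null(config$walk$buffer_width)) 50 else config$walk$buffer_width
  method <- if (is.null(config$overlay$method)) "areal" else config$overlay$method
  resolution <- if (is.null(config$overlay$resolution)) 16L else config$overlay$resolution
  stage_log("walk_model", c(speed = wm$speed, radius = wm$radius,
                            cutoff_s = wm$cutoff, cutoff_min = wm$cutoff / 60))

  waves <- if (is.null(config$waves)) list(list(year = NA)) else config$waves
  cen <- block_centroids(city$blocks)
  pop_by_block <- rowSums(city$blocks$pop)

  wave_results <- lapply(waves, function(wave) {
    yr <- wave$year
    fac <- select_wave_facilities(city$facilities, wave)
    pts <- cbind(fac$x, fac$y)

    ann <- with_stage("ann", {
      a <- nearest_neighbor_stat(pts)
      stage_log("ann", c(year = yr, n = a$n, ann = sprintf("%.3f", a$ann),
                         z = sprintf("%.2f", a$z)))
      a
    })
    fac_moran <- with_stage("facility_moran", {
      counts <- facility_counts_per_block(city$blocks, fac)
      if (stats::var(counts) == 0) NULL else {
        mr <- morans_i(counts, w_blocks)
        stage_log("facility_moran", c(year = yr, I = sprintf("%.4f", mr$I),
                                      z = sprintf("%.2f", mr$z)))
        mr
      }
    })
    kde <- with_stage("kde", {
      h_fac <- kde_bandwidth(pts)
      span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
      cs <- max(h_fac / 10, span / 256)
      surf <- kernel_density(pts, cell_size = cs, bandwidth = h_fac)
      pk <- which(surf$values == max(surf$values), arr.ind = TRUE)[1, ]
      h_pop <- kde_bandwidth(cen, pop_by_block)
      stage_log("kde", c(year = yr, bandwidth_fac = sprintf("%.1f", h_fac),
                         bandwidth_pop = sprintf("%.1f", h_pop)))
      list(facility_bandwidth = h_fac, population_bandwidth = h_pop,
           cell_size = cs, integral = kde_integral(surf),
           peak_cell = c(x = surf$origin[1] + (pk[1] - 0.5) * cs,
                         y = surf$origin[2] + (pk[2] - 0.5) * cs),
           peak_value = max(surf$values))
    })
    access <- with_stage("access", {
      sas <- lapply(seq_len(nrow(fac)), function(i) {
        pos <- snap_facility(city$roads, fac[i, , drop = FALSE])
        service_area(city$roads, pos, wm, buffer_width)
      })
      cov <- union_service_areas(sas)
      fr <- population_with_access(city$blocks, cov, method, resolution)
      tab <- tabulate_access(fr, city$blocks, year = yr)
      tot <- tab[tab$sex == "total" & tab$age == "total", ]
      stage_log("access", c(year = yr, facilities = nrow(fac),
                            no_access_pct = tot$no_access_pct))
      tab
    })
    list(year = yr, n_facilities = nrow(fac), ann = ann,
         facility_moran = fac_moran, poverty_moran = poverty_moran,
         kde = kde, access = access)
  })

  structure(list(waves = wave_results,
                 poverty = poverty,
                 provenance = list(config_hash = config_hash(config),
                                   seed = config$city$synthetic$seed,
                                   walk = unclass(wm),
                                   package_version =
                                     as.character(utils::packageVersion("spaccess")))),
            class = "run_report")
}

# Number of facilities whose point falls in each block (ray-cast containment).
facility_counts_per_block <- function(blocks, fac) {
  counts <- integer(length(blocks$block_id))
  for (k in seq_along(blocks$rings))
    counts[k] <- sum(geom_point_in_ring(fac$x, fac$y, blocks$rings[[k]]))
  counts
}

#' @export
print.run_report <- function(x, ...) {
  cat("Accessibility study report (", length(x$waves), "waves )\n")
  cat(sprintf("  walking model: %.1f m/s, %.0f m -> %.1f min budget\n",
              x$provenance$walk$speed, x$provenance$walk$radius,
              x$provenance$walk$cutoff / 60))
  for (w in x$waves) {
    tot <- w$access[w$access$sex == "total" & w$access$age == "total", ]
    cat(sprintf("  wave %s: %d facilities | ANN %.3f (z %.2f) | poverty I %.3f (z %.2f) | no access %.2f%%\n",
                w$year, w$n_facilities, w$ann$ann, w$ann$z,
                w$poverty_moran$I, w$poverty_moran$z, tot$no_access_pct))
  }
  cat("  config hash:", x$provenance$config_hash, "\n")
  invisible(x)
}

#' Hash of a run report (md5 over its serialised content)
#' @param report a `run_report`
#' @export
report_hash <- function(report) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(report, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Write a run report (JSON + Table-1-shaped access CSVs)
#' @param report a `run_report`
#' @param dir output directory
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (w in report$waves)
    write_access_table(w$access,
                       file.path(dir, sprintf("access_%s.csv", w$year)))
  slim <- list(
    waves = lapply(report$waves, function(w) list(
      year = w$year, n_facilities = w$n_facilities,
      ann = unclass(w$ann),
      facility_moran = if (is.null(w$facility_moran)) NULL else
        unclass(w$facility_moran),
      poverty_moran = unclass(w$poverty_moran),
      kde = w$kde,
      access = as.data.frame(w$access))),
    provenance = report$provenance)
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
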