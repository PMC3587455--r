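# Orchestration of the hourly coupling chain:
# kernels -> superposition -> downscale -> combine -> chemistry.

#' Run the coupled background + road-source model
#'
#' For every hour: builds one unit-emission kernel per road category,
#' superposes all road sources onto the fine grid (NO and primary NO2
#' increments plus concentration-weighted time of flight), bilinearly
#' downscales the coarse background NO/NO2/O3, adds road increments to the
#' background, and relaxes the NO-NO2-O3 chemistry over each cell's time
#' of flight.
#'
#' @param links list of [road_link()] objects
#' @param met hourly meteorology (see [validate_met()]); an optional
#'   `zenith` column feeds the photolysis parameterisation
#' @param background list as returned by [make_background_fields()]:
#'   coarse `grid`, `hours`, arrays `no`, `no2`, `o3` (ppb)
#' @param grid the fine output [grid_spec()]
#' @param profile optional [temporal_profile()] scaling road emissions by
#'   hour of week and month
#' @param j_series optional hourly NO2 photolysis rates, s-1 (overrides
#'   the zenith parameterisation)
#' @param chemistry apply the near-road chemistry step (TRUE) or output
#'   the pre-chemistry combined fields
#' @param progress print per-hour progress to stderr
#' @param ... kernel parameters passed to [build_kernel_set()]
#' @return object of class `aq_run`: `grid`, `hours`, `fields` (per hour:
#'   matrices `no`, `no2`, `o3`, `tof`), `sources`, `report`
#' @export
run_coupled_model <- function(links, met, background, grid, profile = NULL,
                              j_series = NULL, chemistry = TRUE,
                              progress = FALSE, ...) {
  validate_met(met)
  n_hours <- nrow(met)
  if (length(background$hours) != n_hours ||
      any(abs(as.numeric(background$hours) - as.numeric(met$timestamp)) > 1)) {
    stop("background hours do not match met hours")
  }
  sources <- build_sources(links)
  categories <- unique(sources$category)
  fields <- vector("list", n_hours)
  skipped <- integer(0)
  t0 <- proc.time()[["elapsed"]]
  for (t in seq_len(n_hours)) {
    met_t <- met[t, , drop = FALSE]
    if (any(!is.finite(c(met_t$u10, met_t$wdir, met_t$temp,
                         met_t$shf, met_t$pblh)))) {
      skipped <- c(skipped, t)
      next
    }
    src_t <- sources
    if (!is.null(profile)) {
      f <- emission_at_hour(1, profile, met_t$timestamp)
      src_t$no_rate <- src_t$no_rate * f
      src_t$no2_rate <- src_t$no2_rate * f
    }
    kernels <- build_kernel_set(categories, met_t, ...)
    road <- superpose_sources(src_t, kernels, grid, met_t)
    bg <- list(
      no = bilinear_downscale(background$no[, , t], background$grid, grid),
      no2 = bilinear_downscale(background$no2[, , t], background$grid, grid),
      o3 = bilinear_downscale(background$o3[, , t], background$grid, grid))
    road_no_ppb <- ugm3_to_ppb(road$no, "NO", temp = met_t$temp)
    road_no2_ppb <- ugm3_to_ppb(road$no2, "NO2", temp = met_t$temp)
    combined <- combine_fields(bg, road_no_ppb, road_no2_ppb)
    if (chemistry) {
      j <- if (!is.null(j_series)) j_series[t]
           else if (!is.null(met$zenith)) photolysis_j(met_t$zenith)
           else photolysis_j(90)  # no solar information: night
      rates <- rate_params(k1 = rate_k1(met_t$temp), j = j, temp = met_t$temp)
      chem <- apply_chemistry_field(combined, road$tof, rates)
    } else {
      chem <- combined[c("no", "no2", "o3")]
    }
    fields[[t]] <- list(no = chem$no, no2 = chem$no2, o3 = chem$o3,
                        tof = road$tof)
    if (progress) message(sprintf("hour %d/%d done", t, n_hours))
  }
  structure(list(grid = grid, hours = met$timestamp, fields = fields,
                 sources = sources,
                 report = list(n_hours = n_hours, skipped = skipped,
                               n_sources = nrow(sources),
                               categories = categories,
                               elapsed_s = proc.time()[["elapsed"]] - t0)),
            class = "aq_run")
}

#' @export
print.aq_run <- function(x, ...) {
  cat(sprintf("aq_run: %d hours on %d x %d grid (%g m), %d road sources, %.1f s\n",
              x$report$n_hours, x$grid$nx, x$grid$ny, x$grid$spacing,
              x$report$n_sources, x$report$elapsed_s))
  invisible(x)
}

#' Extract the modelled hourly series at a point
#'
#' @param run an `aq_run`
#' @param x,y location, m (snapped to the containing cell centre)
#' @param species "NO", "NO2", "O3" or "NOx"
#' @return numeric vector over the run's hours (NA for skipped hours)
#' @export
extract_site_series <- function(run, x, y, species = "NO2") {
  cc <- cell_centers(run$grid)
  ix <- which.min(abs(cc$x - x))
  iy <- which.min(abs(cc$y - y))
  vapply(run$fields, function(f) {
    if (is.null(f)) return(NA_real_)
    switch(species, NO = f$no[ix, iy], NO2 = f$no2[ix, iy],
           O3 = f$o3[ix, iy], NOx = f$no[ix, iy] + f$no2[ix, iy],
           stop("unknown species: ", species))
  }, numeric(1))
}

#' Evaluate a model run against observations
#'
#' Pairs the modelled series at each site with the observations and
#' produces a statistics table by site, by site type and pooled, per
#' species, plus temporal profiles of the residuals.
#'
#' @param run an `aq_run`
#' @param obs long observations data.frame (see [make_observations()]):
#'   `timestamp`, `site_id`, `site_type`, `species`, `value_ppb`
#' @param sites data.frame `site_id`, `x`, `y` (site locations)
#' @param profile_modes temporal modes for the residual profiles
#' @return list: `by_site`, `by_type` (stats tables), `profiles` (named
#'   list of residual profiles per species)
#' @export
run_evaluation <- function(run, obs, sites,
                           profile_modes = c("hour_of_day", "month")) {
  if (!any(obs$timestamp %in% run$hours)) {
    stop("no overlapping timestamps between run and observations")
  }
  species <- unique(obs$species)
  by_site <- list(); pooled <- list()
  for (sp in species) {
    for (sid in unique(obs$site_id)) {
      rows <- obs[obs$species == sp & obs$site_id == sid, ]
      loc <- sites[sites$site_id == sid, ]
      if (nrow(loc) == 0) next
      m <- extract_site_series(run, loc$x[1], loc$y[1], sp)
      idx <- match(rows$timestamp, run$hours)
      df <- data.frame(timestamp = rows$timestamp,
                       modelled = m[idx], observed = rows$value_ppb)
      keep <- is.finite(df$modelled) & is.finite(df$observed)
      if (sum(keep) < 2) next
      st <- eval_stats(df$modelled, df$observed)
      by_site[[length(by_site) + 1]] <-
        cbind(data.frame(species = sp, site_id = sid,
                         site_type = rows$site_type[1]), st)
      pooled[[length(pooled) + 1]] <-
        cbind(data.frame(species = sp, site_type = rows$site_type[1]),
              df[keep, ])
    }
  }
  by_site <- do.call(rbind, by_site)
  pooled <- do.call(rbind, pooled)
  by_type <- list()
  for (sp in unique(pooled$species)) {
    sub_sp <- pooled[pooled$species == sp, ]
    groups <- c(stats::setNames(nm = unique(sub_sp$site_type)), All = "All")
    for (g in names(groups)) {
      sub <- if (g == "All") sub_sp else sub_sp[sub_sp$site_type == g, ]
      if (nrow(sub) < 2) next
      n_sites <- length(unique(by_site$site_id[by_site$species == sp &
        (g == "All" | by_site$site_type == g)]))
      by_type[[length(by_type) + 1]] <-
        cbind(data.frame(species = sp, site_type = g, sites = n_sites),
              eval_stats(sub$modelled, sub$observed))
    }
  }
  profiles <- list()
  for (sp in unique(pooled$species)) {
    sub <- pooled[pooled$species == sp, ]
    profiles[[sp]] <- lapply(stats::setNames(nm = profile_modes),
                             function(md) residual_profile(
                               sub$timestamp, sub$modelled, sub$observed, md))
  }
  list(by_site = by_site, by_type = do.call(rbind, by_type),
       profiles = profiles)
}

#' Write the hourly fields of a run to long-format CSV
#'
#' Columns: `timestamp`, `x`, `y`, `no`, `no2`, `o3`, `tof`. One row per
#' cell and hour; skipped hours are omitted.
#'
#' @param run an `aq_run`
#' @param path output CSV
#' @export
write_fields_csv <- function(run, path) {
  cc <- cell_centers(run$grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("timestamp,x,y,no,no2,o3,tof", con)
  for (t in seq_along(run$fields)) {
    f <- run$fields[[t]]
    if (is.null(f)) next
    df <- data.frame(
      timestamp = format(run$hours[t], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      x = rep(cc$x, times = run$grid$ny),
      y = rep(cc$y, each = run$grid$nx),
      no = as.vector(f$no), no2 = as.vector(f$no2),
      o3 = as.vector(f$o3), tof = as.vector(f$tof))
    utils::write.table(df, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read coarse background fields from long-format CSV
#'
#' Columns: `timestamp`, `x`, `y`, `species` (NO/NO2/O3), `value_ppb`,
#' with `x`, `y` the coarse cell centres on a regular grid.
#'
#' @param path CSV file
#' @return list as [make_background_fields()]
#' @export
read_background_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- parse_utc(df$timestamp)
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  hours <- sort(unique(df$timestamp))
  sp <- diff(xs)[1]
  grid <- grid_spec(xs[1] - sp / 2, ys[1] - sp / 2, sp,
                    length(xs), length(ys))
  arr <- function(species) {
    a <- array(NA_real_, c(length(xs), length(ys), length(hours)))
    sub <- df[df$species == species, ]
    a[cbind(match(sub$x, xs), match(sub$y, ys),
            match(sub$timestamp, hours))] <- sub$value_ppb
    a
  }
  list(grid = grid, hours = hours,
       no = arr("NO"), no2 = arr("NO2"), o3 = arr("O3"))
}

#' Write coarse background fields to long-format CSV
#' @param background list as [make_background_fields()]
#' @param path output CSV
#' @export
write_background_csv <- function(background, path) {
  cc <- cell_centers(background$grid)
  rows <- list()
  for (sp in c("NO", "NO2", "O3")) {
    a <- background[[tolower(sp)]]
    for (t in seq_along(background$hours)) {
      rows[[length(rows) + 1]] <- data.frame(
        timestamp = format(background$hours[t], "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC"),
        x = rep(cc$x, times = background$grid$ny),
        y = rep(cc$y, each = background$grid$nx),
        species = sp, value_ppb = as.vector(a[, , t]))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Generate and write the complete fixture set to a directory
#'
#' Emits the exact file formats the pipeline consumes: roads GeoJSON, met
#' CSV, background CSV, sites CSV and double-counting site records CSV.
#'
#' @param cfg a [fixture_config()]
#' @param dir output directory (created if missing)
#' @return invisible list of written paths
#' @export
write_fixtures <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  links <- make_road_network(cfg)
  met <- make_met_series(cfg)
  bg <- make_background_fields(cfg)
  paths <- list(
    roads = file.path(dir, "roads.geojson"),
    met = file.path(dir, "met.csv"),
    background = file.path(dir, "background.csv"),
    doublecount = file.path(dir, "doublecount_sites.csv"))
  write_roads_geojson(links, paths$roads)
  met_out <- met
  met_out$timestamp <- format(met$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(met_out, paths$met, row.names = FALSE, quote = FALSE)
  write_background_csv(bg, paths$background)
  utils::write.csv(make_doublecount_sites(cfg), paths$doublecount,
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a run configuration from YAML
#'
#' Fields: `roads`, `met`, `background` (paths), optional `observations`,
#' `output`; `grid` (x0, y0, spacing, nx, ny); optional `seed`,
#' `chemistry` (list: j_max, e or `j_csv`), `kernel` (list passed to the
#' kernel builder). All referenced input paths must exist (fail-fast).
#'
#' @param path YAML file
#' @return validated config list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (p in c("roads", "met", "background")) {
    if (is.null(cfg[[p]])) stop("config missing required path: ", p)
    if (!file.exists(cfg[[p]])) stop("config path does not exist: ", cfg[[p]])
  }
  g <- cfg$grid
  if (is.null(g)) stop("config missing grid")
  cfg$grid_spec <- grid_spec(g$x0, g$y0, g$spacing, g$nx, g$ny)
  cfg
}
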