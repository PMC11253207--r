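#' Build a pipeline configuration
#'
#' A configuration is an ordinary named list (serialisable to YAML) with the
#' master seed, the site list, the seasons to simulate and optional
#' overrides for the generator, the MTR settings, the boosting
#' hyperparameters and the flight track minimum.
#'
#' @param sites list of site definitions (each a named list with the
#'   [site_config()] fields)
#' @param seasons list of `list(season, year)`
#' @param seed master seed
#' @param world named list of [sim_world()] argument overrides
#' @param mtr list: `bin_start`, `bin_end`, `bin_width` (m), `alpha`
#' @param brt named list of [brt_hyperparams()] overrides, plus optional
#'   `marginal_covariates`
#' @param min_tracks minimum bird tracks per flight night
#' @param night_limit optional cap on nights simulated per site-season
#'   (first N evenings); useful for demonstration runs
#' @return named list (class `pipeline_config`)
#' @export
pipeline_config <- function(sites, seasons, seed = 1L, world = list(),
                            mtr = list(), brt = list(), min_tracks = 5L,
                            night_limit = NULL) {
  cfg <- list(seed = as.integer(seed), sites = sites, seasons = seasons,
              world = world,
              mtr = modifyList(list(bin_start = 50, bin_end = 1500,
                                    bin_width = 50, alpha = 0.05), mtr),
              brt = brt, min_tracks = min_tracks,
              night_limit = night_limit)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' A small two-site demonstration configuration
#'
#' One vertical-looking radar in the north and one high-elevation weather
#' radar in the south, one spring and one autumn, capped at 30 nights per
#' site-season, with a reduced boosting tree cap so the model stage runs in
#' seconds.
#'
#' @param seed master seed
#' @return a [pipeline_config()]
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    sites = list(
      list(site_id = "vlr_north", latitude = 33.1, longitude = 35.6,
           elevation = 70, radar_type = "vertical-looking"),
      list(site_id = "wr_south", latitude = 30.6, longitude = 34.8,
           elevation = 868, radar_type = "weather")),
    seasons = list(list(season = "spring", year = 2018),
                   list(season = "autumn", year = 2018)),
    seed = seed,
    brt = list(max_trees = 1000, learning_rate = 0.01),
    night_limit = 30)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path
#' @return [read_pipeline_config()] returns a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- pipeline_config(sites = cfg$sites, seasons = cfg$seasons,
                         seed = cfg$seed %||% 1L,
                         world = cfg$world %||% list(),
                         mtr = cfg$mtr %||% list(),
                         brt = cfg$brt %||% list(),
                         min_tracks = cfg$min_tracks %||% 5L,
                         night_limit = cfg$night_limit)
  cfg
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' @param config a `pipeline_config`
#' @return invisibly TRUE; stops with an itemised message on violations
#' @export
validate_pipeline_config <- function(config) {
  errs <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(is.numeric(config$seed) && length(config$seed) == 1,
       "seed: single integer required")
  need(length(config$sites) >= 1, "sites: at least one site required")
  for (i in seq_along(config$sites)) {
    s <- config$sites[[i]]
    for (f in c("site_id", "latitude", "longitude", "elevation", "radar_type"))
      need(!is.null(s[[f]]), sprintf("sites[%d]: field '%s' missing", i, f))
    if (!is.null(s$latitude))
      need(abs(s$latitude) < 66, sprintf("sites[%d]: latitude beyond 66 deg", i))
    if (!is.null(s$radar_type))
      need(s$radar_type %in% c("weather", "vertical-looking"),
           sprintf("sites[%d]: unknown radar_type '%s'", i, s$radar_type))
  }
  need(length(config$seasons) >= 1, "seasons: at least one season required")
  for (i in seq_along(config$seasons)) {
    ss <- config$seasons[[i]]
    need(!is.null(ss$season) && ss$season %in% c("spring", "autumn"),
         sprintf("seasons[%d]: season must be 'spring' or 'autumn'", i))
    need(!is.null(ss$year), sprintf("seasons[%d]: year missing", i))
  }
  need(config$mtr$bin_width > 0, "mtr: bin_width must be positive")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(TRUE)
}

config_world <- function(config) {
  sites <- lapply(config$sites, function(s) do.call(site_config, s))
  args <- c(list(sites = sites, seasons = config$seasons,
                 rng_seed = config$seed), config$world)
  do.call(sim_world, args)
}

config_bins <- function(config) {
  seq(config$mtr$bin_start, config$mtr$bin_end, by = config$mtr$bin_width)
}

## ---- stage machinery --------------------------------------------------

#' Pipeline stage names, in dependency order
#' @return character vector
#' @export
pipeline_stages <- function() {
  c("simulate", "preprocess", "mtr", "covariates", "flight", "model",
    "contrasts")
}

# upstream files each stage reads, and the stage that produces them
stage_requirements <- function() {
  list(
    simulate = character(),
    preprocess = c(sites = "simulate", echoes = "simulate",
                   rain = "simulate", nights = "simulate"),
    mtr = c(sites = "simulate", rain = "simulate", nights = "simulate",
            filtered_echoes = "preprocess"),
    covariates = c(sites = "simulate", weather = "simulate",
                   nights = "simulate", mtr_nightly = "mtr"),
    flight = c(sites = "simulate", filtered_echoes = "preprocess",
               covariates = "covariates"),
    model = c(modelling_table = "covariates"),
    contrasts = c(night_flight = "flight", covariates = "covariates")
  )
}

stage_path <- function(dir, name, ext = "csv")
  file.path(dir, paste0(name, ".", ext))

plog <- function(level, stage, msg, ..., log_level = "info") {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[log_level]])
    message(sprintf("[%s] %s: %s", level, stage, sprintf(msg, ...)))
}

fmt_utc <- function(x) paste0(format(x, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"), "Z")

parse_utc <- function(x)
  as.POSIXct(strptime(sub("Z$", "", x), "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))

write_stage_csv <- function(df, dir, name) {
  for (cl in names(df)) if (inherits(df[[cl]], "POSIXct"))
    df[[cl]] <- fmt_utc(df[[cl]])
  path <- stage_path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

read_stage_csv <- function(dir, name, stage, producers) {
  path <- stage_path(dir, name)
  if (!file.exists(path))
    stop(sprintf(
      "stage '%s' needs %s, which does not exist; run stage '%s' first",
      stage, path, producers[[name]]), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (cl in intersect(names(df), c("timestamp", "start", "end",
                                    "sunset", "sunrise")))
    df[[cl]] <- parse_utc(df[[cl]])
  df
}

#' Run the analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> mtr -> covariates -> flight ->
#' model -> contrasts over a single configuration. Each stage reads only
#' the CSV outputs of upstream stages from `out_dir`, so partial runs
#' resume from cached artifacts, and re-running with the same configuration
#' and seed reproduces identical outputs. A manifest (config hash, seed,
#' per-stage row counts, file list) is written to `manifest.json`.
#'
#' @param config a `pipeline_config`, or the path to a YAML file
#' @param out_dir output directory (created if needed)
#' @param stages subset of stage names to run, in any order (dependency
#'   order is enforced); default all
#' @param log_level `"debug"`, `"info"`, `"warn"` or `"error"`
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config, out_dir, stages = pipeline_stages(),
                         log_level = "info") {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(config_hash = config_hash(config),
                   master_seed = config$seed,
                   package_version = as.character(packageVersion("nightmtr")),
                   created_utc = fmt_utc(Sys.time()),
                   stages = list())
  for (st in stages) {
    plog("info", st, "starting", log_level = log_level)
    rec <- switch(st,
      simulate = stage_simulate(config, out_dir),
      preprocess = stage_preprocess(config, out_dir),
      mtr = stage_mtr(config, out_dir),
      covariates = stage_covariates(config, out_dir),
      flight = stage_flight(config, out_dir),
      model = stage_model(config, out_dir),
      contrasts = stage_contrasts(config, out_dir))
    plog("info", st, "done (%d rows in, %d rows out)",
         rec$rows_in, rec$rows_out, log_level = log_level)
    manifest$stages[[st]] <- rec
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

site_dates <- function(config, site_id = NULL) {
  dates <- sort(unique(do.call(c, lapply(config$seasons, function(ss) {
    d <- season_dates(ss$season, ss$year)
    if (!is.null(config$night_limit))
      d <- d[seq_len(min(config$night_limit, length(d)))]
    d
  }))))
  dates
}

## ---- stages -----------------------------------------------------------

stage_simulate <- function(config, dir) {
  world <- config_world(config)
  parts <- list()
  for (site in world$sites) {
    for (ss in world$seasons) {
      dates <- season_dates(ss$season, ss$year)
      if (!is.null(config$night_limit))
        dates <- dates[seq_len(min(config$night_limit, length(dates)))]
      weather <- generate_weather(world, site, ss$season, ss$year)
      nights <- solar_nights(site$latitude, site$longitude, dates)
      ech <- lapply(seq_len(nrow(nights)), function(i)
        generate_night_echoes(world, site, nights[i, ], weather))
      parts[[length(parts) + 1L]] <- list(
        weather = weather, nights = cbind(site_id = site$site_id, nights),
        echoes = do.call(rbind, lapply(ech, `[[`, "echoes")),
        truth = do.call(rbind, lapply(ech, `[[`, "truth")),
        rain = do.call(rbind, lapply(ech, `[[`, "rain")),
        intensity = data.frame(site_id = site$site_id,
                               night_id = nights$night_id,
                               season = ss$season,
                               expected_migrants =
                                 vapply(ech, `[[`, 0, "intensity")))
    }
  }
  stack <- function(nm) {
    out <- do.call(rbind, lapply(parts, `[[`, nm)); rownames(out) <- NULL; out
  }
  files <- c(
    write_stage_csv(sites_as_df(world$sites), dir, "sites"),
    write_stage_csv(stack("weather"), dir, "weather"),
    write_stage_csv(stack("nights"), dir, "nights"),
    write_stage_csv(stack("echoes"), dir, "echoes"),
    write_stage_csv(stack("truth"), dir, "echoes_truth"),
    write_stage_csv(stack("rain"), dir, "rain"),
    write_stage_csv(stack("intensity"), dir, "true_intensity"))
  ech <- stack("echoes")
  list(rows_in = 0L, rows_out = nrow(ech), files = as.character(files))
}

stage_preprocess <- function(config, dir) {
  req <- stage_requirements()$preprocess
  sites <- read_stage_csv(dir, "sites", "preprocess", req)
  echoes <- read_stage_csv(dir, "echoes", "preprocess", req)
  rain <- read_stage_csv(dir, "rain", "preprocess", req)
  nights <- read_stage_csv(dir, "nights", "preprocess", req)
  out <- list(); qc <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    pp <- preprocess_site(echoes[echoes$site_id == s$site_id, , drop = FALSE],
                          s, unique(nights$night_id[nights$site_id == s$site_id]),
                          rain[rain$site_id == s$site_id, , drop = FALSE])
    out[[i]] <- pp$echoes; qc[[i]] <- pp$qc
  }
  filtered <- do.call(rbind, out); rownames(filtered) <- NULL
  qc <- do.call(rbind, qc)
  f1 <- write_stage_csv(filtered, dir, "filtered_echoes")
  qcpath <- stage_path(dir, "qc", "jsonl")
  writeLines(vapply(seq_len(nrow(qc)), function(i)
    as.character(jsonlite::toJSON(as.list(qc[i, ]), auto_unbox = TRUE)),
    character(1)), qcpath)
  list(rows_in = nrow(echoes), rows_out = nrow(filtered),
       files = c(f1, qcpath))
}

stage_mtr <- function(config, dir) {
  req <- stage_requirements()$mtr
  sites <- read_stage_csv(dir, "sites", "mtr", req)
  rain <- read_stage_csv(dir, "rain", "mtr", req)
  nights <- read_stage_csv(dir, "nights", "mtr", req)
  filtered <- read_stage_csv(dir, "filtered_echoes", "mtr", req)
  bins <- config_bins(config)
  rows <- list()
  for (i in seq_len(nrow(nights))) {
    nt <- nights[i, ]
    s <- sites[sites$site_id == nt$site_id, ]
    e <- filtered[filtered$site_id == nt$site_id &
                    filtered$night_id == nt$night_id, , drop = FALSE]
    r <- mtr_profile(e, nt, bins, s$effective_transect_width_km,
                     rain[rain$site_id == nt$site_id, , drop = FALSE],
                     alpha = config$mtr$alpha)
    r$site_id <- nt$site_id
    rows[[i]] <- r
  }
  mtr <- do.call(rbind, rows); rownames(mtr) <- NULL
  f <- write_stage_csv(mtr, dir, "mtr_nightly")
  list(rows_in = nrow(filtered), rows_out = nrow(mtr), files = f)
}

stage_covariates <- function(config, dir) {
  req <- stage_requirements()$covariates
  sites <- read_stage_csv(dir, "sites", "covariates", req)
  weather <- read_stage_csv(dir, "weather", "covariates", req)
  nights <- read_stage_csv(dir, "nights", "covariates", req)
  mtr <- read_stage_csv(dir, "mtr_nightly", "covariates", req)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    wn <- nights[nights$site_id == s$site_id, , drop = FALSE]
    wx <- weather[weather$site_id == s$site_id, , drop = FALSE]
    wn$season <- season_of_date(wn$night_id)
    for (se in unique(wn$season)) {
      nn <- wn[wn$season == se, , drop = FALSE]
      rows[[length(rows) + 1L]] <- season_covariates(wx, nn, s, se)
    }
  }
  cov <- do.call(rbind, rows); rownames(cov) <- NULL
  mt <- modelling_table(cov, mtr)
  f1 <- write_stage_csv(cov, dir, "covariates")
  f2 <- write_stage_csv(mt, dir, "modelling_table")
  scr <- correlation_screen(mt, predictors = setdiff(
    brt_covariates(), "radar_type"))
  f3 <- stage_path(dir, "correlation_screen", "json")
  jsonlite::write_json(list(threshold = scr$threshold, flagged = scr$flagged,
                            constant = scr$constant),
                       f3, auto_unbox = TRUE, digits = NA)
  list(rows_in = nrow(weather), rows_out = nrow(mt), files = c(f1, f2, f3))
}

stage_flight <- function(config, dir) {
  req <- stage_requirements()$flight
  sites <- read_stage_csv(dir, "sites", "flight", req)
  filtered <- read_stage_csv(dir, "filtered_echoes", "flight", req)
  cov <- read_stage_csv(dir, "covariates", "flight", req)
  rows <- list()
  vlr <- sites$site_id[sites$radar_type == "vertical-looking"]
  for (sid in vlr) {
    e <- filtered[filtered$site_id == sid, , drop = FALSE]
    if (nrow(e) == 0L) next
    e$season <- season_of_date(e$night_id)
    for (se in unique(e$season)) {
      rows[[length(rows) + 1L]] <- flight_table(
        e[e$season == se, , drop = FALSE],
        cov[cov$site_id == sid & cov$season == se, , drop = FALSE],
        se, config$min_tracks)
    }
  }
  fl <- if (length(rows)) do.call(rbind, rows) else empty_flight_table()
  rownames(fl) <- NULL
  f <- write_stage_csv(fl, dir, "night_flight")
  list(rows_in = nrow(filtered), rows_out = nrow(fl), files = f)
}

stage_model <- function(config, dir) {
  req <- stage_requirements()$model
  mt <- read_stage_csv(dir, "modelling_table", "model", req)
  hp <- do.call(brt_hyperparams,
                config$brt[setdiff(names(config$brt), "marginal_covariates")])
  marg_cov <- config$brt$marginal_covariates %||%
    c("temperature", "wind_speed", "v", "u", "ordinal_date")
  files <- character()
  for (se in sort(unique(mt$season))) {
    d <- mt[mt$season == se, , drop = FALSE]
    fit <- fit_brt(d, "log_mtr", brt_covariates(), hp,
                   seed = derive_seed(config$seed, "brt", se))
    imp <- relative_importance(fit)
    fsum <- stage_path(dir, paste0("model_summary_", se), "json")
    jsonlite::write_json(list(
      season = se, n_rows = nrow(d),
      hyperparams = unclass(hp),
      n_trees_selected = fit$n_trees_selected,
      cv_correlation = fit$cv_correlation,
      importance = imp), fsum, auto_unbox = TRUE, digits = NA)
    marg <- do.call(rbind, lapply(intersect(marg_cov, fit$covariates),
                                  function(cv) marginal_response(fit, cv)))
    fm <- write_stage_csv(marg, dir, paste0("marginal_responses_", se))
    files <- c(files, fsum, fm)
  }
  list(rows_in = nrow(mt), rows_out = nrow(mt), files = files)
}

stage_contrasts <- function(config, dir) {
  req <- stage_requirements()$contrasts
  fl <- read_stage_csv(dir, "night_flight", "contrasts", req)
  cov <- read_stage_csv(dir, "covariates", "contrasts", req)
  both <- all(c("spring", "autumn") %in% fl$season) && nrow(fl) > 3
  rows <- list()
  if (both) {
    for (resp in c("groundspeed", "airspeed"))
      rows[[resp]] <- lmm_season_effect(fl, resp)
  }
  contr <- if (length(rows)) do.call(rbind, rows) else NULL
  files <- character()
  if (!is.null(contr)) {
    rownames(contr) <- NULL
    files <- c(files, write_stage_csv(contr, dir, "season_contrasts"))
  }
  wt <- seasonal_weather_tests(cov)
  files <- c(files, write_stage_csv(wt, dir, "weather_tests"))
  if (both) {
    sc <- speed_contrasts(
      mean(fl$groundspeed[fl$season == "spring"], na.rm = TRUE),
      mean(fl$groundspeed[fl$season == "autumn"], na.rm = TRUE),
      mean(fl$airspeed[fl$season == "spring"], na.rm = TRUE),
      mean(fl$airspeed[fl$season == "autumn"], na.rm = TRUE))
    fsc <- stage_path(dir, "speed_contrasts", "json")
    jsonlite::write_json(sc, fsc, auto_unbox = TRUE, digits = NA)
    files <- c(files, fsc)
  }
  list(rows_in = nrow(fl) + nrow(cov), rows_out = nrow(wt), files = files)
}
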