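# Shared CSV/YAML readers and writers and the pipeline driver. All tabular
# I/O is plain CSV with documented headers; every file starts with comment
# lines stamping the depth convention, assumed constants and seeds.

.depth_convention <- "depth in mm, positive down, 0 = sediment-water interface"

.write_csv_commented <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

.read_csv_commented <- function(path) {
  lines <- readLines(path)
  utils::read.csv(text = paste(lines[!startsWith(lines, "#")],
                               collapse = "\n"),
                  stringsAsFactors = FALSE)
}

#' Write voltammetric scans to CSV
#'
#' Columns: `potential_V`, `current_nA`, `segment`, `depth_mm`, `replicate`.
#'
#' @param scans list of [voltammogram()]s.
#' @param path output file.
#' @param seed generator seed recorded in the header (optional).
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(scans, path, seed = NA_integer_) {
  rows <- lapply(scans, function(s) {
    data.frame(potential_V = s$potential_V, current_nA = s$current_nA,
               segment = s$segment, depth_mm = attr(s, "depth_mm"),
               replicate = attr(s, "replicate"), stringsAsFactors = FALSE)
  })
  .write_csv_commented(do.call(rbind, rows), path,
                       c(.depth_convention,
                         sprintf("seed: %s", seed)))
  invisible(path)
}

#' Read voltammetric scans from CSV
#'
#' Expects the headers written by [write_scan_table()]; scans are grouped by
#' `(depth_mm, replicate)`. Rows with missing or non-numeric fields are
#' rejected with their line numbers; non-monotone potentials within a
#' segment are an error.
#'
#' @param path CSV file.
#' @return list of [voltammogram()]s ordered by depth then replicate.
#' @export
read_scan_table <- function(path) {
  df <- .read_csv_commented(path)
  req <- c("potential_V", "current_nA", "segment", "depth_mm", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("scan table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$potential_V) | !is.finite(df$current_nA) |
                 !df$segment %in% c("forward", "backward"))
  if (length(bad))
    stop("malformed scan rows at data line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  keys <- unique(df[c("depth_mm", "replicate")])
  keys <- keys[order(keys$depth_mm, keys$replicate), ]
  lapply(seq_len(nrow(keys)), function(i) {
    g <- df[df$depth_mm == keys$depth_mm[i] &
              df$replicate == keys$replicate[i], ]
    voltammogram(g$potential_V, g$current_nA, g$segment,
                 depth_mm = keys$depth_mm[i], replicate = keys$replicate[i])
  })
}

#' Write a porewater concentration profile to CSV
#'
#' Columns: `depth_mm`, `analyte`, `conc_uM`, `sd_uM`, `censored`,
#' `source_signal`.
#'
#' @param profile a [porewater_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "porewater_profile"))
  .write_csv_commented(
    profile$data[c("depth_mm", "analyte", "conc_uM", "sd_uM", "censored",
                   "source_signal")],
    path,
    c(.depth_convention,
      sprintf("station: %s", profile$station),
      sprintf("water_depth_m: %g", profile$water_depth_m),
      sprintf("porosity_surface: %g (assumed if no field value)",
              profile$porosity_surface),
      sprintf("salinity: %g, temperature_C: %g", profile$salinity,
              profile$temperature),
      sprintf("seed: %s", profile$seed)))
  invisible(path)
}

#' Read a porewater concentration profile from CSV
#'
#' @param path CSV written by [write_profile_csv()].
#' @param station,water_depth_m,porosity_surface overrides; defaults are
#'   recovered from the file header comments where present.
#' @return a [porewater_profile()].
#' @export
read_profile_csv <- function(path, station = NULL, water_depth_m = NA_real_,
                             porosity_surface = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  pick <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(strsplit(sub(paste0("^# ", key, ": *"), "", m[1]), " ")[[1]][1])
  }
  if (is.null(station)) station <- pick("station")
  if (is.null(station)) station <- basename(path)
  if (is.na(water_depth_m)) {
    w <- pick("water_depth_m")
    water_depth_m <- if (is.null(w)) NA_real_ else as.numeric(w)
  }
  if (is.null(porosity_surface)) {
    p <- pick("porosity_surface")
    porosity_surface <- if (is.null(p)) NULL else as.numeric(p)
  }
  df <- .read_csv_commented(path)
  porewater_profile(station = station, water_depth_m = water_depth_m,
                    data = df, porosity_surface = porosity_surface)
}

#' Write chamber incubation series to CSV
#'
#' Columns: `deployment`, `chamber`, `time_h`, `conc_uM`, `censored`.
#'
#' @param incubations list of [chamber_incubation()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chamber_csv <- function(incubations, path) {
  rows <- lapply(incubations, function(x)
    data.frame(deployment = x$deployment, chamber = x$chamber,
               water_depth_m = x$water_depth_m, height_m = x$height_m,
               time_h = x$data$time_h, conc_uM = x$data$conc_uM,
               censored = ifelse(x$data$censored, "bdl", "ok"),
               stringsAsFactors = FALSE))
  .write_csv_commented(do.call(rbind, rows), path, "chamber time series")
  invisible(path)
}

#' Read chamber incubation series from CSV
#'
#' @param path CSV with columns `deployment`, `chamber`, `time_h`,
#'   `conc_uM`, and optionally `censored`, `water_depth_m`, `height_m`.
#' @param default_height_m enclosed height used when the file has none.
#' @return list of [chamber_incubation()]s.
#' @export
read_chamber_csv <- function(path, default_height_m = 0.15) {
  df <- .read_csv_commented(path)
  req <- c("deployment", "chamber", "time_h", "conc_uM")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("chamber table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$censored)) df$censored <- "ok"
  keys <- unique(df[c("deployment", "chamber")])
  lapply(seq_len(nrow(keys)), function(i) {
    g <- df[df$deployment == keys$deployment[i] &
              df$chamber == keys$chamber[i], ]
    chamber_incubation(
      deployment = keys$deployment[i], chamber = keys$chamber[i],
      water_depth_m = if (is.null(g$water_depth_m)) NA_real_ else
        g$water_depth_m[1],
      time_h = g$time_h, conc_uM = g$conc_uM,
      censored = g$censored %in% c("bdl", "below_dl", "TRUE"),
      height_m = if (is.null(g$height_m)) default_height_m else g$height_m[1])
  })
}

# Stable hash of a configuration list (md5 of its deparsed text).
.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}

#' Run the full synthetic-to-budget pipeline
#'
#' Executes the stages present in the configuration: `simulate` (scenarios
#' to profiles + scan tables), `voltammetry` (scan tables to concentration
#' profiles), `profile_flux` (profiles to a diffusive-flux table),
#' `chamber_flux` (incubation series to a chamber-flux table) and `budget`.
#' Every assumed constant (porosity, molar mass) is logged via `message()`,
#' and each output file records the configuration hash and seed, so that
#' identical configurations yield byte-identical outputs.
#'
#' @param config configuration list or path to a YAML file. Recognised
#'   sections: `seed`; `out_dir`; `simulate` (list of [scenario()] argument
#'   lists); `voltammetry` (`scans`: path, `analytes`); `profile_flux`
#'   (`windows`, `default_window`); `chamber` (`series`: path or `simulate`:
#'   list of [generate_chamber_series()] argument lists); `budget`
#'   (arguments of [filter_budget()]).
#' @return list with the per-stage results (`profiles`, `truth`,
#'   `flux_table`, `chamber_table`, `budget`) and `files`, the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  hash <- .config_hash(config)
  stamp <- c(sprintf("config_hash: %s", hash), sprintf("seed: %d", seed))
  files <- character(0)
  res <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  profiles <- list()
  if (!is.null(config$simulate)) {
    res$truth <- list()
    profiles <- stage("simulate", {
      out <- list()
      for (i in seq_along(config$simulate)) {
        args <- config$simulate[[i]]
        args$seed <- if (is.null(args$seed)) seed + i else args$seed
        for (fld in c("bottom_water_conc", "production_zone", "mat_layer",
                      "fe_source"))
          if (!is.null(args[[fld]])) args[[fld]] <- unlist(args[[fld]])
        gp <- generate_profile(do.call(scenario, args))
        out[[gp$profile$station]] <- gp$profile
        res$truth[[gp$profile$station]] <- gp$truth
        f <- file.path(out_dir, paste0("profile_", gp$profile$station, ".csv"))
        write_profile_csv(gp$profile, f)
        files <- c(files, f)
      }
      out
    })
  }

  if (!is.null(config$voltammetry)) {
    profiles <- c(profiles, stage("voltammetry", {
      scans <- read_scan_table(config$voltammetry$scans)
      calib <- calibration_model()
      analytes <- config$voltammetry$analytes
      if (is.null(analytes)) analytes <- "H2S"
      depths <- sort(unique(vapply(scans, attr, 0, "depth_mm")))
      rows <- do.call(rbind, lapply(depths, function(d) {
        at_depth <- Filter(function(s) attr(s, "depth_mm") == d, scans)
        do.call(rbind, lapply(analytes, function(an) {
          conc <- replicates_to_concentration(at_depth, calib, an)
          cbind(depth_mm = d, conc)
        }))
      }))
      st <- if (is.null(config$voltammetry$station)) "scans" else
        config$voltammetry$station
      p <- porewater_profile(
        station = st,
        water_depth_m = config$voltammetry$water_depth_m %||% NA_real_,
        data = rows,
        porosity_surface = config$voltammetry$porosity)
      f <- file.path(out_dir, paste0("profile_", st, ".csv"))
      write_profile_csv(p, f)
      files <- c(files, f)
      stats::setNames(list(p), st)
    }))
  }

  if (!is.null(config$profile_flux) && length(profiles)) {
    res$flux_table <- stage("profile_flux", {
      tab <- station_flux_report(unname(profiles), config$profile_flux)
      f <- file.path(out_dir, "flux_table.csv")
      .write_csv_commented(tab, f, c(stamp,
        "diffusive fluxes, mmol m-2 day-1, positive = out of sediment"))
      files <- c(files, f)
      tab
    })
  }

  if (!is.null(config$chamber)) {
    res$chamber_table <- stage("chamber_flux", {
      incs <- if (!is.null(config$chamber$series)) {
        read_chamber_csv(config$chamber$series)
      } else {
        lapply(seq_along(config$chamber$simulate), function(i) {
          args <- config$chamber$simulate[[i]]
          args$seed <- if (is.null(args$seed)) seed + 100 + i else args$seed
          do.call(generate_chamber_series, args)
        })
      }
      tab <- deployment_report(incs)
      f <- file.path(out_dir, "chamber_table.csv")
      .write_csv_commented(tab, f, c(stamp,
        "chamber fluxes, mmol m-2 day-1, bdl = below detection"))
      files <- c(files, f)
      tab
    })
  }

  if (!is.null(config$budget)) {
    res$budget <- stage("budget", {
      b <- do.call(filter_budget, config$budget)
      message(sprintf(
        "budget constants: molar mass %g g/mol, %g day/yr (configurable)",
        b$molar_mass_g, b$days_per_year))
      f <- file.path(out_dir, "budget.json")
      jsonlite::write_json(
        c(list(config_hash = hash, seed = seed), unclass(b)), f,
        auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
      b
    })
  }

  res$files <- files
  res$config_hash <- hash
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
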