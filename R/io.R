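#' Load and validate a run configuration
#'
#' Reads a YAML configuration (flat keys, the units stated in the
#' documentation of each parameter), fills in the documented defaults,
#' validates values, and rejects unknown keys. An empty or missing-file
#' content yields the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    cell_class = "I",
    protocol = "min-spines",        # min-spines | ap-origin | tangential |
                                    # mg-sweep | fi
    location = "terminal_tip",
    plane = "tip",
    hold_nA = 0,
    n_spines = NULL,
    mg_levels = c(0, 0.012, 0.12, 1.2, 2.4),
    mg = 1.2,
    currents_nA = c(0, 0.02, 0.03, 0.035, 0.04, 0.045, 0.05, 0.075, 0.1,
                    0.15, 0.2),
    dt_ms = 0.01,
    t_end_ms = 500,
    sample_ms = 0.1,
    out_dir = "results",
    seed = NULL                     # reserved; the pipeline is deterministic
  )
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  if (!cfg$cell_class %in% c("I", "II", "III"))
    stop("cell_class must be one of I, II, III")
  if (!cfg$protocol %in% c("min-spines", "ap-origin", "tangential",
                           "mg-sweep", "fi"))
    stop("unknown protocol: ", cfg$protocol)
  for (k in c("dt_ms", "t_end_ms", "sample_ms"))
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      stop(k, " must be a positive number")
  if (cfg$sample_ms < cfg$dt_ms) stop("sample_ms must be >= dt_ms")
  if (any(cfg$mg_levels < 0)) stop("mg_levels must be non-negative")
  structure(cfg, class = "run_config")
}

#' Write and read trace tables
#'
#' CSV round trip of the long trace format (time_ms, site, quantity,
#' value), with numeric columns printed at 17 significant digits so that
#' doubles survive the round trip exactly.
#'
#' @param traces A `granule_traces` data frame.
#' @param path Output/input CSV path.
#' @return `read_traces` returns the `granule_traces` table.
#' @export
write_traces <- function(traces, path) {
  stopifnot(is.data.frame(traces),
            all(c("time_ms", "site", "quantity", "value") %in% names(traces)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_ms,site,quantity,value", con)
  if (nrow(traces))
    writeLines(sprintf("%.17g,%s,%s,%.17g", traces$time_ms, traces$site,
                       traces$quantity, traces$value), con)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "time_ms,site,quantity,value")
    stop("malformed trace file (line 1): expected header ",
         "'time_ms,site,quantity,value'")
  if (length(lines) == 1) {
    out <- data.frame(time_ms = numeric(0), site = character(0),
                      quantity = character(0), value = numeric(0))
  } else {
    parts <- strsplit(lines[-1], ",", fixed = TRUE)
    bad <- which(lengths(parts) != 4)
    if (length(bad)) stop("malformed trace file (line ", bad[1] + 1,
                          "): expected 4 comma-separated fields")
    m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
    tm <- suppressWarnings(as.numeric(m[, 1]))
    vl <- suppressWarnings(as.numeric(m[, 4]))
    if (anyNA(tm)) stop("malformed trace file (line ",
                        which(is.na(tm))[1] + 1, "): non-numeric time")
    if (anyNA(vl)) stop("malformed trace file (line ",
                        which(is.na(vl))[1] + 1, "): non-numeric value")
    out <- data.frame(time_ms = tm, site = m[, 2], quantity = m[, 3],
                      value = vl, stringsAsFactors = FALSE)
  }
  class(out) <- c("granule_traces", "data.frame")
  out
}

# unit direction vectors used to embed the stylized tree in 3D for SWC
.swc_directions <- function(comp) {
  dirs <- matrix(0, nrow(comp), 3)
  for (i in seq_len(nrow(comp))) {
    r <- comp$region[i]; b <- comp$branch[i]
    dirs[i, ] <- switch(r,
      soma = c(0, 1, 0),
      trunk = c(0, 1, 0),
      deep = { th <- 2 * pi * (b - 1) / 4
               c(0.6 * cos(th), -0.8, 0.6 * sin(th)) / 1 },
      terminal = { th <- 2 * pi * (b - 1) / 4 + switch(comp$zone[i],
                     base = 0.3, middle = 0.8, tip = 1.4)
                   c(0.5 * cos(th), 0.866, 0.5 * sin(th)) },
      spine_neck = c(1, 0, 0),
      spine_head = c(1, 0, 0))
    dirs[i, ] <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
  }
  dirs
}

#' Export a morphology to SWC
#'
#' Standard 7-column SWC (`id type x y z radius parent`). The stylized tree
#' is embedded in 3D with exact segment lengths; coordinates are synthetic.
#' Type codes: 1 soma, 4 trunk, 3 deep dendrite, 7 terminal dendrite
#' (custom), 5 spine neck (custom), 6 spine head (custom). The soma record
#' has parent -1. Note the missing-spine extra membrane area is not
#' representable in SWC.
#'
#' @param tree A `granule_morphology`.
#' @param path Output path.
#' @return Invisibly the path.
#' @export
export_swc <- function(tree, path) {
  stopifnot(inherits(tree, "granule_morphology"))
  comp <- tree$compartments
  type <- c(soma = 1L, trunk = 4L, deep = 3L, terminal = 7L,
            spine_neck = 5L, spine_head = 6L)[comp$region]
  dirs <- .swc_directions(comp)
  xyz <- matrix(0, nrow(comp), 3)
  for (i in seq_len(nrow(comp))) {
    p <- comp$parent_id[i]
    base <- if (is.na(p)) c(0, 0, 0) else xyz[p, ]
    xyz[i, ] <- if (is.na(p)) c(0, 0, 0) else base + comp$length[i] * dirs[i, ]
  }
  lines <- c("# SWC export: stylized granule cell morphology",
             "# type codes: 1 soma, 3 deep, 4 trunk, 7 terminal, 5 spine neck, 6 spine head",
             sprintf("%d %d %.10g %.10g %.10g %.10g %d",
                     comp$id, type, xyz[, 1], xyz[, 2], xyz[, 3],
                     comp$diameter / 2,
                     ifelse(is.na(comp$parent_id), -1L, comp$parent_id)))
  writeLines(lines, path)
  invisible(path)
}

#' Import a morphology from SWC
#'
#' Reads an SWC file written by [export_swc()], reconstructing topology,
#' regions (from the type codes), segment lengths (from point distances)
#' and diameters. Zone/branch annotations are not stored in SWC and are
#' left unset; structural summaries are unaffected.
#'
#' @param path SWC file path.
#' @return A `granule_morphology` (cell_class `"imported"`).
#' @export
read_swc <- function(path) {
  lines <- grep("^\\s*#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) != 7) stop("malformed SWC: expected 7 columns")
  region <- c("soma", NA, "deep", "trunk", "spine_neck", "spine_head",
              "terminal")[m[, 2]]
  parent <- ifelse(m[, 7] < 0, NA_integer_, as.integer(m[, 7]))
  len <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    len[i] <- if (is.na(parent[i])) 8 else
      sqrt(sum((m[i, 3:5] - m[parent[i], 3:5])^2))
  }
  # the soma point has no parent; its length equals its diameter
  len[is.na(parent)] <- m[is.na(parent), 6] * 2
  comp <- data.frame(id = as.integer(m[, 1]), parent_id = parent,
                     region = region, zone = NA_character_,
                     branch = NA_integer_, seg = NA_integer_,
                     length = len, diameter = m[, 6] * 2, extra_area = 0,
                     stringsAsFactors = FALSE)
  comp$path_dist <- .path_distances(comp)
  necks <- comp$id[comp$region == "spine_neck"]
  heads <- comp$id[comp$region == "spine_head"]
  spines <- data.frame(neck_id = necks,
                       head_id = heads[match(necks, comp$parent_id[heads])],
                       parent_id = comp$parent_id[necks])
  structure(list(cell_class = "imported", compartments = comp,
                 spines = spines, params = NULL),
            class = "granule_morphology")
}

#' Build a reproducible run manifest
#'
#' Captures the resolved configuration, package and R versions, wall time
#' and an inventory of output files with MD5 checksums. Re-running the same
#' configuration reproduces the checksummed outputs exactly (the pipeline
#' has no random number generation).
#'
#' @param config A `run_config`.
#' @param files Character vector of output file paths.
#' @param wall_time_s Elapsed wall time, s.
#' @param path If non-NULL, write the manifest there as JSON.
#' @return The manifest list.
#' @export
run_manifest <- function(config, files, wall_time_s = NA_real_, path = NULL) {
  man <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("granulesim")),
    r_version = R.version.string,
    wall_time_s = wall_time_s,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(man)
}

#' Run a configured protocol end to end
#'
#' Dispatches a `run_config` to the matching experiment driver, writes the
#' trace tables and a machine-readable summary into the output directory,
#' and emits a run manifest.
#'
#' @param config A `run_config` from [load_config()].
#' @return Invisibly, the summary list.
#' @export
run_protocol <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- granule_model(config$cell_class)
  if (config$mg != 1.2) {
    model$arrays$syn$mg <- config$mg
    model$biophys$synapse$nmda$mg <- config$mg
  }
  files <- character(0)
  out <- switch(config$protocol,
    "min-spines" = {
      res <- min_spines_for_spike(model, config$location,
                                  n_max = config$n_spines,
                                  t_end_ms = config$t_end_ms,
                                  dt_ms = config$dt_ms)
      list(min_spines = res$min_spines, latencies_ms = as.list(res$latencies),
           epsp_peak_mV = as.list(res$epsp_peak_mV))
    },
    "ap-origin" = {
      res <- ap_origin(model, config$location, n_spines = config$n_spines,
                       t_end_ms = config$t_end_ms, dt_ms = config$dt_ms)
      f <- file.path(config$out_dir, "ap_origin_traces.csv")
      write_traces(res$traces, f); files <- c(files, f)
      res$traces <- NULL
      unclass(res)
    },
    "tangential" = {
      res <- tangential_stimulation(model, config$plane, config$hold_nA,
                                    t_end_ms = max(config$t_end_ms, 600),
                                    dt_ms = config$dt_ms)
      f <- file.path(config$out_dir, "tangential_traces.csv")
      write_traces(res$traces, f); files <- c(files, f)
      res$traces <- NULL
      res
    },
    "mg-sweep" = {
      res <- mg_sweep(model, config$mg_levels, t_end_ms = config$t_end_ms,
                      dt_ms = config$dt_ms)
      as.list(res)
    },
    "fi" = {
      res <- fi_curve(model, config$currents_nA, dt_ms = config$dt_ms)
      as.list(res)
    })
  summary_file <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(out, summary_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, summary_file)
  run_manifest(config, files,
               wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
               path = file.path(config$out_dir, "manifest.json"))
  invisible(out)
}
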