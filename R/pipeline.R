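#' Run configuration
#'
#' Bundles every input and setting of a per-lesion analysis run. Paths are
#' resolved relative to the config file's directory when read from YAML.
#'
#' @param sections character vector of cross-section JSON paths, ordered
#'   proximal to distal, or a directory containing `frame_*.json` files.
#' @param labels optional character vector of position labels (PR/PS/MLA/
#'   DS/DR) matching `sections`; if `NULL`, representative frames are
#'   selected from the lumen areas of all sections.
#' @param tracing path to the pressure tracing CSV.
#' @param pullback path to the pullback curve CSV.
#' @param materials path to a materials YAML (default: packaged table).
#' @param output_dir run output directory.
#' @param h_superficial,h_bulk mesh sizes, mm.
#' @param n_steps monotone load steps to the peak.
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds synthetic-study generation).
#' @param control a [solver_control()].
#' @param write_vtk write per-frame VTK field files (default TRUE).
#' @return object of class `"run_config"`.
#' @export
run_config <- function(sections, labels = NULL, tracing, pullback,
                       materials = NULL, output_dir = "pss_run",
                       h_superficial = 0.045, h_bulk = 0.15, n_steps = 10L,
                       seed = 1L, control = solver_control(),
                       write_vtk = TRUE) {
  if (length(sections) == 1L && dir.exists(sections))
    sections <- sort(list.files(sections, "^frame_.*\\.json$", full.names = TRUE))
  if (!length(sections)) stop("config error at 'sections': no section files")
  missing <- sections[!file.exists(sections)]
  if (length(missing))
    stop("config error at 'sections': missing file(s) ",
         paste(missing, collapse = ", "))
  if (!is.null(labels) && length(labels) != length(sections))
    stop("config error at 'labels': length must match 'sections'")
  if (!file.exists(tracing)) stop("config error at 'tracing': file not found")
  if (!file.exists(pullback)) stop("config error at 'pullback': file not found")
  if (!is.null(materials) && !file.exists(materials))
    stop("config error at 'materials': file not found")
  structure(list(sections = sections, labels = labels, tracing = tracing,
                 pullback = pullback, materials = materials,
                 output_dir = output_dir, h_superficial = h_superficial,
                 h_bulk = h_bulk, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), control = control,
                 write_vtk = isTRUE(write_vtk)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()] (paths relative to
#'   the file's directory; `control` fields override [solver_control()]
#'   defaults).
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else
    ifelse(grepl("^/", p), p, file.path(base, p))
  ctl <- do.call(solver_control, cfg$control %||% list())
  run_config(sections = rel(unlist(cfg$sections)),
             labels = cfg$labels %||% NULL,
             tracing = rel(cfg$tracing), pullback = rel(cfg$pullback),
             materials = rel(cfg$materials %||% NULL),
             output_dir = rel(cfg$output_dir %||% "pss_run"),
             h_superficial = cfg$h_superficial %||% 0.045,
             h_bulk = cfg$h_bulk %||% 0.15,
             n_steps = cfg$n_steps %||% 10L,
             seed = cfg$seed %||% 1L,
             control = ctl,
             write_vtk = cfg$write_vtk %||% TRUE)
}

#' Analyze one lesion end to end
#'
#' For each selected frame: build the layered geometry, mesh it, derive the
#' frame's relative-pressure load from the tracing and the pullback curve,
#' solve the pressure cycle and compute the stress metrics. Frames are
#' isolated: a failure in one frame is recorded in the manifest and does not
#' abort the others. Writes `results.csv`, `manifest.json` and (optionally)
#' per-frame VTK fields into the output directory.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `results` (data.frame) and `manifest`.
#' @export
run_lesion <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  read_failures <- list()
  sections <- list()
  labels_in <- config$labels
  keep_labels <- character(0)
  for (i in seq_along(config$sections)) {
    cs <- tryCatch(read_cross_section(config$sections[[i]]),
                   error = function(e) e)
    if (inherits(cs, "error")) {
      read_failures[[length(read_failures) + 1L]] <- list(
        frame_id = NA_integer_, label = if (is.null(labels_in)) NA_character_
          else labels_in[i],
        file = basename(config$sections[[i]]), status = "failed",
        message = conditionMessage(cs), seconds = 0)
    } else {
      sections[[length(sections) + 1L]] <- cs
      if (!is.null(labels_in)) keep_labels <- c(keep_labels, labels_in[i])
    }
  }
  labels <- if (is.null(labels_in)) NULL else keep_labels
  if (is.null(labels)) {
    areas <- vapply(sections, function(cs) polygon_area(cs$lumen), 0)
    ids <- vapply(sections, function(cs) cs$frame_id, 0L)
    mk <- select_representative_frames(areas, c(ids[1], ids[length(ids)]))
    sel <- match(c(mk$pr, mk$ps, mk$mla, mk$ds, mk$dr), ids)
    labels <- c("PR", "PS", "MLA", "DS", "DR")[!is.na(sel)]
    sections <- sections[sel[!is.na(sel)]]
  }
  if (!length(sections)) stop("no frames selected for analysis")

  materials <- if (is.null(config$materials)) default_materials()
               else read_materials(config$materials)
  tracing <- extract_representative_beat(read_pressure_tracing(config$tracing))
  pullback <- read_ofr_pullback(config$pullback)

  rows <- list()
  frame_status <- read_failures
  for (i in seq_along(sections)) {
    cs <- sections[[i]]
    t0 <- Sys.time()
    res <- tryCatch({
      p_t <- position_pressure(tracing, pullback, cs$pullback_position)
      load <- relative_pressure(p_t, tracing$time)
      geom <- build_layered_geometry(cs)
      mesh <- generate_mesh(geom, config$h_superficial, config$h_bulk)
      sol <- solve_cycle(mesh, materials, load, n_steps = config$n_steps,
                         control = config$control)
      sm <- stress_metrics(sol, cs, position_label = labels[i])
      if (config$write_vtk) {
        last <- sol$steps[[length(sol$steps)]]
        write_vtk(mesh,
                  file.path(config$output_dir,
                            sprintf("frame_%03d_fields.vtk", cs$frame_id)),
                  cell_data = list(von_mises_kpa = last$von_mises),
                  point_data = list(displacement_mm = last$u))
      }
      sm
    }, error = function(e) e)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      frame_status[[length(frame_status) + 1L]] <- list(
        frame_id = cs$frame_id, label = labels[i], status = "failed",
        message = conditionMessage(res), seconds = round(dt, 2))
    } else {
      rows[[length(rows) + 1L]] <- as.data.frame(res)
      frame_status[[length(frame_status) + 1L]] <- list(
        frame_id = cs$frame_id, label = labels[i], status = "converged",
        seconds = round(dt, 2))
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stress_metrics_schema())
  res_path <- file.path(config$output_dir, "results.csv")
  utils::write.csv(format(results, digits = 10, trim = TRUE, scientific = FALSE),
                   res_path, row.names = FALSE, quote = FALSE)

  manifest <- list(
    software = paste("plaquestress",
                     as.character(utils::packageVersion("plaquestress"))),
    schema_version = "1",
    seed = config$seed,
    config = list(sections = basename(config$sections),
                  tracing = basename(config$tracing),
                  pullback = basename(config$pullback),
                  h_superficial = config$h_superficial, h_bulk = config$h_bulk,
                  n_steps = config$n_steps,
                  penalty_factor = config$control$penalty_factor,
                  follower_load = config$control$follower_load),
    materials = material_manifest(materials),
    frames = frame_status,
    total_seconds = round(as.numeric(difftime(Sys.time(), t_start,
                                              units = "secs")), 2))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, manifest = manifest))
}

stress_metrics_schema <- function() {
  data.frame(frame_id = integer(), position_label = character(),
             dpss_kpa = numeric(), ldc_mm = numeric(),
             ldc_percent = numeric(), plaque_burden_pct = numeric(),
             cap_thickness_um = numeric(), peak_load_kpa = numeric())
}

# bit-exact echo of the material table for the manifest
material_manifest <- function(materials) {
  lapply(materials, function(m) {
    cls <- class(m)[1]
    pars <- unclass(m)
    attr(pars, "source") <- NULL
    list(model = cls, parameters = pars, source = attr(m, "source") %||% "")
  })
}

#' Descriptive summary of cohort results
#'
#' Groups analyzed frames into normal segments (PR, DR) and diseased segments
#' (PS, MLA, DS) and reports per-position and per-group descriptive
#' statistics (mean, median, type-7 quartiles) of the stress and deformation
#' metrics. Descriptive only, no inference.
#'
#' @param results results data.frame(s) from [run_lesion()] (rows are frames).
#' @return list with `by_position` and `by_group` data.frames.
#' @export
summarize_cohort <- function(results) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  known <- c("PR", "PS", "MLA", "DS", "DR")
  if (!all(results$position_label %in% known))
    stop("unknown position label(s): ",
         paste(setdiff(results$position_label, known), collapse = ", "))
  results$group <- ifelse(results$position_label %in% c("PR", "DR"),
                          "normal", "diseased")
  metrics <- c("dpss_kpa", "ldc_mm", "ldc_percent")
  describe <- function(d, key) {
    do.call(rbind, lapply(split(d, d[[key]]), function(g) {
      row <- data.frame(level = g[[key]][1], n = nrow(g))
      for (m in metrics) {
        q <- stats::quantile(g[[m]], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        row[[paste0(m, "_mean")]] <- mean(g[[m]])
        row[[paste0(m, "_q1")]] <- q[1]
        row[[paste0(m, "_median")]] <- q[2]
        row[[paste0(m, "_q3")]] <- q[3]
      }
      row
    }))
  }
  list(by_position = describe(results, "position_label"),
       by_group = describe(results, "group"))
}

#' Write a complete synthetic study to a run directory
#'
#' Generates a labeled synthetic cohort, a pressure tracing and a pullback
#' curve, writes them in the package's file formats together with a ready
#' `config.yaml`, so that `run_lesion(read_run_config(...))` can analyze it.
#'
#' @param dir output directory.
#' @param cohort a [cohort_spec()].
#' @param systolic,diastolic,hr,gradient,noise_sd tracing parameters
#'   (see [make_pressure_tracing()]).
#' @param drop pullback ratio drop (see [make_ofr_pullback()]).
#' @param seed integer seed for tracing noise (cohort carries its own seed).
#' @return invisibly, the config file path.
#' @export
write_synthetic_study <- function(dir, cohort = cohort_spec(),
                                  systolic = 120, diastolic = 80, hr = 75,
                                  gradient = 0.12, noise_sd = 0, drop = 0.15,
                                  seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- make_cohort(cohort)
  paths <- character(0)
  labels <- character(0)
  for (e in entries) {
    p <- file.path(dir, sprintf("frame_%03d.json", e$section$frame_id))
    write_cross_section(e$section, p)
    paths <- c(paths, basename(p))
    labels <- c(labels, e$label)
  }
  tr <- make_pressure_tracing(systolic, diastolic, hr, n_beats = 3L,
                              gradient = gradient, noise_sd = noise_sd,
                              seed = seed)
  write_pressure_tracing(tr, file.path(dir, "tracing.csv"))
  pb <- make_ofr_pullback(length = 50, lesion_center = 22, drop = drop)
  write_ofr_pullback(pb, file.path(dir, "pullback.csv"))
  cfg <- list(sections = as.list(paths), labels = as.list(labels),
              tracing = "tracing.csv", pullback = "pullback.csv",
              output_dir = "results", seed = seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}
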