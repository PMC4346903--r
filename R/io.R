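#' Read and write titration files
#'
#' Titration files are delimited text (comma- or tab-separated) with a
#' header row and columns `volume_mL` plus exactly one of `emf_mV` or
#' `pH`.  Experiment metadata travels either as `# key = value` comment
#' lines at the top of the same file (the canonical dialect) or in a
#' sidecar YAML file with the same keys; both dialects parse to identical
#' datasets.  Recognized keys: `v0_mL`, `sbo_g_per_L`,
#' `c_strong_acid_mol_per_L`, `titrant_mol_per_L`, `titrant_sign`, `pKw`,
#' `temperature_C`, `ionic_strength_mol_per_L`.
#'
#' Validation: rows must parse as numbers (failures are reported with
#' their line number), volumes must be non-decreasing, and duplicated
#' volumes are rejected with the offending line.
#'
#' @param path File to read or write.
#' @param sidecar Optional sidecar YAML path; on read it supplies
#'   metadata, on write metadata goes there instead of `#` header lines.
#' @return `read_titration()`: a `titration_data` tibble with the
#'   [solution_state()] attached.  `write_titration()`: `path`,
#'   invisibly.
#' @export
read_titration <- function(path, sidecar = NULL) {
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  meta <- parse_meta_lines(lines[is_meta])
  if (!is.null(sidecar)) {
    if (length(meta) > 0) {
      abort("both header metadata and a sidecar file supplied: pick one dialect",
            class = "protofit_dialect")
    }
    meta <- yaml::read_yaml(sidecar)
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  first_line <- which(!is_meta & nzchar(trimws(lines)))[1]
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- tryCatch(
    read.csv(text = paste(body, collapse = "\n"), sep = sep,
             colClasses = "numeric", check.names = FALSE),
    error = function(e) abort(paste0("malformed table in ", path, ": ",
                                     conditionMessage(e)),
                              class = "protofit_invalid_data"),
    warning = function(e) abort(paste0("malformed table in ", path, ": ",
                                       conditionMessage(e)),
                                class = "protofit_invalid_data"))
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0)[1]
    abort(paste0("non-numeric value at line ", first_line + bad, " of ",
                 path),
          class = "protofit_invalid_data")
  }
  has_e <- "emf_mV" %in% names(df); has_p <- "pH" %in% names(df)
  if (!"volume_mL" %in% names(df)) {
    abort("missing volume_mL column", class = "protofit_dialect")
  }
  if (has_e == has_p) {
    abort("need exactly one of emf_mV or pH columns",
          class = "protofit_dialect")
  }
  v <- df$volume_mL
  if (any(diff(v) < 0)) {
    abort(paste0("volumes decrease at line ",
                 first_line + which(diff(v) < 0)[1] + 1),
          class = "protofit_invalid_data")
  }
  if (anyDuplicated(v)) {
    abort(paste0("duplicated volume at line ",
                 first_line + which(duplicated(v))[1]),
          class = "protofit_invalid_data")
  }
  state <- if (length(meta) > 0) state_from_meta(meta) else NULL
  as_titration_data(df, state = state)
}

meta_keys <- c(v0_mL = "v0", sbo_g_per_L = "sbo_conc",
               c_strong_acid_mol_per_L = "c_strong_acid",
               titrant_mol_per_L = "titrant_conc",
               titrant_sign = "titrant_sign", pKw = "pKw",
               temperature_C = "temperature_C",
               ionic_strength_mol_per_L = "ionic_strength")

parse_meta_lines <- function(lines) {
  lines <- sub("^\\s*#\\s*", "", lines)
  kv <- lines[grepl("=", lines)]
  if (length(kv) == 0) return(list())
  keys <- trimws(sub("=.*$", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  setNames(as.list(as.numeric(vals)), keys)
}

state_from_meta <- function(meta) {
  unknown <- setdiff(names(meta), names(meta_keys))
  if (length(unknown) > 0) {
    abort(paste0("unknown metadata key(s): ", paste(unknown, collapse = ", ")),
          class = "protofit_dialect")
  }
  args <- setNames(meta, meta_keys[names(meta)])
  do.call(solution_state, args)
}

#' @rdname read_titration
#' @param data A `titration_data` (or data frame with the same columns).
#' @export
write_titration <- function(data, path, sidecar = NULL) {
  st <- attr(data, "state")
  meta <- if (is.null(st)) list() else
    setNames(st[unname(meta_keys)], names(meta_keys))
  cols <- intersect(c("volume_mL", "emf_mV", "pH"), names(data))
  df <- as.data.frame(data)[, cols, drop = FALSE]
  body <- c(paste(cols, collapse = ","),
            apply(df, 1, function(r)
              paste(vapply(r, format_num, character(1)), collapse = ",")))
  if (!is.null(sidecar)) {
    yaml::write_yaml(meta, sidecar, precision = 15)
    writeLines(body, path)
  } else {
    hdr <- sprintf("# %s = %s", names(meta),
                   vapply(unlist(meta), format_num, character(1)))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

format_num <- function(x) format(x, digits = 15, scientific = FALSE,
                                 trim = TRUE)

#' Read and write protonation-model files
#'
#' Plain-YAML model files: a `name`, an optional `sbo` label, and a list
#' of `sites`, each with `id`, `logbeta` (list of cumulative constants)
#' and `conc_mmol_per_g`.  Reported standard deviations (`sd_logbeta`,
#' `sd_conc`, `sigma_fit_reported`) are carried along as attributes when
#' present.
#'
#' @param path YAML file.
#' @return A [protonation_model()].
#' @export
read_protonation_model <- function(path) {
  y <- yaml::read_yaml(path)
  sites <- lapply(y$sites, function(s)
    acid_site(s$id, unlist(s$logbeta), s$conc_mmol_per_g))
  m <- protonation_model(y$name, sites)
  attr(m, "sbo") <- y$sbo
  attr(m, "sd") <- lapply(y$sites, function(s)
    list(id = s$id, sd_logbeta = unlist(s$sd_logbeta), sd_conc = s$sd_conc))
  attr(m, "sigma_fit_reported") <- y$sigma_fit_reported
  m
}

#' @rdname read_protonation_model
#' @param model A [protonation_model()].
#' @export
write_protonation_model <- function(model, path) {
  y <- list(
    sbo = attr(model, "sbo"),
    name = model$name,
    sites = lapply(model$sites, function(s)
      list(id = s$site_id, logbeta = as.list(s$cum_logbeta),
           conc_mmol_per_g = s$conc_per_gram))
  )
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a composition table
#'
#' CSV with one row per sample: `sbo`, `ash_pct`, `pct_C`, `pct_N`, the
#' six C-type mole fractions (`f_aliphatic`, `f_nr`, `f_or`, `f_ar`,
#' `f_phoy`, `f_coy`) and `cmc_g_per_L`.
#'
#' @param path CSV file.
#' @export
read_composition <- function(path) {
  df <- as_tibble(read.csv(path, check.names = FALSE))
  need <- c("sbo", "pct_C", "pct_N", "f_phoy", "f_coy")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("composition file lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "protofit_invalid_data")
  }
  df
}

#' Run the full workflow from one configuration
#'
#' Executes, in order and as enabled by `config$stages`: electrode
#' `calibrate` (strong acid/base titration), model `fit` (one or more
#' structures), `compare` (rank by the weighted standard deviation of the
#' fit) and functional-group `breakdown`.  Emits a
#' protonation-constants table, a functional-groups table and a
#' machine-readable JSON report embedding the resolved configuration and
#' the package version, so a run is fully reproducible from (config,
#' input files).
#'
#' @param config A list or a path to a YAML file with entries:
#'   `stages` (subset of `c("calibrate", "fit", "compare", "breakdown")`),
#'   `titration` (path), `calibration` (path, for the calibrate stage),
#'   `models` (character vector of model-file paths), `composition`
#'   (path, for breakdown), `electrode` (list of [electrode_model()]
#'   arguments), `refine` (calibration parameters to refine),
#'   `weighting` (list of [weighting_scheme()] arguments),
#'   `threshold_logK`, `ph_range`, `out_dir`.
#' @return Invisibly, a list with the stage results (`electrode`, `fits`,
#'   `comparison`, `breakdown`, `report_path`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% character(0)
  known <- c("calibrate", "fit", "compare", "breakdown")
  if (length(setdiff(stages, known)) > 0) {
    abort(paste0("unknown stage(s): ",
                 paste(setdiff(stages, known), collapse = ", ")))
  }
  if (length(stages) == 0) {
    warn("no stages enabled; nothing to do")
    return(invisible(list()))
  }
  out <- list()
  electrode <- do.call(electrode_model, config$electrode %||% list())
  weighting <- do.call(weighting_scheme, config$weighting %||% list())

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
            class = "protofit_pipeline"))
  }

  if ("calibrate" %in% stages) {
    out$calibration <- run_stage("calibrate", {
      cal <- read_titration(config$calibration)
      calibrate_electrode(cal, refine = config$refine %||% "e0",
                          start = electrode, weighting = weighting)
    })
    electrode <- out$calibration$electrode
  }

  fits <- NULL
  if (any(c("fit", "compare") %in% stages)) {
    structures <- run_stage("fit", lapply(config$models,
                                          read_protonation_model))
    data <- run_stage("fit", read_titration(config$titration))
    if ("compare" %in% stages && length(structures) >= 2) {
      out$comparison <- run_stage("compare", compare_models(
        data, electrode, structures, weighting = weighting,
        ph_range = config$ph_range))
      fits <- out$comparison$fit
      names(fits) <- out$comparison$model
    } else {
      fits <- run_stage("fit", lapply(structures, function(s)
        fit_protonation_model(data, electrode, s, weighting = weighting,
                              ph_range = config$ph_range)))
      names(fits) <- vapply(structures, `[[`, character(1), "name")
    }
    out$fits <- fits
  }

  if ("breakdown" %in% stages) {
    out$breakdown <- run_stage("breakdown", {
      comp <- read_composition(config$composition)
      fit_best <- if (!is.null(fits)) fits[[1]] else
        read_protonation_model(config$models[[1]])
      group_breakdown(comp[1, ], fit_best,
                      threshold_logK = config$threshold_logK %||% 7)
    })
  }

  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(out$fits)) {
    tabs <- purrr::imap(out$fits, function(f, nm)
      dplyr::mutate(tidy.sbo_fit(f), model = nm, .before = 1))
    write.csv(purrr::list_rbind(tabs),
              file.path(out_dir, "protonation_constants.csv"),
              row.names = FALSE)
  }
  if (!is.null(out$breakdown)) {
    write.csv(out$breakdown, file.path(out_dir, "functional_groups.csv"),
              row.names = FALSE)
  }
  report <- list(
    package = "protofit",
    version = as.character(packageVersion("protofit")),
    config = config,
    electrode = unclass(electrode),
    comparison = if (!is.null(out$comparison))
      dplyr::select(out$comparison, -"fit"),
    fits = if (!is.null(out$fits))
      purrr::map(out$fits, function(f)
        list(tidy = tidy.sbo_fit(f), glance = glance.sbo_fit(f))),
    breakdown = out$breakdown
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  out$report_path <- report_path
  invisible(out)
}
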