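#' Write a tensiometry trace to CSV
#'
#' Columns `time_s, gamma_mJ_m2[, Gamma_um2][, area_mm2][, volume_uL]`;
#' metadata entries are written as commented `# key=value` header lines.
#'
#' @param trace A [tensiometry_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "tensiometry_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  md <- attr(trace, "metadata")
  for (nm in names(md)) {
    writeLines(sprintf("# %s=%s", nm, format(md[[nm]], digits = 15)), con)
  }
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a tensiometry trace from CSV
#'
#' Validates the dialect written by [write_trace_csv()]: a `time_s` and a
#' `gamma_mJ_m2` column are required, time must be strictly increasing and
#' all cells numeric. `#`-prefixed header lines are parsed back into
#' metadata.
#'
#' @param path Input file path.
#' @return A [tensiometry_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  metadata <- list()
  for (ln in lines[meta_lines]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      metadata[[key]] <- if (!is.na(num)) num else val
    }
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines),
                                                   meta_lines)],
                                     collapse = "\n"))
  for (col in c("time_s", "gamma_mJ_m2")) {
    if (!col %in% names(df)) {
      stop(sprintf("malformed trace file %s: missing column '%s'",
                   path, col))
    }
  }
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("non-numeric cell in %s: column '%s', data row %d",
                   path, col, bad))
    }
  }
  if (any(diff(df$time_s) <= 0)) {
    bad <- which(diff(df$time_s) <= 0)[1] + 1L
    stop(sprintf("non-monotone time in %s at data row %d", path, bad))
  }
  tensiometry_trace(df$time_s, df$gamma_mJ_m2,
                    Gamma_um2 = df$Gamma_um2,
                    area_mm2 = df$area_mm2, volume_uL = df$volume_uL,
                    metadata = metadata)
}

#' Read an induction-time dataset from CSV
#'
#' Expects columns `c_uM` and `t_induction_s`.
#'
#' @param path Input file path.
#' @return An [induction_dataset()].
#' @export
read_induction_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("c_uM", "t_induction_s") %in% names(df))) {
    stop("induction dataset needs columns c_uM, t_induction_s")
  }
  induction_dataset(df$c_uM, df$t_induction_s, provenance = path)
}

#' Write an induction-time dataset to CSV
#'
#' @param data An [induction_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_induction_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read area-step experiments from CSV
#'
#' Expects columns `label`, `A_r`, `gamma_mJ_m2`; one experiment per
#' distinct label.
#'
#' @param path Input file path.
#' @return A list of [area_step_experiment()]s.
#' @export
read_area_step_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("label", "A_r", "gamma_mJ_m2") %in% names(df))) {
    stop("area-step file needs columns label, A_r, gamma_mJ_m2")
  }
  lapply(split(df, df$label), function(d) {
    area_step_experiment(d$A_r, d$gamma_mJ_m2, label = d$label[1])
  })
}

#' Write area-step experiments to CSV
#'
#' @param experiments A list of [area_step_experiment()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_area_step_csv <- function(experiments, path) {
  if (inherits(experiments, "area_step_experiment")) {
    experiments <- list(experiments)
  }
  rows <- do.call(rbind, lapply(experiments, function(e) {
    data.frame(label = attr(e, "label"), A_r = e$A_r,
               gamma_mJ_m2 = e$gamma_mJ_m2)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a simulation configuration from a JSON file
#'
#' Reads a flat JSON object of scalar fields; unknown keys are rejected.
#' Recognised keys: `c_bulk_uM`, `t_end_s`, `dt_out_s`, `seed`,
#' `radius_sphere_mm`, `area_mm2`, `volume_uL`, `molar_mass_g_mol`,
#' `diffusion_um2_s`, `gamma0_mJ_m2`, `Gamma0_um2`, `E0_mJ_m2`,
#' `Pi_max_mJ_m2`, `B_um2_s`, `q`, `s`, `K_um3`, `n_cells`,
#' `h_surface_um`.
#'
#' @param path Path to a JSON config file.
#' @return A [simulation_config()].
#' @export
read_config_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("c_bulk_uM", "t_end_s", "dt_out_s", "seed", "radius_sphere_mm",
             "area_mm2", "volume_uL", "molar_mass_g_mol", "diffusion_um2_s",
             "gamma0_mJ_m2", "Gamma0_um2", "E0_mJ_m2", "Pi_max_mJ_m2",
             "B_um2_s", "q", "s", "K_um3", "n_cells", "h_surface_um")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$c_bulk_uM)) stop("config must set c_bulk_uM")
  pick <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  geometry <- drop_geometry(pick("radius_sphere_mm", 2.1),
                            pick("area_mm2", 50), pick("volume_uL", 40))
  protein <- protein_spec(pick("molar_mass_g_mol", 27e3),
                          pick("diffusion_um2_s", 45))
  eos <- surface_eos(pick("gamma0_mJ_m2", 72.0), pick("Gamma0_um2", 24e3),
                     pick("E0_mJ_m2", 15), pick("Pi_max_mJ_m2", 22))
  barrier <- barrier_params(pick("B_um2_s", 70e3), pick("q", 0.15),
                            pick("s", 1 / 20))
  clustering <- if (!is.null(cfg$K_um3) && cfg$K_um3 > 0) {
    isodesmic_params(cfg$K_um3)
  } else NULL
  simulation_config(cfg$c_bulk_uM, geometry = geometry, protein = protein,
                    eos = eos, barrier = barrier, clustering = clustering,
                    t_end_s = pick("t_end_s", 7200),
                    dt_out_s = pick("dt_out_s", 1),
                    n_cells = pick("n_cells", 150),
                    h_surface_um = pick("h_surface_um", 1),
                    seed = pick("seed", 1L))
}
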