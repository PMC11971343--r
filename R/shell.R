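# I/O, configuration and pipeline orchestration.

#' Analysis configuration
#'
#' Bundles experimental conditions and photon-count correction factors
#' used across analysis stages.
#'
#' @param temperature_K sample temperature in kelvin (default 295.15,
#'   i.e. 22 C).
#' @param h1_freq_MHz proton Larmor frequency of the spectrometer in MHz
#'   (750 by default; 600 also used for the folded domain).
#' @param forster_radius_nm Forster radius R0 of the dye pair in nm
#'   (default 5.4).
#' @param ionic_strength_M total ionic strength in mol/L, including the
#'   8 mM buffer contribution (default 0.165).
#' @param random_seed integer seed recorded with stochastic stages.
#' @param corrections named list of photon correction factors:
#'   \code{bg_D}, \code{bg_A} (background counts per burst),
#'   \code{crosstalk} (donor-to-acceptor channel crosstalk fraction),
#'   \code{direct_exc} (acceptor direct-excitation fraction), and
#'   \code{gamma} (detection-efficiency/quantum-yield ratio). Identity
#'   defaults leave counts unchanged.
#' @return object of class \code{analysis_config}.
#' @export
analysis_config <- function(temperature_K = 295.15,
                            h1_freq_MHz = 750,
                            forster_radius_nm = 5.4,
                            ionic_strength_M = 0.165,
                            random_seed = 1L,
                            corrections = list()) {
  check_positive(temperature_K, "temperature_K")
  check_positive(forster_radius_nm, "forster_radius_nm")
  corr <- list(bg_D = 0, bg_A = 0, crosstalk = 0, direct_exc = 0, gamma = 1)
  corr[names(corrections)] <- corrections
  check_nonneg(unlist(corr), "corrections")
  structure(list(temperature_K = temperature_K,
                 h1_freq_MHz = h1_freq_MHz,
                 forster_radius_nm = forster_radius_nm,
                 ionic_strength_M = ionic_strength_M,
                 random_seed = as.integer(random_seed),
                 corrections = corr),
            class = "analysis_config")
}

#' Read a flat key-value configuration file
#'
#' One \code{key = value} pair per line; lines starting with \code{#}
#' are comments. Recognized keys map onto [analysis_config()] arguments;
#' unrecognized keys are kept as stage parameters in the
#' \code{extra} attribute.
#'
#' @param path file path.
#' @return \code{analysis_config} object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop_input("malformed config line: %s", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  known <- c("temperature_K", "h1_freq_MHz", "forster_radius_nm",
             "ionic_strength_M", "random_seed")
  corr_keys <- c("bg_D", "bg_A", "crosstalk", "direct_exc", "gamma")
  args <- lapply(vals[keys %in% known], as.numeric)
  names(args) <- keys[keys %in% known]
  corr <- lapply(vals[keys %in% corr_keys], as.numeric)
  names(corr) <- keys[keys %in% corr_keys]
  cfg <- do.call(analysis_config, c(args, list(corrections = corr)))
  extra <- vals[!(keys %in% c(known, corr_keys))]
  names(extra) <- keys[!(keys %in% c(known, corr_keys))]
  attr(cfg, "extra") <- as.list(extra)
  cfg
}

#' Load a delimited table against a column schema
#'
#' Reads tab- or comma-delimited text with a header row, checks required
#' columns, coerces them to numeric or character as declared, and drops
#' rows whose required numeric fields fail to parse (the number dropped
#' is reported via a message and the \code{n_dropped} attribute). Extra
#' columns are preserved untouched.
#'
#' @param path file path.
#' @param schema named character vector mapping required column names to
#'   types (\code{"numeric"} or \code{"character"}).
#' @return data.frame with attribute \code{n_dropped}.
#' @export
load_table <- function(path, schema) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  hdr <- readLines(path, n = 1L, warn = FALSE)
  if (!length(hdr) || !nzchar(hdr)) stop_input("empty input file: %s", path)
  sep <- if (grepl("\t", hdr)) "\t" else if (grepl(",", hdr)) "," else ""
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "")
  if (nrow(df) == 0L) stop_input("no data rows in %s", path)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop_input("missing required column(s): %s", paste(missing, collapse = ", "))
  keep <- rep(TRUE, nrow(df))
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[col]]))
      keep <- keep & !is.na(v)
      df[[col]] <- v
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("load_table: dropped %d row(s) with unparseable required fields", n_dropped))
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Trajectory frames container
#'
#' @param coords numeric array \code{[n_atoms, 3, n_frames]}, nm.
#' @param dt_ps frame interval in ps.
#' @param atoms data.frame with columns \code{resid} (1-based residue
#'   index), \code{resname}, \code{atomname}, \code{chain},
#'   \code{element}.
#' @param box optional box dimensions c(x, y, z) in nm (orthorhombic).
#' @return object of class \code{trajectory_frames}.
#' @export
trajectory_frames <- function(coords, dt_ps, atoms, box = NULL) {
  check_positive(dt_ps, "dt_ps")
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop_input("coords must be an [n_atoms, 3, n_frames] array")
  if (dim(coords)[1] != nrow(atoms))
    stop_input("atom metadata rows (%d) do not match coordinate atoms (%d)",
               nrow(atoms), dim(coords)[1])
  if (any(atoms$resid < 1)) stop_input("residue indices must be >= 1")
  structure(list(coords = coords, dt_ps = dt_ps, atoms = atoms, box = box),
            class = "trajectory_frames")
}

#' @export
print.trajectory_frames <- function(x, ...) {
  cat(sprintf("trajectory_frames: %d atoms, %d frames at %g ps\n",
              dim(x$coords)[1], dim(x$coords)[3], x$dt_ps))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Load a trajectory from standard MD formats
#'
#' Topology from a PDB file; frames from a DCD file or the models of a
#' multi-model PDB (in which case \code{coords_path} may equal
#' \code{topology_path}). Coordinates are converted from Angstrom to nm.
#'
#' @param coords_path frame file (DCD or multi-model PDB).
#' @param topology_path PDB topology.
#' @param dt_ps frame interval in ps (DCD headers do not reliably carry
#'   it; required).
#' @return [trajectory_frames()] object.
#' @export
load_trajectory <- function(coords_path, topology_path, dt_ps) {
  if (!file.exists(topology_path)) stop_input("topology not found: %s", topology_path)
  if (!file.exists(coords_path)) stop_input("coordinates not found: %s", coords_path)
  top <- bio3d::read.pdb(topology_path, multi = TRUE)
  at <- top$atom
  atoms <- data.frame(resid = at$resno, resname = at$resid,
                      atomname = at$elety, chain = ifelse(is.na(at$chain), "A", at$chain),
                      element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                                       substr(trimws(at$elety), 1, 1), trimws(at$elesy)),
                      stringsAsFactors = FALSE)
  n_at <- nrow(atoms)
  ext <- tolower(tools::file_ext(coords_path))
  if (ext == "xtc")
    stop_input("XTC frames are not supported; supply DCD or multi-model PDB")
  xyz <- if (ext == "dcd") {
    bio3d::read.dcd(coords_path, verbose = FALSE)
  } else {
    bio3d::read.pdb(coords_path, multi = TRUE)$xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_at)
    stop_input("atom-count mismatch: topology has %d atoms, frames have %g",
               n_at, ncol(xyz) / 3)
  nf <- nrow(xyz)
  coords <- array(0, dim = c(n_at, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10  # A -> nm
  trajectory_frames(coords, dt_ps, atoms)
}

#' Write trajectory frames as a multi-model PDB
#'
#' Plain-text writer used for fixtures and round-tripping; coordinates
#' are written in Angstrom at PDB precision (0.001 A).
#'
#' @param traj [trajectory_frames()] object.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f] * 10  # nm -> A
    lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     seq_len(nrow(at)), substr(at$atomname, 1, 4),
                     substr(at$resname, 1, 3), substr(at$chain, 1, 1),
                     at$resid, xyz[, 1], xyz[, 2], xyz[, 3], at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- pipeline ----------------------------------------------------------

pipeline_stages <- function() {
  list(
    "fit-titration" = function(cfg, pars, out) {
      tab <- load_table(pars$titration, c(g_tot_M = "numeric", p_tot_M = "numeric",
                                          mean_E = "numeric", se_E = "numeric"))
      ts <- titration_series(tab$g_tot_M, tab$p_tot_M, tab$mean_E, tab$se_E)
      fit <- fit_titration(ts, model = pars$model %||% "1to1")
      fit$parameters
    },
    "fit-salt" = function(cfg, pars, out) {
      tab <- load_table(pars$salt, c(ionic_strength_M = "numeric",
                                     kd_M = "numeric", se_kd_M = "numeric"))
      fit <- fit_salt_dependence(salt_series(tab$ionic_strength_M, tab$kd_M, tab$se_kd_M))
      data.frame(parameter = c("ions_released", "intercept_log10"),
                 estimate = c(fit$ions_released, fit$intercept),
                 se = c(fit$ions_released_se, fit$intercept_se),
                 ci90_lo = c(fit$ci90[1], fit$intercept_ci90[1]),
                 ci90_hi = c(fit$ci90[2], fit$intercept_ci90[2]))
    },
    "melt-fit" = function(cfg, pars, out) {
      tab <- load_table(pars$melt, c(x = "numeric", signal = "numeric"))
      fit <- fit_thermal_melt(cd_curve(tab$x, tab$signal, mode = "thermal"))
      fit$parameters
    },
    "csp" = function(cfg, pars, out) {
      free <- load_table(pars$free, c(residue = "numeric", delta_H_ppm = "numeric",
                                      delta_N_ppm = "numeric"))
      bound <- load_table(pars$bound, c(residue = "numeric", delta_H_ppm = "numeric",
                                        delta_N_ppm = "numeric"))
      compute_csp(free, bound)
    }
  )
}

#' Run a sequence of analysis stages
#'
#' Each stage reads its input tables from paths in \code{params}, runs
#' the corresponding fit, and writes its result table under
#' \code{out_dir} together with a machine-readable JSON summary and a
#' run log recording the seed and configuration. A failing stage aborts
#' with the stage named; tables from earlier stages are retained.
#'
#' @param config [analysis_config()] object.
#' @param stages character vector of stage names; see Details. Known
#'   stages: \code{fit-titration}, \code{fit-salt}, \code{melt-fit},
#'   \code{csp}.
#' @param params named list of per-stage parameter lists (input paths
#'   etc.), keyed by stage name.
#' @param out_dir output directory (created if needed).
#' @return named list of per-stage result tables, invisibly; also
#'   written to disk.
#' @export
run_pipeline <- function(config, stages, params = list(), out_dir = tempfile("polybind_run_")) {
  registry <- pipeline_stages()
  unknown <- setdiff(stages, names(registry))
  if (length(unknown))
    stop_input("unknown stage name(s): %s", paste(unknown, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$random_seed)
  results <- list()
  for (st in stages) {
    res <- tryCatch(registry[[st]](config, params[[st]] %||% list(), out_dir),
                    error = function(e) stop_input("stage '%s' failed: %s", st,
                                                   conditionMessage(e)))
    results[[st]] <- res
    write.table(res, file.path(out_dir, paste0(st, ".tsv")), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  summary <- lapply(results, function(r) as.list(r))
  jsonlite::write_json(list(seed = config$random_seed,
                            config = unclass(config)[c("temperature_K", "h1_freq_MHz",
                                                       "forster_radius_nm", "ionic_strength_M")],
                            stages = stages, results = summary),
                       file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("polybind %s", as.character(utils::packageVersion("polybind"))),
               sprintf("seed: %d", config$random_seed),
               sprintf("stages: %s", paste(stages, collapse = ", "))),
             file.path(out_dir, "run.log"))
  invisible(results)
}
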