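#' Trajectory CSV round trip
#'
#' Writes the recorded samples as plain CSV (columns `t`, `V`, `a_r`,
#' `a_sd`, `a_sr`, `i_ext`); numbers are serialized at full double
#' precision so the round trip is lossless.
#'
#' @param traj an [hb_integrate()] trajectory.
#' @param path file path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a data.frame with the six columns.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(t = traj$t, V = traj$V, a_r = traj$a_r,
                   a_sd = traj$a_sd, a_sr = traj$a_sr, i_ext = traj$i_ext)
  write_csv_full(df, path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  read.csv(path)
}

#' Basin map CSV round trip
#'
#' Long-format CSV with columns `x`, `y`, `label`; the grid is recovered
#' from the unique coordinates on read.
#'
#' @param basin a [compute_basin()] map.
#' @param path file path.
#' @return `read_basin_csv()` returns a `basin_map` (without the original
#'   spec provenance); the labels matrix round-trips identically.
#' @export
write_basin_csv <- function(basin, path) {
  df <- data.frame(x = rep(basin$x, times = length(basin$y)),
                   y = rep(basin$y, each = length(basin$x)),
                   label = as.vector(basin$labels))
  write_csv_full(df, path)
}

#' @rdname write_basin_csv
#' @export
read_basin_csv <- function(path) {
  df <- read.csv(path, colClasses = c("numeric", "numeric", "character"))
  xs <- unique(df$x)
  ys <- unique(df$y)
  structure(list(x = xs, y = ys,
                 labels = matrix(df$label, length(xs), length(ys)),
                 spec = NULL),
            class = "basin_map")
}

write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a declarative experiment and write a manifest
#'
#' Dispatches a named analysis to the corresponding package operation,
#' writes its outputs as CSV/JSON under `out_dir`, and returns (and
#' writes) a manifest with the configuration and an MD5 checksum per
#' output file.  Re-running the same configuration reproduces identical
#' checksums: the pipeline contains no randomness.
#'
#' @param analysis one of `"simulate"`, `"continuation"`, `"staircase"`,
#'   `"basin"`, `"lyapunov"`, `"energy_profile"`.
#' @param args named list of arguments for the underlying operation.
#' @param out_dir output directory (created if missing).
#' @param params an [hb_params()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_experiment <- function(analysis = c("simulate", "continuation",
                                        "staircase", "basin", "lyapunov",
                                        "energy_profile"),
                           args, out_dir, params = hb_params()) {
  analysis <- match.arg(analysis)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  summary <- list()
  if (analysis == "simulate") {
    tr <- do.call(hb_integrate, c(args, list(params = params)))
    f <- file.path(out_dir, "trajectory.csv")
    write_trajectory_csv(tr, f)
    files <- f
    summary$n_samples <- length(tr$t)
  } else if (analysis == "continuation") {
    sw <- do.call(continuation_sweep, c(args, list(params = params)))
    f <- file.path(out_dir, "continuation.csv")
    write_csv_full(sw$points, f)
    files <- f
    summary$onset <- sw$onset
    summary$offset <- sw$offset
  } else if (analysis == "staircase") {
    sc <- do.call(isi_bifurcation_scan, c(args, list(params = params)))
    f1 <- file.path(out_dir, "isi.csv")
    f2 <- file.path(out_dir, "labels.csv")
    write_csv_full(sc$isi %||% data.frame(omega = numeric(0),
                                          isi = numeric(0)), f1)
    df <- sc$labels
    df$category <- as.character(df$category)
    write.csv(df, f2, row.names = FALSE, quote = FALSE)
    files <- c(f1, f2)
  } else if (analysis == "basin") {
    bm <- do.call(compute_basin, c(args, list(params = params)))
    f <- file.path(out_dir, "basin.csv")
    write_basin_csv(bm, f)
    files <- f
    summary$label_counts <- as.list(table(bm$labels))
  } else if (analysis == "lyapunov") {
    ly <- do.call(max_lyapunov, c(args, list(params = params)))
    f <- file.path(out_dir, "lyapunov.json")
    jsonlite::write_json(list(lambda = ly$lambda, se = ly$se,
                              t_accum = ly$t_accum),
                         f, auto_unbox = TRUE, digits = NA)
    files <- f
    summary$lambda <- ly$lambda
  } else if (analysis == "energy_profile") {
    ep <- do.call(energy_resonance_profile, c(args, list(params = params)))
    f <- file.path(out_dir, "energy_profile.csv")
    write_csv_full(ep, f)
    files <- f
  }
  manifest <- list(analysis = analysis,
                   package_version = as.character(
                     utils::packageVersion("hbneuron")),
                   outputs = lapply(files, function(f)
                     list(file = basename(f),
                          md5 = unname(tools::md5sum(f)))),
                   summary = summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
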