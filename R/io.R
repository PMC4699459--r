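#' Write simulation results to a directory
#'
#' Deterministic file layout: `trajectory.csv` (columns `tau, x_p, v` plus
#' `a_b` for rebinding runs, or `tau, x_p, y_p, v_x, v_y` in 2D), one
#' `snapshot_tau<t>.txt` delimited-text field per requested snapshot time,
#' and `manifest.json` holding the fully resolved config, seed, package
#' version, timestamps and the file inventory — enough to reproduce the run
#' bit-for-bit.
#'
#' @param result a `para_trajectory` (from [simulate_1d()]/[simulate_2d()]),
#'   a [sweep_parameter()] table, or a [speed_curve()] data frame.
#' @param out_dir output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(result, out_dir) {
  t_start <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    ok <- tryCatch({
      write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) {
      stop("failed writing ", path, ": ", conditionMessage(e))
    })
    files <<- c(files, path)
    path
  }

  inventory <- function() c(basename(files), "manifest.json")
  if (inherits(result, "para_trajectory")) {
    df <- if (result$dims == 2L) {
      data.frame(tau = result$tau, x_p = result$x_p, y_p = result$y_p,
                 v_x = result$v_x, v_y = result$v_y)
    } else if (!is.null(result$a_b)) {
      data.frame(tau = result$tau, x_p = result$x_p, v = result$v,
                 a_b = result$a_b)
    } else {
      data.frame(tau = result$tau, x_p = result$x_p, v = result$v)
    }
    emit(df, "trajectory.csv")
    for (i in seq_along(result$snapshot_tau)) {
      snap <- result$snapshots[[i]]
      name <- sprintf("snapshot_tau%g.txt", result$snapshot_tau[i])
      path <- file.path(out_dir, name)
      write.table(as.matrix(snap), path, sep = "\t",
                  row.names = FALSE, col.names = FALSE)
      files <- c(files, path)
    }
    manifest <- list(
      kind = paste0("simulate", result$dims, "d"),
      mode = result$mode,
      config = result$config,
      seed = result$config$seed,
      package_version = as.character(packageVersion("parabead")),
      started = t_start,
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      files = inventory(),
      boundary_hit = isTRUE(result$boundary_hit)
    )
  } else if (inherits(result, "sweep_result")) {
    emit(as.data.frame(result), "sweep.csv")
    manifest <- list(kind = "sweep", parameter = attr(result, "parameter"),
                     package_version = as.character(packageVersion("parabead")),
                     started = t_start,
                     finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     files = inventory())
  } else if (is.data.frame(result)) {
    emit(result, "speed_curve.csv")
    manifest <- list(kind = "speed_curve",
                     package_version = as.character(packageVersion("parabead")),
                     started = t_start,
                     finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     files = inventory())
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest_path)
  invisible(files)
}
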