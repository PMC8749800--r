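# Trial files are delimited text with a fixed header
#   t_ms, Ax_g, Ay_g, Az_g, Gx_dps, Gy_dps, Gz_dps [, Ex_deg, Ey_deg, Ez_deg]
# plus an optional JSON metadata sidecar (<path>.meta.json) carrying
# sample_rate, side and subject. Gzipped files are read and written
# transparently (a ".gz" suffix).

trial_columns <- c(t_ms = "t", Ax_g = "A_x", Ay_g = "A_y", Az_g = "A_z",
                   Gx_dps = "G_x", Gy_dps = "G_y", Gz_dps = "G_z",
                   Ex_deg = "E_x", Ey_deg = "E_y", Ez_deg = "E_z")

#' Read a trial file
#'
#' Reads a delimited foot-motion trial into a validated
#' [foot_motion_signal()]. The time column must be uniform (the sampling step
#' defines the rate unless a sidecar provides it); acceleration samples
#' outside +/- 16 g and angular velocities outside +/- 2000 deg/s — the
#' sensor's measurement ranges — are kept but flagged with a saturation
#' warning.
#'
#' @param path CSV/TSV trial file (optionally gzipped); the delimiter is
#'   sniffed from the header line.
#' @param side Instrumented foot; overrides the sidecar.
#' @return A [foot_motion_signal()].
#' @export
read_trial <- function(path, side = NULL) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  con <- file(path, "rt")
  header <- readLines(con, n = 1L)
  close(con)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("t_ms", "Ay_g", "Gx_dps")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trial file is missing required column(s): ",
         paste(miss, collapse = ", "))
  meta_path <- paste0(sub("\\.gz$", "", path), ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  t <- df$t_ms
  if (length(t) > 1L) {
    dt <- diff(t)
    step <- dt[1L]
    bad <- which(abs(dt - step) > 1e-6 * max(step, 1) | dt <= 0)
    if (length(bad))
      stop(sprintf("non-uniform time vector; first bad row: %d (t = %g ms)",
                   bad[1L] + 1L, t[bad[1L] + 1L]))
  }
  sample_rate <- meta$sample_rate %||% (1000 / diff(t[1:2]))
  acc <- intersect(c("Ax_g", "Ay_g", "Az_g"), names(df))
  gyr <- intersect(c("Gx_dps", "Gy_dps", "Gz_dps"), names(df))
  n_sat_a <- sum(vapply(acc, function(cn) sum(abs(df[[cn]]) > 16), numeric(1)))
  n_sat_g <- sum(vapply(gyr, function(cn) sum(abs(df[[cn]]) > 2000), numeric(1)))
  if (n_sat_a + n_sat_g > 0)
    warning(sprintf(
      "%d acceleration sample(s) beyond +/-16 g and %d angular-velocity sample(s) beyond +/-2000 deg/s (kept)",
      n_sat_a, n_sat_g))
  args <- list(t = t, sample_rate = sample_rate,
               side = side %||% meta$side %||% "right")
  for (cn in names(trial_columns)) {
    if (cn %in% names(df) && cn != "t_ms")
      args[[trial_columns[[cn]]]] <- df[[cn]]
  }
  do.call(foot_motion_signal, args)
}

#' Write a trial file
#'
#' Serialises a [foot_motion_signal()] in the dialect [read_trial()] reads,
#' with a JSON metadata sidecar.
#'
#' @param signal A [foot_motion_signal()].
#' @param path Output CSV path (a `.gz` suffix gzips it).
#' @param subject Optional subject identifier stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trial <- function(signal, path, subject = NULL) {
  df <- as.data.frame(signal)
  names(df) <- names(trial_columns)[match(names(df), trial_columns)]
  names(df)[1L] <- "t_ms"
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  meta <- list(sample_rate = signal$sample_rate, side = signal$side)
  if (!is.null(subject)) meta$subject <- subject
  jsonlite::write_json(meta, paste0(sub("\\.gz$", "", path), ".meta.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
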