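# CSV round-trips for trajectories and growth datasets.  Numeric columns are
# written as %.17g so a write/read cycle reproduces every double exactly.

.write_csv17 <- function(df, path) {
  chr <- as.data.frame(lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(chr) <- names(df)
  utils::write.table(chr, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' All columns at full double precision; protocol metadata (plant type,
#' per-day photoperiods, step sizes) goes into `#`-prefixed header comments so
#' [read_trajectory()] can restore the object.
#'
#' @param traj a `plant_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# plant_type: ", attr(traj, "plant_type")),
    paste0("# photoperiods: ", paste(sprintf("%.17g", attr(traj, "photoperiods")),
                                     collapse = " ")),
    paste0("# dt: ", sprintf("%.17g", attr(traj, "dt"))),
    paste0("# record_dt: ", sprintf("%.17g", attr(traj, "record_dt"))),
    paste0("# clamps: ", attr(traj, "clamps") %||% 0),
    paste0("# shift_day: ", attr(traj, "shift_day") %||% "")), con)
  close(con)
  on.exit()
  chr <- as.data.frame(lapply(as.data.frame(traj), function(col) sprintf("%.17g", col)))
  names(chr) <- names(traj)
  suppressWarnings(utils::write.table(chr, path, sep = ",", quote = FALSE,
                                      row.names = FALSE, append = TRUE,
                                      col.names = TRUE))
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path.
#' @param params parameter set to re-attach (trajectory CSVs carry protocol
#'   metadata but not the full parameter set); defaults to
#'   [default_parameters()].
#' @return a `plant_trajectory`.
#' @export
read_trajectory <- function(path, params = default_parameters()) {
  if (!file.exists(path)) stop("cannot open trajectory file: ", path)
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    trimws(sub(paste0("# ", key, ":"), "", ln, fixed = TRUE))
  }
  df <- utils::read.csv(path, comment.char = "#", colClasses = "numeric")
  shift <- meta("shift_day")
  structure(df, class = c("plant_trajectory", "data.frame"),
            params = params,
            plant_type = meta("plant_type"),
            photoperiods = as.numeric(strsplit(meta("photoperiods"), " ")[[1]]),
            dt = as.numeric(meta("dt")),
            record_dt = as.numeric(meta("record_dt")),
            clamps = as.numeric(meta("clamps")),
            shift_day = if (nzchar(shift)) as.integer(shift) else NULL)
}

#' Write a growth dataset to CSV
#'
#' Header `genotype,time_h,fresh_weight_g`, full double precision.
#'
#' @param data a growth dataset.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_growth_dataset <- function(data, path) {
  validate_growth_dataset(data)
  .write_csv17(data[c("genotype", "time_h", "fresh_weight_g")], path)
}

#' Read a growth dataset from CSV
#'
#' @param path CSV path with header `genotype,time_h,fresh_weight_g`.
#' @return a validated growth dataset.
#' @export
read_growth_dataset <- function(path) {
  validate_growth_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}
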