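# Config files and tabular output.

#' Read a scenario configuration from file
#'
#' Reads a flat key-value document (YAML or JSON, auto-detected from the
#' file extension) whose keys are the [model_config()] field names, and
#' returns the validated configuration.  Missing keys fall back to the
#' `model_config()` defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [model_config()].
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path),
                stop("config file must be .yaml/.yml or .json, got: .", ext))
  if (!is.list(raw)) stop("config file must hold a key-value mapping")
  allowed <- names(formals(model_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(model_config, raw)
}

#' Write a trajectory to CSV
#'
#' Deterministic column order, RFC-4180 dialect with `.` as the decimal
#' separator (independent of the session locale); a write–read round
#' trip reproduces the values to full double precision.
#'
#' @param trajectory A data frame as returned by
#'   [integrate_coevolution()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  cols <- c("time", "z1", "z2", "h", "dW_dz1", "dW_dz2", "dW_dh", "O_m")
  cols <- c(intersect(cols, names(trajectory)),
            setdiff(names(trajectory), cols))
  df <- as.data.frame(trajectory)[, cols, drop = FALSE]
  for (j in seq_along(df))
    if (is.numeric(df[[j]]))
      df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV file path.
#' @return A data frame of class `trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  class(df) <- c("trajectory", "data.frame")
  df
}
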