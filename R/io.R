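## Delimited-text I/O for estimator inputs: work-profile tables (column 1 =
## xi, one column per trajectory) and lambda-series tables (lambda, dudl,
## optional se). Header comment lines start with '#'.

#' Write a work-profile table
#'
#' @param profiles a [work_profile_set()].
#' @param path output TSV path.
#' @param header optional extra comment lines (prefixed with `#`).
#' @return Invisibly, `path`.
#' @export
write_work_table <- function(profiles, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sprintf("# work profiles: %d trajectories, units kJ/mol, xi %s",
                    profiles$n, profiles$units), header)
  writeLines(meta, con)
  df <- data.frame(xi = profiles$xi, profiles$W)
  names(df) <- c("xi", paste0("traj", seq_len(profiles$n)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a work-profile table
#'
#' @param path TSV written by [write_work_table()] (or any table with an
#'   `xi` column followed by one column per trajectory).
#' @param units coordinate units label.
#' @return A [work_profile_set()].
#' @export
read_work_table <- function(path, units = "nm") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (names(df)[1] != "xi") stop("first column must be xi")
  work_profile_set(df$xi, as.matrix(df[, -1, drop = FALSE]), units = units)
}

#' Write a lambda-series table
#'
#' @param series a [lambda_series()].
#' @param path output TSV path.
#' @param header optional extra comment lines.
#' @return Invisibly, `path`.
#' @export
write_lambda_table <- function(series, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# lambda series: dudl in kcal/mol", header), con)
  utils::write.table(as.data.frame(series), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a lambda-series table
#'
#' @param path TSV with columns lambda, dudl, optionally se.
#' @return A [lambda_series()].
#' @export
read_lambda_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("lambda", "dudl") %in% names(df)))
    stop("lambda table needs columns lambda, dudl")
  lambda_series(df$lambda, df$dudl,
                se = if ("se" %in% names(df)) df$se else NULL)
}
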