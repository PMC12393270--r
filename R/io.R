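# Trial-table CSV and YAML config I/O. Output CSVs may carry a manifest
# hash as a leading comment line; the readers skip comment lines.

#' Read / write trial tables
#'
#' Trial tables are plain CSV with the columns documented in
#' [simulate_agent()] (plus `subject_id` for cohorts); 1-based trial
#' indices. A leading `# manifest: <hash>` comment, if present, is
#' ignored on read.
#'
#' @param trials trial table.
#' @param path file path.
#' @param manifest_hash optional hash written as a header comment.
#' @return `read_trials`: the trial table; `write_trials`: `path`,
#'   invisibly.
#' @export
write_trials <- function(trials, path, manifest_hash = NULL) {
  write_csv_commented(trials, path, manifest_hash)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("valid" %in% names(tr)) tr$valid <- as.logical(tr$valid)
  tr
}

write_csv_commented <- function(df, path, manifest_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest_hash)) {
    writeLines(paste0("# manifest: ", manifest_hash), con)
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read / write task or pipeline configuration as YAML
#'
#' @param config a named list.
#' @param path file path.
#' @return `read_config`: a named list; `write_config`: `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

# md5 of a canonical YAML rendering of an R object
hash_object <- function(obj) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(obj, tf)
  unname(tools::md5sum(tf))
}
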