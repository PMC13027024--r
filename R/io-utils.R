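## Input/config error conditions: the CLI maps them to exit codes 1 and 2.
stop_input <- function(...) {
  stop(structure(class = c("adar_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_config <- function(...) {
  stop(structure(class = c("adar_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

require_file <- function(path, what) {
  if (is.null(path)) stop_config(what, " path missing from the configuration")
  if (!file.exists(path)) stop_input(what, " file not found: ", path)
  path
}

#' Read an expression matrix TSV (features x samples)
#'
#' First column holds feature identifiers; remaining columns are numeric
#' sample values.
#'
#' @param path TSV path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_expr_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

#' @param m Feature x sample matrix.
#' @param id_col Name of the identifier column (default `"feature_id"`).
#' @rdname read_expr_tsv
#' @export
write_expr_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

## TSV with a commented provenance header (version, config hash, seed).
## No timestamps: outputs must be byte-identical for a fixed config + seed.
write_tsv_prov <- function(df, path, config = NULL, seed = NULL,
                           header = TRUE) {
  lines <- character()
  if (header) {
    lines <- c(sprintf("#adarindex_version=%s",
                       as.character(utils::packageVersion("adarindex"))),
               sprintf("#config_md5=%s", config_hash(config)))
    if (!is.null(seed)) lines <- c(lines, sprintf("#seed=%d", as.integer(seed)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_config("invalid JSON config ", path, ": ",
                                conditionMessage(e)))
  cfg
}

cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}
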