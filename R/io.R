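# Validated delimited-text readers and writers for the five pipeline inputs.
# All tables are comma-separated UTF-8 with dot decimals.

table_schemas <- function() {
  list(
    trials = list(
      required = c(trial_id = "character", review_id = "character",
                   class_a = "character", class_b = "character",
                   n_a = "numeric", n_b = "numeric",
                   mean_a = "numeric", mean_b = "numeric",
                   sd_a = "numeric", sd_b = "numeric",
                   followup_months = "numeric", scale_name = "character"),
      checks = list(
        list(col = "n_a", ok = function(x) x >= 2, msg = "n_a must be >= 2"),
        list(col = "n_b", ok = function(x) x >= 2, msg = "n_b must be >= 2"),
        list(col = "sd_a", ok = function(x) x > 0, msg = "sd_a must be > 0"),
        list(col = "sd_b", ok = function(x) x > 0, msg = "sd_b must be > 0"),
        list(col = "followup_months", ok = function(x) x >= 0,
             msg = "followup_months must be >= 0"))
    ),
    respondents = list(
      required = c(id = "numeric", weight = "numeric", lbp = "numeric",
                   leg_pain = "numeric", sf12 = "numeric"),
      checks = list(
        list(col = "weight", ok = function(x) x > 0, msg = "weight must be > 0"),
        list(col = "lbp", ok = function(x) x %in% c(0, 1),
             msg = "lbp must be 0/1"),
        list(col = "leg_pain", ok = function(x) x %in% c(0, 1),
             msg = "leg_pain must be 0/1"))
    ),
    crosswalk_pairs = list(
      required = c(health_state = "character", sf12 = "numeric",
                   dw = "numeric"),
      checks = list(
        list(col = "dw", ok = function(x) x > 0 & x < 1,
             msg = "dw must lie strictly in (0, 1)"))
    ),
    haq = list(
      required = c(country = "character", year = "numeric", haq = "numeric"),
      checks = list(
        list(col = "haq", ok = function(x) x >= 0 & x <= 100,
             msg = "haq must lie in [0, 100]"))
    ),
    prevalence = list(
      required = c(country = "character", prevalence = "numeric"),
      checks = list(
        list(col = "prevalence", ok = function(x) x > 0,
             msg = "prevalence must be > 0"))
    )
  )
}

#' Read and validate a pipeline input table
#'
#' Checks header names, column types, and value ranges against the documented
#' schema; validation errors name the offending row and column. Extra columns
#' (e.g. dynamic `cond_*` / `trt_*` indicators or `true_*` ground-truth
#' columns) are kept as-is.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"trials"`, `"respondents"`, `"crosswalk_pairs"`,
#'   `"haq"`, `"prevalence"`.
#' @return A validated data.frame (possibly empty, with a warning).
#' @export
read_input_table <- function(path, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    lbp_validation_error(paste0("unknown schema '", schema, "'"))
  }
  if (!file.exists(path)) {
    lbp_validation_error(paste0("input file not found: ", path))
  }
  df <- as.data.frame(data.table::fread(path, colClasses = NULL,
                                        showProgress = FALSE))
  sc <- schemas[[schema]]
  missing <- setdiff(names(sc$required), names(df))
  if (length(missing)) {
    lbp_validation_error(paste0("table '", schema, "' missing column(s): ",
                                paste(missing, collapse = ", ")))
  }
  if (!nrow(df)) {
    warning(sprintf("table '%s' (%s) is empty", schema, path))
    return(df)
  }
  for (col in names(sc$required)) {
    want <- sc$required[[col]]
    x <- df[[col]]
    if (want == "numeric" && !is.numeric(x)) {
      lbp_validation_error(sprintf(
        "table '%s', column '%s': expected numeric values", schema, col))
    }
    if (want == "character" && !is.character(x)) df[[col]] <- as.character(x)
  }
  for (chk in sc$checks) {
    bad <- which(!chk$ok(df[[chk$col]]) | is.na(df[[chk$col]]))
    if (length(bad)) {
      lbp_validation_error(sprintf("table '%s', row %d, column '%s': %s",
                                   schema, bad[1L], chk$col, chk$msg))
    }
  }
  df
}

#' Write a table as CSV
#'
#' @param df data.frame to write.
#' @param path Output path (parent directory created if missing).
#' @return Invisibly, the path.
#' @export
write_output_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}
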