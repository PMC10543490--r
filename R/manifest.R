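# Cohort manifests: one row per subject with demographics, derived volumes
# and the file paths needed to run segmentation. CSV with a fixed header (or
# an equivalent JSON array of records).

MANIFEST_COLUMNS <- c("subject_id", "age", "sex", "diagnosis", "tiv_cm3",
                      "lvv_cm3", "t1_path", "t2_path", "flair_path",
                      "mask_path", "transform_path")

#' Load and validate a cohort manifest
#'
#' @param path CSV file with header
#'   `subject_id,age,sex,diagnosis,tiv_cm3,lvv_cm3,t1_path,t2_path,flair_path,mask_path,transform_path`
#'   or a JSON array of records with the same fields. Relative paths are
#'   resolved against the manifest's directory.
#' @param check_files verify that every referenced file exists.
#' @return A `data.frame` of class `cohort_manifest`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stopf("manifest does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    # sex codes like "F" must not be parsed as logicals
    read.csv(path, stringsAsFactors = FALSE,
             colClasses = c(sex = "character"))
  }
  validate_manifest(df, base_dir = dirname(path), check_files = check_files)
}

#' Validate a manifest data frame
#'
#' @param df data frame with the manifest columns.
#' @param base_dir directory against which relative paths are resolved;
#'   `NULL` leaves paths untouched.
#' @param check_files verify that referenced files exist.
#' @return The validated data frame (paths resolved), class `cohort_manifest`.
#' @export
validate_manifest <- function(df, base_dir = NULL, check_files = FALSE) {
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols)) {
    stopf("manifest is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stopf("manifest has no rows")
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) {
    stopf("duplicated subject_id: %s", paste(unique(dup), collapse = ", "))
  }
  df$age <- as.numeric(df$age)
  bad_age <- which(!is.finite(df$age) | df$age < 0 | df$age > 120)
  if (length(bad_age)) {
    stopf("age out of [0, 120] in row(s) %s",
          paste(bad_age, collapse = ", "))
  }
  if (!all(df$sex %in% c("F", "M"))) {
    stopf("sex must be 'F' or 'M' (rows %s)",
          paste(which(!df$sex %in% c("F", "M")), collapse = ", "))
  }
  for (col in c("tiv_cm3", "lvv_cm3")) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad)) {
      stopf("%s must be positive (rows %s)", col, paste(bad, collapse = ", "))
    }
  }
  path_cols <- grep("_path$", MANIFEST_COLUMNS, value = TRUE)
  if (!is.null(base_dir)) {
    for (col in path_cols) {
      rel <- !is.na(df[[col]]) & nzchar(df[[col]]) &
        !grepl("^(/|[A-Za-z]:)", df[[col]])
      df[[col]][rel] <- file.path(base_dir, df[[col]][rel])
    }
  }
  if (check_files) {
    for (col in path_cols) {
      ref <- !is.na(df[[col]]) & nzchar(df[[col]])
      missing <- ref & !file.exists(df[[col]])
      if (any(missing)) {
        stopf("missing file(s) referenced by %s: %s", col,
              paste(df[[col]][missing], collapse = ", "))
      }
    }
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a manifest to CSV
#'
#' @param df manifest data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path) {
  write.csv(as.data.frame(df)[, union(MANIFEST_COLUMNS,
                                      names(df))], path, row.names = FALSE)
  invisible(path)
}
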