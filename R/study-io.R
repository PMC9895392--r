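# Study-level data model: each record is one two-arm study (case = GDM,
# control = non-GDM) with per-arm (n, mean, sd) and stratification metadata.

.required_cols <- c("study_id", "timing", "level",
                    "n_case", "mean_case", "sd_case",
                    "n_control", "mean_control", "sd_control")
.meta_cols <- c("sample_type", "country_year", "diagnostic_criteria",
                "excludes_confounders")
.timing_levels <- c("middle", "late")
.level_levels <- c("mRNA", "protein")
.tri_state <- c("yes", "no", "not_available")

#' Construct a study collection
#'
#' A `study_collection` is a data frame of two-arm study summaries, one row
#' per (study, gestational-timing stratum), carrying per-arm sample size,
#' mean and SD plus stratification metadata. Row order is preserved
#' throughout the package: it defines analysis and forest-table order.
#'
#' @param df data frame with columns `study_id`, `timing` (`"middle"` or
#'   `"late"`), `level` (`"mRNA"` or `"protein"`), `n_case`, `mean_case`,
#'   `sd_case`, `n_control`, `mean_control`, `sd_control`; optional metadata
#'   columns `sample_type`, `country_year`, `diagnostic_criteria`,
#'   `excludes_confounders` (`"yes"`, `"no"` or `"not_available"`) are
#'   filled with `"not_available"` when absent.
#' @param provenance free-text label recording where the rows came from.
#' @return A `study_collection` (data frame subclass).
#' @examples
#' study_collection(data.frame(
#'   study_id = "S1", timing = "late", level = "protein",
#'   n_case = 30, mean_case = 5.2, sd_case = 1.1,
#'   n_control = 28, mean_control = 4.4, sd_control = 0.9))
#' @export
study_collection <- function(df, provenance = "user") {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (mc in .meta_cols) {
    if (!mc %in% names(df)) df[[mc]] <- rep("not_available", nrow(df))
    df[[mc]] <- as.character(df[[mc]])
    df[[mc]][is.na(df[[mc]]) | df[[mc]] == ""] <- "not_available"
  }
  df <- df[, c(.required_cols[1:3], .meta_cols, .required_cols[4:9])]
  validate_study_collection(df)
  structure(df, class = c("study_collection", "data.frame"),
            provenance = provenance)
}

validate_study_collection <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  df$study_id <- as.character(df$study_id)
  if (any(is.na(df$study_id) | df$study_id == "")) {
    stop("study_id must be non-empty", call. = FALSE)
  }
  bad <- !df$timing %in% .timing_levels
  if (any(bad)) {
    stop("row ", which(bad)[1L], ": timing must be one of ",
         paste(.timing_levels, collapse = "/"), call. = FALSE)
  }
  bad <- !df$level %in% .level_levels
  if (any(bad)) {
    stop("row ", which(bad)[1L], ": level must be one of ",
         paste(.level_levels, collapse = "/"), call. = FALSE)
  }
  bad <- !df$excludes_confounders %in% .tri_state
  if (any(bad)) {
    stop("row ", which(bad)[1L], ": excludes_confounders must be one of ",
         paste(.tri_state, collapse = "/"), call. = FALSE)
  }
  key <- paste(df$study_id, df$timing, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (study_id, timing) pair: ",
         sub("\r", " / ", key[duplicated(key)][1L]), call. = FALSE)
  }
  for (col in c("n_case", "n_control")) {
    x <- df[[col]]
    if (!is.numeric(x) || anyNA(x)) {
      stop("row ", which(is.na(suppressWarnings(as.numeric(x))))[1L], ": ",
           col, " is not numeric", call. = FALSE)
    }
    bad <- x < 1 | x != round(x)
    if (any(bad)) {
      stop("row ", which(bad)[1L], ": ", col,
           " must be a positive integer", call. = FALSE)
    }
  }
  for (col in c("mean_case", "mean_control", "sd_case", "sd_control")) {
    x <- df[[col]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
      stop(col, " must be finite numeric", call. = FALSE)
    }
  }
  bad <- df$sd_case < 0 | df$sd_control < 0
  if (any(bad)) {
    stop("row ", which(bad)[1L], ": sd must be non-negative", call. = FALSE)
  }
  invisible(df)
}

#' @export
print.study_collection <- function(x, ...) {
  cat(sprintf("study_collection: %d record(s) [%s]\n", nrow(x),
              attr(x, "provenance") %||% "unknown"))
  if (nrow(x) > 0L) {
    cat(sprintf("  case n = %d, control n = %d\n",
                sum(x$n_case), sum(x$n_control)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strip a study collection down to a plain data frame
#'
#' @param x a `study_collection`.
#' @param ... unused.
#' @return A plain data frame without the provenance attribute.
#' @export
as.data.frame.study_collection <- function(x, ...) {
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  x
}

#' Read a study table from CSV
#'
#' Reads a comma-separated study table (header row required) into a
#' [study_collection()]. Numeric columns are parsed as decimals; missing
#' optional metadata becomes `"not_available"`.
#'
#' @param path path to a CSV file with the columns listed in
#'   [study_collection()].
#' @param sep field separator, `","` by default.
#' @return A `study_collection` with one record per data row, in file order.
#' @seealso [write_study_table()] for the inverse.
#' @export
read_study_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("n_case", "n_control", "mean_case", "mean_control",
                "sd_case", "sd_control")) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    if (nrow(df) > 0L && anyNA(parsed)) {
      stop("row ", which(is.na(parsed))[1L], ": non-numeric value in ",
           col, call. = FALSE)
    }
    df[[col]] <- parsed
  }
  study_collection(df, provenance = path)
}

#' Write a study table to CSV
#'
#' @param collection a [study_collection()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(collection, path) {
  stopifnot(inherits(collection, "study_collection"))
  utils::write.csv(as.data.frame(collection), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Load the packaged GDF-15 study fixtures
#'
#' Returns the study-level summaries of the GDF-15/GDM combined analysis:
#' 13 GEO dataset rows (mRNA; GSE154377 contributes one middle- and one
#' late-pregnancy stratum) and 7 article rows (serum protein; Tang and
#' Banerjee each contribute both strata). Values are the printed table
#' values; samples taken at delivery are filed under the late stratum.
#'
#' @param level `"mRNA"` (GEO expression datasets) or `"protein"` (serum
#'   articles); `NULL` returns both.
#' @param timing `"middle"` or `"late"` pregnancy stratum; `NULL` returns
#'   both.
#' @return A [study_collection()].
#' @examples
#' late_mrna <- load_gdf15_fixture("mRNA", "late")   # 12 datasets
#' sum(late_mrna$n_case)                             # 142 GDM patients
#' @export
load_gdf15_fixture <- function(level = NULL, timing = NULL) {
  if (!is.null(level)) level <- match.arg(level, .level_levels)
  if (!is.null(timing)) timing <- match.arg(timing, .timing_levels)
  paths <- c(
    mRNA = system.file("extdata", "gdf15_mrna_studies.csv",
                       package = "metagdf15"),
    protein = system.file("extdata", "gdf15_protein_studies.csv",
                          package = "metagdf15"))
  want <- if (is.null(level)) names(paths) else level
  parts <- lapply(paths[want], function(p) as.data.frame(read_study_table(p)))
  df <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out <- study_collection(df, provenance = "gdf15 fixture")
  filter_studies(out, timing = timing)
}

#' Subset a study collection on metadata
#'
#' Keeps rows matching every supplied criterion, preserving input order.
#' `NULL` criteria are ignored; an empty result is valid.
#'
#' @param collection a [study_collection()].
#' @param timing,level,excludes_confounders optional single values to match.
#' @param study_id optional character vector of study identifiers to keep.
#' @return The filtered `study_collection`.
#' @examples
#' prot <- load_gdf15_fixture("protein", "late")
#' filter_studies(prot, excludes_confounders = "yes")  # Tang, Yakut, Jacobsen
#' @export
filter_studies <- function(collection, timing = NULL, level = NULL,
                           excludes_confounders = NULL, study_id = NULL) {
  stopifnot(inherits(collection, "study_collection"))
  keep <- rep(TRUE, nrow(collection))
  if (!is.null(timing)) {
    keep <- keep & collection$timing %in% timing
  }
  if (!is.null(level)) {
    keep <- keep & collection$level %in% level
  }
  if (!is.null(excludes_confounders)) {
    keep <- keep & collection$excludes_confounders %in% excludes_confounders
  }
  if (!is.null(study_id)) {
    keep <- keep & collection$study_id %in% study_id
  }
  out <- as.data.frame(collection)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(collection),
            provenance = attr(collection, "provenance"))
}
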