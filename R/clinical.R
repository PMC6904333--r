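#' Read a per-sample clinical table
#'
#' Parses a delimited clinical file into the standardized covariate set
#' the pipeline uses: `sex` (male/female, `NA` if unknown), the binary
#' age dichotomy `age_ge_18m` (at least 18 months at diagnosis),
#' `mycn_amplified` (1/0/`NA`), the binary stage dichotomy `stage4`
#' (stage 4 versus stages 1/2/3/4S), and one or two survival endpoints
#' given as time (months) plus event indicator columns. Samples with
#' unknown categories are retained with `NA`; analyses exclude them
#' listwise only where the field is needed.
#'
#' @param path delimited text file with a header row.
#' @param column_map named list mapping standardized names to column
#'   names in the file. Recognized entries: `sample`, `sex`, `age`,
#'   `mycn`, `stage`, `os_time`, `os_event`, `efs_time`, `efs_event`.
#'   At least `sample` and one `*_time`/`*_event` pair are required.
#' @param delimiter field separator, default tab.
#' @param time_unit `"months"` (stored as-is) or `"days"` (divided by
#'   30.4375); survival times are stored in months.
#' @return a `data.frame` of class `"clinical_table"` with columns
#'   `sample_id`, `sex`, `age_ge_18m`, `mycn_amplified`, `stage4` and the
#'   mapped endpoint columns.
#' @export
read_clinical <- function(path, column_map, delimiter = "\t",
                          time_unit = c("months", "days")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop_("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  need <- function(key) {
    col <- column_map[[key]]
    if (is.null(col)) return(NULL)
    if (!col %in% colnames(raw))
      stop_("mapped column '", col, "' (", key, ") not present in file")
    raw[[col]]
  }
  sample_id <- need("sample")
  if (is.null(sample_id)) stop_("column_map must name a 'sample' column")
  if (anyDuplicated(sample_id))
    stop_("duplicate sample identifiers in clinical table")
  n <- length(sample_id)

  out <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  out$sex <- recode_domain(need("sex"), c(
    "male" = "male", "m" = "male", "female" = "female", "f" = "female"),
    "sex", allow_missing = TRUE)
  out$age_ge_18m <- recode_domain(need("age"), c(
    "<18 months" = 0, ">=18 months" = 1, "≥18 months" = 1,
    "0" = 0, "1" = 1), "age", allow_missing = TRUE, numeric = TRUE)
  out$mycn_amplified <- recode_domain(need("mycn"), c(
    "amplified" = 1, "not amplified" = 0, "0" = 0, "1" = 1),
    "mycn", allow_missing = TRUE, numeric = TRUE)
  out$stage4 <- recode_domain(need("stage"), c(
    "1" = 0, "2" = 0, "3" = 0, "4s" = 0, "4" = 1),
    "stage", allow_missing = TRUE, numeric = TRUE)

  got_endpoint <- FALSE
  for (ep in c("os", "efs")) {
    tcol <- need(paste0(ep, "_time")); ecol <- need(paste0(ep, "_event"))
    if (is.null(tcol) && is.null(ecol)) next
    if (is.null(tcol) || is.null(ecol))
      stop_("endpoint '", ep, "' needs both time and event columns")
    t_miss <- tolower(trimws(tcol)) %in% c("", "na")
    tt <- suppressWarnings(as.numeric(tcol))
    if (any(is.na(tt) & !t_miss))
      stop_("non-numeric ", ep, " time value: ",
            paste(unique(tcol[is.na(tt) & !t_miss]), collapse = ", "))
    if (any(tt < 0, na.rm = TRUE)) stop_("negative ", ep, " survival time")
    if (time_unit == "days") tt <- tt / 30.4375
    e_miss <- tolower(trimws(ecol)) %in% c("", "na")
    ev <- suppressWarnings(as.numeric(ecol))
    bad <- (!is.na(ev) & !ev %in% c(0, 1)) | (is.na(ev) & !e_miss)
    if (any(bad))
      stop_("event indicator for '", ep, "' outside {0,1}: ",
            paste(unique(ecol[bad]), collapse = ", "))
    out[[paste0(ep, "_time")]] <- tt
    out[[paste0(ep, "_event")]] <- ev
    got_endpoint <- TRUE
  }
  if (!got_endpoint) stop_("column_map names no survival endpoint")
  class(out) <- c("clinical_table", "data.frame")
  out
}

# map raw strings onto a stated domain; anything unmapped is an error,
# empty/unknown strings become NA when missing values are allowed
recode_domain <- function(x, map, field, allow_missing = FALSE,
                          numeric = FALSE) {
  if (is.null(x)) return(NULL)
  key <- tolower(trimws(x))
  miss <- key %in% c("", "na", "nan", "unknown", "missing", "-", "--")
  val <- map[key]
  bad <- is.na(names(val)) & !miss
  if (any(bad) || (any(miss) && !allow_missing))
    stop_("unmapped value(s) for '", field, "': ",
          paste(unique(x[bad | (miss & !allow_missing)]), collapse = ", "))
  out <- unname(val)
  out[miss] <- NA
  if (numeric) as.numeric(out) else as.character(out)
}
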