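#' Default column-name map for multichannel DIA precursor reports
#'
#' Maps the internal field names used throughout the package to the
#' column headers of a DIA-NN-style multichannel precursor report.
#' Report dialects drift across software versions, so every reader
#' accepts a user-supplied override of this map.
#'
#' @return Named character vector: names are internal field names,
#'   values are the expected report column headers.
#' @export
default_column_map <- function() {
  c(
    run               = "Run",
    precursor_id      = "Precursor.Id",
    modified_sequence = "Modified.Sequence",
    stripped_sequence = "Stripped.Sequence",
    charge            = "Precursor.Charge",
    global_q          = "Q.Value",
    channel           = "Channel",
    channel_q         = "Channel.Q.Value",
    ptm_q             = "PTM.Q.Value",
    ptm_site_conf     = "PTM.Site.Confidence",
    intensity_L       = "Channel.L",
    intensity_H       = "Channel.H",
    ms1_area          = "Ms1.Area",
    protein_group     = "Protein.Group",
    genes             = "Genes"
  )
}

.numeric_fields <- c("charge", "global_q", "channel_q", "ptm_q",
                     "ptm_site_conf", "intensity_L", "intensity_H", "ms1_area")
.intensity_fields <- c("intensity_L", "intensity_H", "ms1_area")
.q_fields <- c("global_q", "channel_q", "ptm_q", "ptm_site_conf")

#' Read a multichannel DIA precursor report
#'
#' Parses a tab-separated precursor report (one row per run x precursor x
#' channel) into the internal record layout. Channel labels are normalized
#' to `L`, `H` and `decoy`; decoy rows are retained so that downstream
#' diagnostic summaries remain possible, and are excluded by the analysis
#' filters instead. Empty numeric cells become `NA`, never 0, and
#' intensities of exactly 0 are converted to `NA`: a zero MS1 area is
#' indistinguishable from non-detection in these reports.
#'
#' @param path Path to a tab-separated report with a header row.
#' @param column_map Named character vector mapping internal field names to
#'   report column headers; see [default_column_map()]. Fields other than
#'   the required ones may be dropped from the map only if absent upstream.
#' @return A `data.frame` of class `precursor_report` with one row per
#'   report row and the internal column names.
#' @export
read_precursor_report <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop("report file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), quote = "")
  parse_precursor_report(raw, column_map = column_map, source = path)
}

#' Coerce a raw report data frame to the internal record layout
#'
#' Same validation and normalization as [read_precursor_report()], applied
#' to an in-memory data frame (e.g. one produced by
#' [simulate_channel_report()]).
#'
#' @param raw Data frame carrying the report columns named per `column_map`.
#' @param column_map See [default_column_map()].
#' @param source Label used in error messages.
#' @return A `precursor_report` data frame.
#' @export
parse_precursor_report <- function(raw, column_map = default_column_map(),
                                   source = "report") {
  stopifnot(is.data.frame(raw))
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    stop("schema error in ", source, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rec <- raw[unname(column_map)]
  names(rec) <- names(column_map)

  for (f in .numeric_fields) {
    v <- rec[[f]]
    if (is.character(v) || is.factor(v)) {
      vc <- as.character(v)
      num <- suppressWarnings(as.numeric(vc))
      bad <- !is.na(vc) & vc != "" & is.na(num)
      if (any(bad)) {
        stop("unparseable numeric in column '", column_map[[f]], "' of ",
             source, " at line(s) ",
             paste(utils::head(which(bad) + 1L, 5L), collapse = ", "))
      }
      rec[[f]] <- num
    } else {
      rec[[f]] <- as.numeric(v)
    }
  }

  ch <- as.character(rec$channel)
  norm <- rep(NA_character_, length(ch))
  norm[toupper(ch) %in% c("L", "LIGHT")] <- "L"
  norm[toupper(ch) %in% c("H", "HEAVY")] <- "H"
  norm[tolower(ch) %in% c("decoy", "d")] <- "decoy"
  if (anyNA(norm[!is.na(ch)])) {
    offending <- unique(ch[!is.na(ch) & is.na(norm)])
    stop("unknown channel label(s) in ", source, ": ",
         paste(offending, collapse = ", "))
  }
  rec$channel <- norm

  # zero intensity is indistinguishable from non-detection
  for (f in .intensity_fields) {
    v <- rec[[f]]
    v[!is.na(v) & v <= 0] <- NA_real_
    if (any(!is.na(v) & !is.finite(v))) {
      stop("non-finite intensity in column '", column_map[[f]], "' of ", source)
    }
    rec[[f]] <- v
  }
  for (f in .q_fields) {
    v <- rec[[f]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("values outside [0,1] in column '", column_map[[f]], "' of ", source)
    }
  }
  key <- paste(rec$run, rec$precursor_id, rec$channel, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (run, precursor, channel) rows in ", source, ": e.g. ",
         gsub("\r", " / ", key[duplicated(key)][1L]))
  }
  rownames(rec) <- NULL
  class(rec) <- c("precursor_report", "data.frame")
  rec
}

#' Write precursor records back to a report TSV
#'
#' Inverse of [read_precursor_report()]: emits a tab-separated file using
#' the report column headers from `column_map`. Numerics are written with
#' 17 significant digits so a read/write round trip reproduces values to
#' full double precision.
#'
#' @param records A `precursor_report` data frame.
#' @param path Output file path.
#' @param column_map See [default_column_map()].
#' @return Invisibly, `path`.
#' @export
write_precursor_report <- function(records, path,
                                   column_map = default_column_map()) {
  out <- records[names(column_map)]
  for (f in .numeric_fields) {
    v <- out[[f]]
    out[[f]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  names(out) <- unname(column_map)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.precursor_report <- function(x, ...) {
  cat(sprintf("Multichannel precursor report: %d rows, %d runs, %d precursors\n",
              nrow(x), length(unique(x$run)), length(unique(x$precursor_id))))
  tab <- table(x$channel)
  cat("  channels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read and validate a study-design table
#'
#' The design maps runs to the levels of the 2x2 treatment design
#' (MEK inhibitor x growth-factor mix) plus replicate and cell line.
#' Accepts a TSV with columns `run`, `cell_line`, `meki`, `gf`, `replicate`
#' or a YAML file holding a list of such records.
#'
#' @param path Path to a TSV or YAML (`.yml`/`.yaml`) design file.
#' @return A `data.frame` of class `study_design`.
#' @export
read_study_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(lst, function(e) as.data.frame(e, stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  as_study_design(df)
}

#' Validate a study-design data frame
#'
#' @param df Data frame with columns `run`, `cell_line`, `meki`, `gf`,
#'   `replicate`.
#' @return A validated `study_design` data frame.
#' @export
as_study_design <- function(df) {
  req <- c("run", "cell_line", "meki", "gf", "replicate")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[req]
  df$run <- as.character(df$run)
  df$cell_line <- as.character(df$cell_line)
  df$meki <- as.integer(df$meki)
  df$gf <- as.integer(df$gf)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$run)) {
    stop("duplicate run identifier(s) in design: ",
         paste(unique(df$run[duplicated(df$run)]), collapse = ", "))
  }
  if (anyNA(df$meki) || !all(df$meki %in% c(0L, 1L))) {
    stop("design column 'meki' must be 0 or 1")
  }
  if (anyNA(df$gf) || !all(df$gf %in% c(0L, 1L))) {
    stop("design column 'gf' must be 0 or 1")
  }
  if (anyNA(df$replicate) || any(df$replicate < 1L)) {
    stop("design column 'replicate' must be a positive integer")
  }
  rownames(df) <- NULL
  class(df) <- c("study_design", "data.frame")
  df
}

#' Condition label per design row
#'
#' @param design A `study_design`.
#' @return Character vector, one `MEKi<0/1>.GF<0/1>` label per run.
#' @export
design_condition <- function(design) {
  sprintf("MEKi%d.GF%d", design$meki, design$gf)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d runs, %d cell line(s)\n",
              nrow(x), length(unique(x$cell_line))))
  tab <- table(design_condition(x))
  cat("  replicates per condition:",
      paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Cross-validate a report against a study design
#'
#' Every run in the report must appear in the design and vice versa.
#'
#' @param records A `precursor_report`.
#' @param design A `study_design`.
#' @return Invisibly `TRUE`; errors name the offending runs otherwise.
#' @export
validate_report_design <- function(records, design) {
  rr <- unique(records$run)
  dr <- design$run
  only_report <- setdiff(rr, dr)
  only_design <- setdiff(dr, rr)
  if (length(only_report)) {
    stop("run(s) present in report but absent from design: ",
         paste(only_report, collapse = ", "))
  }
  if (length(only_design)) {
    stop("run(s) present in design but absent from report: ",
         paste(only_design, collapse = ", "))
  }
  invisible(TRUE)
}
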