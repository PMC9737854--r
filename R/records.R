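.required_columns <- c("subject_id", "group", "timepoint",
                       "pss10", "swls", "nmq", "mbi_ee", "mbi_dp", "mbi_pa")

#' Validate a records table
#'
#' Checks column presence, score types, legal ranges of all six scales and
#' uniqueness of (subject_id, timepoint). All row-level problems are
#' collected and reported together, each with its row number.
#'
#' @param records A data frame (column names case-insensitive, any order).
#' @return The validated data frame with canonical lower-case column names.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  names(records) <- tolower(names(records))
  missing <- setdiff(.required_columns, names(records))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- records[.required_columns]
  records$subject_id <- as.character(records$subject_id)
  records$group <- as.character(records$group)
  records$timepoint <- as.character(records$timepoint)

  problems <- character(0)
  ranges <- plus_scales()
  for (i in seq_len(nrow(ranges))) {
    sc <- ranges$scale[i]
    v <- suppressWarnings(as.numeric(records[[sc]]))
    bad_num <- which(is.na(v))
    if (length(bad_num) > 0L) {
      problems <- c(problems, sprintf(
        "row %d: %s is not a number", bad_num, sc))
    }
    out <- which(!is.na(v) & (v < ranges$min[i] | v > ranges$max[i]))
    if (length(out) > 0L) {
      problems <- c(problems, sprintf(
        "row %d: %s = %g outside legal range [%g, %g]",
        out, sc, v[out], ranges$min[i], ranges$max[i]))
    }
    records[[sc]] <- v
  }
  dup <- duplicated(records[c("subject_id", "timepoint")])
  if (any(dup)) {
    problems <- c(problems, sprintf(
      "row %d: duplicate (subject_id, timepoint) = (%s, %s)",
      which(dup), records$subject_id[dup], records$timepoint[dup]))
  }
  if (length(problems) > 0L) {
    stop("invalid records:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  records
}

#' Read a per-subject questionnaire records file
#'
#' Reads a delimited text file with one row per subject per assessment and
#' the columns \code{subject_id}, \code{group}, \code{timepoint},
#' \code{pss10}, \code{swls}, \code{nmq}, \code{mbi_ee}, \code{mbi_dp},
#' \code{mbi_pa} (any order, case-insensitive), and validates every row.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter (default comma; use \code{";"} for
#'   spreadsheet exports from semicolon locales).
#' @return A validated records data frame.
#' @export
read_records <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                           check.names = FALSE)
  validate_records(raw)
}

#' Score every row of a records table
#'
#' @param records A records data frame (validated if not already).
#' @param model A \code{plus_model}.
#' @return The records with ten appended columns: the six normalized tier-1
#'   values (\code{norm_*}), the three module outputs and \code{plus_score}.
#' @details Inference is memoized per tier over the distinct input
#'   combinations actually present (questionnaire totals are integers, so
#'   cohorts repeat values heavily); results are identical to calling
#'   \code{\link{plus_evaluate}} row by row.
#' @export
plus_score_records <- function(records, model = plus_default_model()) {
  records <- validate_records(records)
  ids <- names(model$normalizers)
  norm <- lapply(ids, function(id) {
    ux <- unique(records[[id]])
    lut <- vapply(ux, function(x) plus_normalize(id, x, model), numeric(1))
    lut[match(records[[id]], ux)]
  })
  names(norm) <- ids
  memo_infer <- function(sys, inmat) {
    key <- apply(round(inmat, 12), 1L, paste, collapse = ",")
    first <- which(!duplicated(key))
    vals <- vapply(first, function(i)
      infer(sys, setNames(inmat[i, ], names(sys$inputs))), numeric(1))
    vals[match(key, key[first])]
  }
  mental <- memo_infer(model$module_mental, cbind(norm$pss10, norm$swls))
  burnout <- memo_infer(model$module_burnout,
                        cbind(norm$mbi_ee, norm$mbi_dp, norm$mbi_pa))
  final <- memo_infer(model$final, cbind(mental, norm$nmq, burnout))
  out <- as.data.frame(norm)
  names(out) <- paste0("norm_", ids)
  out$module_mental <- mental
  out$module_physical <- norm$nmq
  out$module_burnout <- burnout
  out$plus_score <- final
  cbind(records, out)
}

#' Write scored results
#'
#' CSV output holds one row per subject-timepoint with the six normalized
#' values, three module outputs and the PLUS score, at 12 significant
#' digits (lossless round-trip at that precision). JSON output holds the
#' same rows as an array of objects at full precision.
#'
#' @param results Non-empty data frame from \code{\link{plus_score_records}}.
#' @param path Output path.
#' @param format \code{"csv"} or \code{"json"} (default from the file
#'   extension).
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path,
                          format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) stop("no results to write", call. = FALSE)
  if (format == "csv") {
    num <- vapply(results, is.numeric, logical(1))
    out <- results
    out[num] <- lapply(out[num], function(v) formatC(v, digits = 12,
                                                     format = "g"))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
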