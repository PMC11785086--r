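#' Write a cohort table to CSV/TSV
#'
#' Numeric cells are serialized with 17 significant digits so that a
#' write/read round trip reproduces finite values bit-exactly; missing cells
#' are written as empty fields.
#'
#' @param table a cohort data.frame.
#' @param path output file; a `.tsv` extension selects tab separation.
#' @export
write_cohort <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- as.data.frame(table)
  for (cl in names(out)) {
    if (is.double(out[[cl]])) {
      v <- sprintf("%.17g", out[[cl]])
      v[is.na(out[[cl]])] <- NA
      out[[cl]] <- v
    }
  }
  data.table::fwrite(out, path, sep = sep, na = "", quote = "auto")
  invisible(path)
}

#' Read a cohort table from CSV/TSV
#'
#' Validates the mandatory columns, coerces covariate factors to the schema
#' levels, and restricts metabolite columns to the supplied panel. Unknown
#' columns are dropped with a warning; empty fields become missing cells.
#'
#' @param path CSV/TSV file with a header row.
#' @param panel a [metabolite_panel()] naming the expected metabolite
#'   columns.
#' @return A `cohort` data.frame.
#' @export
read_cohort <- function(path, panel = default_panel()) {
  raw <- data.table::fread(path, na.strings = "", data.table = FALSE,
                           check.names = FALSE)
  if (!all(c("status", "prs") %in% names(raw)))
    stop("cohort file must contain 'status' and 'prs' columns")
  if (anyNA(raw$status) || anyNA(raw$prs))
    stop("status and prs may not be missing")
  if (!all(raw$status %in% c(0, 1)))
    stop("status must be coded 0/1")

  s <- cohort_schema()
  known <- c("participant_id", "status", "prs", covariate_names(),
             panel$name)
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
    raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  }
  missing_mets <- setdiff(panel$name, names(raw))
  if (length(missing_mets))
    stop("metabolite columns absent from file: ",
         paste(utils::head(missing_mets, 5), collapse = ", "))

  for (nm in names(s$factors)) {
    if (nm %in% names(raw)) {
      v <- as.character(raw[[nm]])
      bad <- !is.na(v) & !(v %in% s$factors[[nm]])
      if (any(bad)) stop("invalid level in column ", nm)
      raw[[nm]] <- factor(v, levels = s$factors[[nm]])
    }
  }
  raw$status <- as.integer(raw$status)
  # schema-typed storage so round trips are exact whatever fread guessed
  for (nm in intersect(c("prs", s$numeric, panel$name), names(raw)))
    raw[[nm]] <- as.double(raw[[nm]])
  for (nm in intersect(s$binary, names(raw)))
    raw[[nm]] <- as.integer(raw[[nm]])
  attr(raw, "panel") <- panel
  class(raw) <- c("cohort", "data.frame")
  raw
}
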