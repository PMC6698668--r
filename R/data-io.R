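# Reading and writing the delimited-table interchange formats.
#
# Canonical calibration table (long): assay_id, amp_percent, cpg_pos,
# apparent_percent.  Canonical sample table (long): sample_id, group,
# cpg_pos, observed_percent.  Tab- or comma-separation is auto-detected;
# empty fields and "NA" both encode missing values.

.detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (length(line) == 0L) stop("no records in ", path)
  if (grepl("\t", line)) "\t" else ","
}

.read_table <- function(path, dialect) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sep <- switch(dialect, auto = .detect_sep(path), tsv = "\t", csv = ",",
                stop("unknown table dialect: ", dialect))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (nrow(tab) == 0L) stop("no records in ", path)
  tab
}

.num_col <- function(tab, col, path) {
  v <- tab[[col]]
  if (is.null(v)) stop(sprintf("column '%s' is missing in %s", col, path))
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s' at data row %d of %s",
                 v[bad[1L]], col, bad[1L], path))
  out
}

.check_percent_col <- function(v, col, path) {
  bad <- which(!is.na(v) & (v < 0 | v > 100))
  if (length(bad))
    stop(sprintf("value %g in column '%s' at data row %d of %s is outside [0,100]",
                 v[bad[1L]], col, bad[1L], path))
}

#' Read a calibration table
#'
#' Reads a long-format delimited calibration table with columns `assay_id`,
#' `amp_percent`, `cpg_pos`, `apparent_percent` and assembles the `l x m`
#' apparent-methylation grid.  CpG x AMP combinations absent from the file
#' are recorded as missing cells.
#'
#' @param path file path.
#' @param dialect `"auto"` (default; detects tab vs comma), `"tsv"` or
#'   `"csv"`.
#' @param proportions set `TRUE` to accept methylation as proportions in
#'   \[0,1\] and rescale to percent; by default proportions are rejected
#'   since all internal arithmetic is on the percent scale.
#' @param region optional `GRanges` region to attach to the design.
#' @return A [CalibrationData-class].
#' @export
readCalibrationTable <- function(path, dialect = "auto", proportions = FALSE,
                                 region = NULL) {
  tab <- .read_table(path, dialect)
  amp <- .num_col(tab, "amp_percent", path)
  pos <- .num_col(tab, "cpg_pos", path)
  val <- .num_col(tab, "apparent_percent", path)
  if (proportions) { amp <- amp * 100; val <- val * 100 }
  .check_percent_col(amp, "amp_percent", path)
  .check_percent_col(val, "apparent_percent", path)
  assay <- unique(as.character(tab$assay_id))
  if (length(assay) != 1L)
    stop("calibration table must contain exactly one assay_id (found ",
         length(assay), ") in ", path)
  dup <- duplicated(cbind(amp, pos))
  if (any(dup))
    stop(sprintf("duplicate (AMP, CpG) pair (%g, %g) at data row %d of %s",
                 amp[dup][1L], pos[dup][1L], which(dup)[1L], path))
  lev <- sort(unique(amp))
  ps <- sort(unique(pos))
  y <- matrix(NA_real_, length(lev), length(ps))
  y[cbind(match(amp, lev), match(pos, ps))] <- val
  calibrationData(calibrationDesign(lev, ps, assayId = assay, region = region), y)
}

#' Read a sample table
#'
#' Reads a long-format delimited sample table with columns `sample_id`,
#' `group`, `cpg_pos`, `observed_percent`.
#'
#' @inheritParams readCalibrationTable
#' @param design optional [CalibrationDesign-class]; when supplied, the
#'   sample CpGs must be a subset of the design's and are aligned to its
#'   order (design CpGs missing from the table become missing columns).
#' @return A [SampleData-class].
#' @export
readSampleTable <- function(path, dialect = "auto", design = NULL,
                            proportions = FALSE) {
  tab <- .read_table(path, dialect)
  ids <- as.character(tab$sample_id)
  if (is.null(tab$sample_id)) stop("column 'sample_id' is missing in ", path)
  grp <- as.character(tab$group)
  bad <- which(!grp %in% c("control", "case"))
  if (length(bad))
    stop(sprintf("unknown group label '%s' at data row %d of %s (expected control/case)",
                 grp[bad[1L]], bad[1L], path))
  pos <- .num_col(tab, "cpg_pos", path)
  val <- .num_col(tab, "observed_percent", path)
  if (proportions) val <- val * 100
  .check_percent_col(val, "observed_percent", path)
  ps <- if (is.null(design)) sort(unique(pos)) else design@cpgPositions
  if (!is.null(design) && !all(pos %in% ps))
    stop("sample table contains CpG position(s) not present in the design: ",
         paste(utils::head(setdiff(pos, ps), 3L), collapse = ", "))
  uid <- unique(ids)
  obs <- matrix(NA_real_, length(uid), length(ps),
                dimnames = list(uid, NULL))
  obs[cbind(match(ids, uid), match(pos, ps))] <- val
  g <- grp[match(uid, ids)]
  sampleData(obs, g, ps, sampleIds = uid)
}

#' Write / read a correction table
#'
#' Writes a [CorrectionResult-class] as a delimited table with columns
#' `id`, `group`, `cpg_pos`, `observed`, `corrected`, `method`, rows ordered
#' by id then position, numeric values echoed to 4 decimal places.
#'
#' @param result a non-empty [CorrectionResult-class].
#' @param path output (input) file path.
#' @param sep field separator (default tab).
#' @return `readCorrectionTable` returns the restored
#'   [CorrectionResult-class].
#' @export
writeCorrectionTable <- function(result, path, sep = "\t") {
  stopifnot(is(result, "CorrectionResult"))
  tab <- result@table
  if (nrow(tab) == 0L) stop("empty correction result")
  tab <- tab[order(as.character(tab$id), tab$cpg_pos), , drop = FALSE]
  out <- data.frame(id = tab$id, group = tab$group, cpg_pos = tab$cpg_pos,
                    observed = sprintf("%.4f", tab$observed),
                    corrected = sprintf("%.4f", tab$corrected),
                    method = result@method)
  out$observed[is.na(tab$observed)] <- NA
  out$corrected[is.na(tab$corrected)] <- NA
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCorrectionTable
#' @export
readCorrectionTable <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (nrow(tab) == 0L) stop("no records in ", path)
  method <- unique(tab$method)
  if (length(method) != 1L) stop("correction table mixes methods")
  new("CorrectionResult",
      table = data.frame(id = as.character(tab$id), group = tab$group,
                         cpg_pos = as.numeric(tab$cpg_pos),
                         observed = as.numeric(tab$observed),
                         corrected = as.numeric(tab$corrected)),
      method = method)
}

#' Read CpG positions from a BED-like file
#'
#' Accepts a 4-column BED-like file (`chrom`, `start`, `end`, `cpg_index`;
#' 0-based half-open coordinates as in BED) and returns the 1-based CpG
#' positions (`start + 1`), sorted.  Uses `rtracklayer` when available.
#'
#' @param path BED file path.
#' @return Numeric vector of 1-based positions.
#' @export
readCpGBed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    return(sort(IRanges::start(gr)))     # import() already converts to 1-based
  }
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  sort(as.numeric(tab[[2L]]) + 1)
}
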