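#' Read genomic intervals from a BED file
#'
#' Parses BED3/BED6/narrowPeak-style tab-separated files into a
#' \link[GenomicRanges]{GRanges} with an \code{id} metadata column.
#' Coordinates are interpreted as BED 0-based half-open and stored in the
#' usual 1-based closed \code{GRanges} convention.  Strand is read from
#' column 6 when present; otherwise intervals are unstranded.  Names come
#' from the name column when present and non-empty (\code{"."} counts as
#' empty); missing names are replaced by a synthetic
#' \code{"<chrom>:<start>-<end>:<line>"} id so every interval is addressable.
#' Extra columns (e.g. narrowPeak score and signal) are ignored: the method
#' uses only coordinates.
#'
#' @param path Path to a tab-separated BED-like file.
#' @param id_column 1-based index of the column holding interval names;
#'   defaults to the standard BED name column (4).
#' @return A \code{GRanges} with metadata column \code{id}.  An empty file
#'   yields an empty \code{GRanges}.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tp1", "chr1\t5000\t5400"), bed)
#' read_bed(bed)
#' @export
read_bed <- function(path, id_column = 4L) {
  if (!file.exists(path)) {
    stop_parse("file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) &
    !startsWith(lines, "track") & !startsWith(lines, "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(.granges_from_bed(character(), integer(), integer(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_parse("line %d: expected >= 3 tab-separated columns, found %d",
               line_no[which(nf < 3)[1]], nf[nf < 3][1])
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad) > 0) {
    stop_parse("line %d: non-integer coordinate", line_no[bad[1]])
  }
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad) > 0) {
    stop_parse("line %d: invalid interval [%d, %d): need 0 <= start < end",
               line_no[bad[1]], start0[bad[1]], end0[bad[1]])
  }
  ids <- rep(NA_character_, length(lines))
  if (!is.null(id_column)) {
    has <- nf >= id_column
    ids[has] <- vapply(fields[has], `[[`, character(1), id_column)
  }
  missing_id <- is.na(ids) | !nzchar(ids) | ids == "."
  ids[missing_id] <- sprintf("%s:%d-%d:%d", chrom[missing_id],
                             start0[missing_id], end0[missing_id],
                             line_no[missing_id])
  strand <- rep("*", length(lines))
  has6 <- nf >= 6
  s6 <- rep(NA_character_, length(lines))
  s6[has6] <- vapply(fields[has6], `[[`, character(1), 6L)
  strand[!is.na(s6) & s6 %in% c("+", "-")] <- s6[!is.na(s6) & s6 %in% c("+", "-")]
  .granges_from_bed(chrom, start0, end0, ids, strand)
}

#' Read perturbation expression statistics
#'
#' Reads a tab-separated table with a header, a region-id column and one or
#' two signed statistic columns (fold-change or t-statistic per factor).
#' Statistics must be finite numbers; region ids must be unique.  With one
#' statistic column the returned column is named \code{stat}; with two they
#' are named \code{stat_x} and \code{stat_y} (in the order given), so
#' downstream code is independent of the input header.
#'
#' @param path Path to a TSV file with a header row.
#' @param id_col Name of the region-id column.
#' @param stat_cols Character vector of one or two statistic column names.
#' @return A data.frame with columns \code{region_id} and \code{stat} (or
#'   \code{stat_x}, \code{stat_y}), rows in file order.  The original
#'   statistic column names are kept in attribute \code{"stat_names"}.
#' @export
read_expression <- function(path, id_col = "region_id",
                            stat_cols = c("stat_x", "stat_y")) {
  if (!file.exists(path)) {
    stop_parse("file not found: %s", path)
  }
  if (!length(stat_cols) %in% c(1L, 2L)) {
    stop_contract("stat_cols must name 1 or 2 columns")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(c(id_col, stat_cols), names(df))
  if (length(missing_cols) > 0) {
    stop_parse("column(s) not found in %s: %s", path,
               paste(missing_cols, collapse = ", "))
  }
  ids <- df[[id_col]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop_parse("duplicate region id(s): %s",
               paste(utils::head(dup, 10), collapse = ", "))
  }
  out <- data.frame(region_id = ids, stringsAsFactors = FALSE)
  std_names <- if (length(stat_cols) == 1) "stat" else c("stat_x", "stat_y")
  for (k in seq_along(stat_cols)) {
    raw <- df[[stat_cols[k]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.finite(num))
    if (length(bad) > 0) {
      stop_parse("row %d, column '%s': non-numeric statistic '%s'",
                 bad[1], stat_cols[k], raw[bad[1]])
    }
    out[[std_names[k]]] <- num
  }
  attr(out, "stat_names") <- stat_cols
  out
}

#' Write a result table to tab-separated text
#'
#' Writes any result data.frame (associated peaks, direct targets, KS
#' comparisons, expression records) as TSV with a header.  Doubles are
#' printed with 17 significant digits so values survive a write/read
#' round-trip exactly.
#'
#' @param records A data.frame; an empty one yields a header-only file.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @seealso [read_result()] for the matching reader.
#' @export
write_table <- function(records, path) {
  if (is.null(records)) {
    stop_contract("records must be non-null")
  }
  records <- as.data.frame(records)
  fmt <- records
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  ok <- tryCatch({
    utils::write.table(fmt, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_parse("cannot write %s: %s", path, conditionMessage(ok))
  }
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path Path to a TSV file with a header.
#' @return A data.frame with column types inferred (numbers as numeric).
#' @export
read_result <- function(path) {
  if (!file.exists(path)) {
    stop_parse("file not found: %s", path)
  }
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
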