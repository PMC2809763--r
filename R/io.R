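#' Read a section-count table
#'
#' Reads the `SectionCounts` CSV schema: UTF-8, comma-separated, header
#' `animal_id,genotype,section_position_um,count`; positions in decimal
#' micrometres (dot decimal separator, locale-independent), counts
#' non-negative integers.  Row order is preserved.  Schema violations
#' (missing column, non-integer or negative count) raise a parse error
#' naming the offending row.
#'
#' @param path file path.
#' @return a `SectionCounts` data frame.
#' @export
read_section_counts <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("animal_id", "genotype", "section_position_um", "count")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_domain("missing column(s): %s", paste(missing, collapse = ", "))
  df <- df[required]
  df$animal_id <- as.character(df$animal_id)
  df$genotype <- as.character(df$genotype)
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(!is.finite(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad))
    stop_domain("count '%s' at data row %d is not a non-negative integer",
                as.character(df$count[bad[1]]), bad[1])
  df$count <- as.integer(cnt)
  df$section_position_um <- as.numeric(df$section_position_um)
  if (any(!is.finite(df$section_position_um)))
    stop_domain("non-numeric section position at data row %d",
                which(!is.finite(df$section_position_um))[1])
  df
}

#' Write a section-count table
#'
#' Inverse of [read_section_counts()]; the write -> read round trip is an
#' identity on valid tables.
#'
#' @param counts a `SectionCounts` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_section_counts <- function(counts, path) {
  required <- c("animal_id", "genotype", "section_position_um", "count")
  stopifnot(is.data.frame(counts), all(required %in% names(counts)))
  utils::write.csv(counts[required], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
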