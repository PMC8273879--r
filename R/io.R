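RESPONSE_COLS <- c("participant", "trial", "prime_structure",
                   "grammatical", "semantic_correct", "response")

#' Read a coded-response table
#'
#' Reads a CSV of coded trial responses with the documented header
#' `participant,trial,prime_structure,grammatical,semantic_correct,
#' response`. Response labels must be one of the prime structures or
#' `"N/A"` (uncodable); violations are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A response-table data frame.
#' @export
read_responses <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(RESPONSE_COLS, names(tab))
  if (length(missing) > 0) {
    stop("response table missing columns: ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[, RESPONSE_COLS]
  tab$trial <- as.integer(tab$trial)
  tab$semantic_correct[tab$semantic_correct == ""] <- NA_character_
  allowed <- c(unique(tab$prime_structure), "N/A")
  bad <- which(!tab$response %in% allowed)
  if (length(bad) > 0) {
    stop("unknown response label(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), ": ",
         paste(unique(tab$response[bad]), collapse = ", "))
  }
  tab
}

#' Write a coded-response table
#'
#' Writes the table as CSV with the documented header; a
#' [read_responses()] round-trip restores the identical table.
#'
#' @param table A response-table data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(table, path) {
  stopifnot(all(RESPONSE_COLS %in% names(table)))
  utils::write.csv(table[, RESPONSE_COLS], path, row.names = FALSE,
                   quote = TRUE, na = "")
  invisible(path)
}
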