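#' Tabular input/output
#'
#' All tables are UTF-8 tab-separated text with a header row. Schemas:
#' \describe{
#'   \item{roster}{`respondent_id`, `age_group`, `sex`, `region`
#'     (optionally `u_i` for synthetic data).}
#'   \item{assignments}{`respondent_id`, `vignette_index`, `trade`,
#'     `risk`, `deal`.}
#'   \item{responses}{`respondent_id`, `vignette_index`, `cash`
#'     (billion EUR), `doses` (million doses).}
#'   \item{video}{`respondent_id`, `treated`, `attitude`,
#'     `donation_points`.}
#'   \item{priorities}{`respondent_id`, `priority` in
#'     higher/equal/lower.}
#' }
#' Real survey exports conforming to these schemas can be fed through the
#' same pipeline as the synthetic tables.
#'
#' @param path File path.
#' @name table_io
NULL

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "))
  x
}

#' @rdname table_io
#' @export
read_roster <- function(path)
  .read_tsv(path, c("respondent_id", "age_group", "sex", "region"))

#' @rdname table_io
#' @export
read_assignments <- function(path)
  .read_tsv(path, c("respondent_id", "vignette_index", "trade", "risk",
                    "deal"))

#' @rdname table_io
#' @export
read_responses <- function(path)
  .read_tsv(path, c("respondent_id", "vignette_index", "cash"))

#' @rdname table_io
#' @export
read_video <- function(path)
  .read_tsv(path, c("respondent_id", "treated", "attitude",
                    "donation_points"))

#' @rdname table_io
#' @export
read_priorities <- function(path)
  .read_tsv(path, c("respondent_id", "priority"))

#' @rdname table_io
#' @param x Data frame to write.
#' @export
write_table_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Join responses with their vignette conditions
#'
#' Matches each contribution response to its vignette assignment on
#' (`respondent_id`, `vignette_index`) and appends the `trade`, `risk`,
#' `deal` condition columns, the form expected by [support_cdf()].
#'
#' @param responses,assignments Tables as documented in [table_io].
#' @return `responses` with condition columns appended.
#' @export
merge_experiment <- function(responses, assignments) {
  .join_experiment(responses, assignments)
}
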