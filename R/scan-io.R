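# Plain-CSV persistence of scan tables.

#' Read / write scan datasets as CSV
#'
#' The CSV carries one row per probe placement with columns `axis_id`,
#' `distance_angstrom`, `ex`, `ey`, `ez`, `e_ref_kcal` (required), plus
#' `mx`, `my`, `mz`, `weight` and `e_fq_kcal` when available.  A
#' write-then-read round trip reproduces all numeric fields to better
#' than 1e-12.
#'
#' @param path CSV file path.
#' @param dataset a [scan_dataset].
#' @return `read_scan_csv` returns a [scan_dataset]; `write_scan_csv`
#'   returns `path` invisibly.
#' @export
read_scan_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty scan file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty scan dataset in ", path)
  scan_dataset(df)
}

#' @rdname read_scan_csv
#' @export
write_scan_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
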