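#' Read a delimited table with separator auto-detection
#'
#' Accepts comma- or tab-separated text; the separator is chosen from the
#' header line. Used by all tabular readers in the package.
#'
#' @param path File path.
#' @param required Character vector of required column names; a missing
#'   column raises an error naming it.
#' @return A data frame.
#' @export
read_delim_auto <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t"
         else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         comment.char = "")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read a tidy isotope measurement table
#'
#' Expected columns: `sample_id`, `treatment`, `fraction`, `timepoint`,
#' `element`, `value`, `value_type` (one of `delta`, `atom_percent`), plus
#' optional `replicate_index` and spike columns. Delta readings are
#' converted to atom percent on read.
#'
#' @param path Delimited text file (comma or tab).
#' @return Data frame with `value` on the atom-percent scale and
#'   `value_type` set to `"atom_percent"`.
#' @export
read_isotope_table <- function(path) {
  x <- read_delim_auto(path, required = c("sample_id", "treatment",
                                          "fraction", "timepoint", "element",
                                          "value", "value_type"))
  bad <- setdiff(unique(x$value_type), c("delta", "atom_percent"))
  if (length(bad)) {
    stop("unknown value_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  is_delta <- x$value_type == "delta"
  if (any(is_delta)) {
    for (el in unique(x$element[is_delta])) {
      i <- is_delta & x$element == el
      x$value[i] <- delta_to_atom_percent(x$value[i], el)
    }
    x$value_type <- "atom_percent"
  }
  x
}

#' Read a respirometry incubation table
#'
#' @param path Delimited text with columns `sample_id`, `treatment`,
#'   `do_start`, `do_end`, `chamber_volume_l`, `wet_weight_g`, `duration_h`,
#'   `light`.
#' @return Data frame with `light` coerced to logical.
#' @export
read_incubation_table <- function(path) {
  x <- read_delim_auto(path, required = c("sample_id", "treatment",
                                          "do_start", "do_end",
                                          "chamber_volume_l", "wet_weight_g",
                                          "duration_h", "light"))
  x$light <- as.logical(x$light)
  x
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
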