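#' Percentage of a count over a total
#'
#' @param n count captured.
#' @param total denominator count.
#' @param digits optional rounding (default none).
#' @return `100 * n / total`.
#' @export
percentage <- function(n, total, digits = NULL) {
  if (total <= 0) stop("total must be positive")
  out <- 100 * n / total
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Published summary counts shipped with the package
#'
#' Loads the small table of study-level counts (numbers of up/down regulated
#' genes, genes captured within given TSS distances of bound sites, and the
#' hypogammaglobulinemia screening tallies) from `inst/extdata`, for use in
#' worked-example recomputations.
#'
#' @return data.frame with columns quantity, value.
#' @export
reported_counts <- function() {
  path <- system.file("extdata", "reported_counts.tsv",
                      package = "chromassoc", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @keywords internal
count_value <- function(counts, quantity) {
  v <- counts$value[counts$quantity == quantity]
  if (length(v) != 1L) stop("unknown quantity: ", quantity)
  v
}
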