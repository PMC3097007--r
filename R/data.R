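#' Convert between grouped counts and raw per-subject values
#'
#' A two-group discrete numerical dataset can be stored either as raw
#' per-subject values or as a 2 x g table of counts per outcome value
#' (g = K + 1 outcome values on the scale \{0, ..., K\}).
#' \code{expand_counts()} turns a count vector into the raw values it
#' represents; \code{collapse_counts()} tabulates raw values back into
#' counts. The two are mutually inverse up to within-group ordering.
#'
#' @param counts Vector of g non-negative integer counts; element i is
#'   the number of subjects with value i - 1.
#' @param K Scale maximum. Defaults to \code{length(counts) - 1} for
#'   \code{expand_counts()} and \code{max(values)} for
#'   \code{collapse_counts()}.
#' @return \code{expand_counts()}: an integer vector of raw values;
#'   \code{collapse_counts()}: an integer vector of g counts.
#' @examples
#' expand_counts(c(2, 1, 0))          # 0 0 1
#' collapse_counts(c(0, 0, 1), K = 2) # 2 1 0
#' @export
expand_counts <- function(counts, K = length(counts) - 1L) {
  K <- .check_K(K)
  if (length(counts) != K + 1 || any(counts < 0) ||
      any(counts != round(counts)) || anyNA(counts)) {
    stop("counts must be ", K + 1, " non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) {
    stop("counts are all zero: at least one subject is required",
         call. = FALSE)
  }
  rep(0:K, times = counts)
}

#' @param values Integer vector of raw values in \{0, ..., K\}.
#' @rdname expand_counts
#' @export
collapse_counts <- function(values, K = max(values)) {
  K <- .check_K(K)
  if (!length(values) || anyNA(values) || any(values != round(values)) ||
      any(values < 0) || any(values > K)) {
    stop("values must be integers in {0..", K, "}", call. = FALSE)
  }
  tabulate(values + 1L, nbins = K + 1L)
}

#' Read a grouped-counts file
#'
#' Reads a delimited text file with a header row and columns
#' \code{value}, then one count column per group (typically two). Lines
#' starting with \code{#} are ignored. The value column must enumerate
#' the full scale 0..K in order.
#'
#' @param path Path to the file (tab, comma or whitespace delimited).
#' @return A tibble with the \code{value} column and one integer count
#'   column per group, with attribute \code{K}.
#' @seealso [grouped_to_samples()]
#' @export
read_grouped_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                          check.names = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "value") {
    stop("expected a 'value' column followed by one count column per group",
         call. = FALSE)
  }
  K <- max(df$value)
  if (!identical(as.integer(df$value), 0:K)) {
    stop("the value column must enumerate 0..K in order", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "K") <- as.integer(K)
  out
}

#' Expand a grouped-counts table to per-group raw samples
#'
#' @param gc A tibble as returned by [read_grouped_counts()]: a
#'   \code{value} column plus one count column per group.
#' @return Named list of integer vectors, one per group column.
#' @export
grouped_to_samples <- function(gc) {
  stopifnot(is.data.frame(gc), "value" %in% names(gc))
  K <- max(gc$value)
  groups <- setdiff(names(gc), "value")
  out <- lapply(groups, function(g) expand_counts(gc[[g]], K = K))
  names(out) <- groups
  out
}
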