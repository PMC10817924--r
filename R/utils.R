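#' Tucker congruence coefficient between two loading vectors
#'
#' Cosine-type similarity used to decide whether two factors extracted from
#' different data halves (or different factor counts) represent the same
#' dietary construct. Equals +/-1 iff the vectors are proportional.
#'
#' @param x,y Numeric vectors of equal length (loadings over the same foods).
#' @return A scalar in \[-1, 1\].
#' @export
tucker_phi <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (all(x == 0) || all(y == 0)) return(0)
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Write a table as deterministic UTF-8 TSV
#'
#' Plain tab-separated output with a header row and no quoting, so that two
#' runs of the same seeded pipeline produce byte-identical files.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# validate an integer seed; reproducibility is mandatory throughout
check_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed) || !is.numeric(seed))
    stop("a single integer 'seed' is required; reproducibility is mandatory",
         call. = FALSE)
  if (abs(seed) >= 2^30) stop("'seed' must lie below 2^30", call. = FALSE)
  as.integer(seed)
}

# deterministic child seeds for sub-streams (metabolome, folds, trees, ...)
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 11 + as.numeric(offset) * 7919) %% 2147480017)
}
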