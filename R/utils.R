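#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile pchisq p.adjust lm coef residuals shapiro.test
#'   t.test wilcox.test rnorm runif rbinom rpois setNames var ave reshape
#' @importFrom utils read.delim write.table head
NULL

# stop() with a consistent prefix so callers can grep error origins
ta_stop <- function(...) stop(sprintf(...), call. = FALSE)

ta_warn <- function(...) warning(sprintf(...), call. = FALSE)

# binary check used by every reader/constructor: reject NA and non-0/1
check_binary <- function(x, what) {
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    ta_stop("%s must be strictly binary (0/1, no missing values)", what)
  }
  invisible(TRUE)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items,
#' used throughout for planted-structure recovery checks. Items are matched
#' by name when both vectors are named.
#'
#' @param a,b cluster label vectors (named or positional).
#' @return a single number in \[-1, 1\]; 1 means identical partitions.
#' @export
ari <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) < 2L) ta_stop("fewer than 2 shared items between partitions")
    a <- a[common]
    b <- b[common]
  }
  if (length(a) != length(b)) ta_stop("partitions have different lengths")
  mclust::adjustedRandIndex(a, b)
}

# write a TSV the way every pipeline output is written
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) ta_stop("file not found: %s", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
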