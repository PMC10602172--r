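# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 20-letter amino-acid alphabet used to validate CDR3 sequences.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a test-result record
#'
#' Uniform one-row container for the statistical tests in the package:
#' the statistic name and value, the two-sided p-value, and the per-group
#' sample sizes (kept as an attribute).
#'
#' @param statistic Name of the statistic.
#' @param value Numeric statistic value.
#' @param p_value Two-sided p-value in \[0, 1\].
#' @param n Sample size(s) used.
#' @return A one-row data frame of class `TestResult`.
#' @keywords internal
new_test_result <- function(statistic, value, p_value, n) {
  stopifnot(is.character(statistic), length(value) == 1L, is.finite(value))
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p-value outside [0, 1]")
  }
  out <- data.frame(statistic = statistic, value = as.numeric(value),
                    p_value = as.numeric(p_value), stringsAsFactors = FALSE)
  attr(out, "n") <- n
  class(out) <- c("TestResult", "data.frame")
  out
}

# Vectorised random CDR3 amino-acid strings of a fixed length.
random_cdr3 <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(AA20, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Clone identity is the (CDR3aa, V, J) triple.
clone_key <- function(df) paste(df$cdr3_aa, df$v_gene, df$j_gene, sep = "|")
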