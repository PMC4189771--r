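#' @keywords internal
"_PACKAGE"

# Gene symbols are matched by exact string after uppercasing; mixed-case
# symbols in the input tables would otherwise fail joins between the
# interactome, module and regulator tables.
norm_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# split a delimited field ("A, B,C") into a clean uppercase character vector
split_field <- function(x, sep = ",") {
  out <- norm_symbols(strsplit(as.character(x), sep, fixed = TRUE)[[1L]])
  out[nzchar(out) & out != "-"]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pnsmap <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "pnsmap_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of planted cluster structure. Values near 1
#' indicate near-identical partitions; 0 is the expected value for
#' independent labelings.
#'
#' @param x,y label vectors of equal length (any atomic type).
#' @return A single numeric value (at most 1).
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- b * cc / n2
  mx <- (b + cc) / 2
  if (mx == expected) return(1)
  (a - expected) / (mx - expected)
}
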