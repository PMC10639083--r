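# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

stop_param <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_param(name, " must lie in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (any(!is.finite(x)) || any(x < min) || any(x != round(x))) {
    stop_param(name, " must be an integer >= ", min)
  }
  invisible(x)
}

#' Write a data frame as a TSV file
#'
#' Plain tab-separated output with a header line, no quoting and no row
#' names; the format used for every tabular artifact the package emits.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV file written by [write_tsv()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# Deterministic RNG scope: evaluates `expr` under `seed` and restores the
# caller's RNG state afterwards, so generators never leak global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
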