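#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows distinct n pull rename count across
NULL

BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste0(x, collapse = "")

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

check_positions <- function(position, len, what = "position") {
  bad <- which(!is.finite(position) | position < 1 | position > len)
  if (length(bad)) {
    abort(sprintf("%s out of range [1, %d]: %s", what, len,
                  paste(position[bad], collapse = ", ")))
  }
  invisible(position)
}

# 3 alternatives to each base, used by the mutation simulator
other_bases <- function(base) setdiff(BASES, base)
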