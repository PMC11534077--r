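#' Ancestry codebook
#'
#' The ordered mapping between reference-ancestry names and the integer
#' codes used in RFMIX2 \code{.msp.tsv} files.  Codes are always the
#' contiguous range \code{0..K-1} in the order the names are given, which
#' is the order the columns appear in \code{.rfmix.Q} files and the order
#' colors are assigned when plotting.
#'
#' @param names Character vector of ancestry (source-population) names,
#'   unique and non-empty.  Position \code{i} receives code \code{i - 1}.
#' @return An object of class \code{ancestry_codebook}: a named integer
#'   vector of codes, named by ancestry.
#' @examples
#' cb <- ancestry_codebook(c("MiddleEast", "Europe", "SubSaharanAfrica"))
#' cb["Europe"] # code 1
#' @export
ancestry_codebook <- function(names) {
  names <- as.character(names)
  if (length(names) < 1L) {
    stop_validation("codebook must contain at least one ancestry")
  }
  if (anyNA(names) || any(!nzchar(names))) {
    stop_validation("ancestry names must be non-empty")
  }
  if (anyDuplicated(names)) {
    dup <- unique(names[duplicated(names)])
    stop_validation(sprintf(
      "duplicate ancestry name(s): %s", paste(dup, collapse = ", ")))
  }
  structure(
    stats::setNames(seq_along(names) - 1L, names),
    class = "ancestry_codebook"
  )
}

#' @export
print.ancestry_codebook <- function(x, ...) {
  cat(sprintf("<ancestry_codebook> K = %d\n", length(x)))
  cat(paste(sprintf("  %s = %d", names(x), unclass(x)), collapse = "\n"), "\n")
  invisible(x)
}

codebook_names <- function(cb) names(cb)
codebook_size <- function(cb) length(cb)

#' Assert that per-chromosome codebooks agree and return the shared one
#'
#' Per-chromosome RFMIX2 files of one run must share the same ancestry
#' order/codes; combining files with different codebooks would silently
#' scramble ancestries.  This checks exact equality (names and order) and
#' errors naming the first two disagreeing chromosomes.
#'
#' @param codebooks List of \code{ancestry_codebook} objects, optionally
#'   named by chromosome label (names are used in error messages).
#' @return The single shared codebook.
#' @export
merge_codebooks <- function(codebooks) {
  if (!is.list(codebooks) || length(codebooks) < 1L) {
    stop_validation("merge_codebooks() needs at least one codebook")
  }
  ref <- codebooks[[1L]]
  labels <- names(codebooks) %||% as.character(seq_along(codebooks))
  labels[!nzchar(labels)] <- as.character(seq_along(codebooks))[!nzchar(labels)]
  for (i in seq_along(codebooks)) {
    cb <- codebooks[[i]]
    if (!identical(names(cb), names(ref)) ||
        !identical(as.integer(cb), as.integer(ref))) {
      stop_validation(sprintf(
        "codebook mismatch between chromosomes '%s' and '%s': [%s] vs [%s]",
        labels[1L], labels[i],
        paste(names(ref), collapse = ","), paste(names(cb), collapse = ",")))
    }
  }
  ref
}
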