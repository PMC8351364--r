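# 4-CpG epiallele pattern encoding.
#
# A pattern index in 0..15 encodes the methylation state of the 4 CpGs in
# genomic order, most significant bit first: index = 8*b1 + 4*b2 + 2*b3 + b4
# with b_j = 1 if CpG j is methylated. So UUUU -> 0, MUUU -> 8, MMMM -> 15.

.N_PATTERNS <- 16L

# number of methylated CpGs for pattern index 0..15
.PATTERN_POPCOUNT <- vapply(0:15, function(i)
  sum(as.integer(intToBits(i))[1:4]), integer(1))

.PATTERN_BITS <- t(vapply(0:15, function(i)
  as.integer(intToBits(i))[4:1], integer(4)))  # rows: index; cols: CpG 1..4

.PATTERN_STRINGS <- apply(.PATTERN_BITS, 1, function(b)
  paste(ifelse(b == 1L, "M", "U"), collapse = ""))

#' Encode a 4-CpG methylation call vector as a pattern index
#'
#' The encoding is bijective over the 16 possible patterns: the first CpG in
#' genomic order is the most significant bit, so `UUUU -> 0`, `MUUU -> 8` and
#' `MMMM -> 15`.
#'
#' @param calls Either a character vector of length 4 over `"M"`/`"U"`, or a
#'   single 4-character string such as `"MUMU"`. Missing calls (`"."`) are not
#'   encodable; reads carrying them are excluded from the locus.
#' @return Integer pattern index in `0:15`.
#' @seealso [decode_pattern()]
#' @export
#' @examples
#' encode_pattern("MUMU")
#' encode_pattern(c("M", "M", "M", "M"))
encode_pattern <- function(calls) {
  if (is.character(calls) && length(calls) == 1L && nchar(calls) == 4L)
    calls <- strsplit(calls, "", fixed = TRUE)[[1L]]
  if (length(calls) != 4L)
    stop("expected exactly 4 CpG calls")
  if (any(calls == "."))
    stop("MISSING call present: pattern not encodable")
  if (!all(calls %in% c("M", "U")))
    stop("calls must be 'M' or 'U'")
  bits <- as.integer(calls == "M")
  sum(bits * c(8L, 4L, 2L, 1L))
}

#' Decode a pattern index into its 4 methylation calls
#'
#' @param index Integer in `0:15`.
#' @return Character vector of length 4 over `"M"`/`"U"`, genomic order.
#' @export
#' @examples
#' decode_pattern(8)  # "M" "U" "U" "U"
decode_pattern <- function(index) {
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 0L || index > 15L)
    stop("pattern index must be a single integer in 0..15")
  ifelse(.PATTERN_BITS[index + 1L, ] == 1L, "M", "U")
}

.check_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) != .N_PATTERNS)
    stop("expected a numeric vector of 16 pattern counts")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("pattern counts must be finite and non-negative")
  counts
}

.check_dist <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || length(p) != .N_PATTERNS)
    stop("expected a numeric vector of 16 pattern proportions")
  if (any(!is.finite(p)) || any(p < -tol))
    stop("pattern proportions must be finite and non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("pattern proportions are not normalized (sum != 1)")
  pmax(p, 0)
}

#' Convert pattern counts to a pattern distribution
#'
#' @param counts Numeric vector of 16 non-negative pattern counts (indexed by
#'   the bit encoding of [encode_pattern()]).
#' @return Numeric vector of 16 proportions summing to 1.
#' @export
#' @examples
#' counts <- c(30, rep(0, 14), 30)
#' counts_to_distribution(counts)[c(1, 16)]
counts_to_distribution <- function(counts) {
  counts <- .check_counts(counts)
  depth <- sum(counts)
  if (depth <= 0)
    stop("undefined for zero depth")
  counts / depth
}

# internal: pull the 16 count columns (n0..n15) out of a pattern table
.counts_matrix <- function(patterns) {
  cols <- paste0("n", 0:15)
  if (!all(cols %in% names(patterns)))
    stop("pattern table must contain columns n0..n15")
  m <- as.matrix(patterns[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

.locus_id <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)
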