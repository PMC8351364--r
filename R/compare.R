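# Paired-sample epiallele shift analysis: delta-S, elocus calling, EPM,
# multi-control consensus, hyper/hypo direction and pattern-change classes.

#' Classify the epiallele pattern change between two stages
#'
#' Four defined categories, driven by the minor (30%) and dominant (70%)
#' proportion thresholds (strict inequalities):
#' * `disorder_maintenance`: no predominant pattern (all proportions below
#'   the minor threshold) at either stage;
#' * `selection`: no predominant pattern at stage 1, one pattern highly
#'   predominant (above the dominant threshold) at stage 2;
#' * `disorder`: one pattern highly predominant at stage 1, none at stage 2;
#' * `switch`: both stages have a highly predominant pattern but the two
#'   patterns differ.
#' Any locus matching none of the four is `unclassified`.
#'
#' @param p1,p2 Pattern distributions (16 proportions) at stages 1 and 2.
#' @param config [epishift_config()]; uses `minor_threshold` and
#'   `dominant_threshold`.
#' @return One of `"disorder_maintenance"`, `"selection"`, `"disorder"`,
#'   `"switch"`, `"unclassified"`.
#' @export
classify_change <- function(p1, p2, config = epishift_config()) {
  p1 <- .check_dist(p1); p2 <- .check_dist(p2)
  lo <- config$minor_threshold; hi <- config$dominant_threshold
  disordered1 <- max(p1) < lo; disordered2 <- max(p2) < lo
  dominant1 <- max(p1) > hi; dominant2 <- max(p2) > hi
  if (disordered1 && disordered2) return("disorder_maintenance")
  if (disordered1 && dominant2) return("selection")
  if (dominant1 && disordered2) return("disorder")
  if (dominant1 && dominant2 && which.max(p1) != which.max(p2))
    return("switch")
  "unclassified"
}

.CHANGE_CATEGORIES <- c("disorder_maintenance", "selection", "disorder",
                        "switch", "unclassified")

#' Eloci per million loci covered
#'
#' `EPM = 1e6 * E / C` where `E` is the number of eloci between two samples
#' and `C` the number of loci covered by both.
#'
#' @param E Elocus count (`0 <= E <= C`).
#' @param C Count of loci covered in both samples (`> 0`).
#' @return EPM.
#' @export
#' @examples
#' epm(250, 1e6)
epm <- function(E, C) {
  if (length(E) != 1L || length(C) != 1L || !is.finite(E) || !is.finite(C))
    stop("E and C must be single finite numbers")
  if (C <= 0) stop("EPM undefined for C = 0")
  if (E < 0 || E > C) stop("need 0 <= E <= C")
  1e6 * E / C
}

#' Compare the epiallele composition of two samples locus by locus
#'
#' Loci are matched by identical chromosome and 4-CpG positions; both inputs
#' are assumed depth-filtered (see [enumerate_loci()]), so the shared locus
#' count `C` honours the both-samples coverage requirement of the EPM
#' definition. For each shared locus the entropy difference
#' `delta_s = S2 - S1` is computed; the elocus test uses `delta_s` (signed,
#' default) or `-abs(delta_s)` when `elocus_on_absolute_delta_s` is set, with
#' the strict rule `delta_s* < elocus_delta_s_threshold`. The methylation
#' shift direction is `hyper` when `meth2 - meth1 >= meth_diff_threshold`,
#' `hypo` when `<= -meth_diff_threshold`, else `none`.
#'
#' @param patterns1,patterns2 Pattern tables for stage 1 and stage 2.
#' @param config [epishift_config()].
#' @return list of class `epishift_comparison`: `comparisons` (per-locus
#'   data.frame with `s1`, `s2`, `delta_s`, `is_elocus`, `meth1`, `meth2`,
#'   `meth_diff`, `direction`, `category`), `E`, `C`, and `epm` (`NA` when
#'   `C == 0`).
#' @export
compare_samples <- function(patterns1, patterns2, config = epishift_config()) {
  key1 <- paste(patterns1$chrom, patterns1$positions)
  key2 <- paste(patterns2$chrom, patterns2$positions)
  shared <- intersect(key1, key2)
  i1 <- match(shared, key1); i2 <- match(shared, key2)
  C <- length(shared)
  if (C == 0L) {
    cmp <- data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      positions = character(),
                      s1 = numeric(), s2 = numeric(), delta_s = numeric(),
                      is_elocus = logical(), meth1 = numeric(),
                      meth2 = numeric(), meth_diff = numeric(),
                      direction = character(), category = character(),
                      stringsAsFactors = FALSE)
    return(structure(list(comparisons = cmp, E = 0L, C = 0L, epm = NA_real_),
                     class = "epishift_comparison"))
  }
  m1 <- .counts_matrix(patterns1)[i1, , drop = FALSE]
  m2 <- .counts_matrix(patterns2)[i2, , drop = FALSE]
  p1 <- m1 / rowSums(m1)
  p2 <- m2 / rowSums(m2)
  s_of <- function(p) {
    pl <- p * log2(p); pl[p == 0] <- 0
    config$entropy_scale * rowSums(pl)
  }
  s1 <- s_of(p1); s2 <- s_of(p2)
  delta_s <- s2 - s1
  delta_star <- if (config$elocus_on_absolute_delta_s) -abs(delta_s) else delta_s
  is_elocus <- delta_star < config$elocus_delta_s_threshold
  meth1 <- as.vector(p1 %*% .PATTERN_POPCOUNT) / 4
  meth2 <- as.vector(p2 %*% .PATTERN_POPCOUNT) / 4
  meth_diff <- meth2 - meth1
  direction <- ifelse(meth_diff >= config$meth_diff_threshold, "hyper",
                      ifelse(meth_diff <= -config$meth_diff_threshold,
                             "hypo", "none"))
  category <- vapply(seq_len(C), function(i)
    classify_change(p1[i, ], p2[i, ], config), character(1))
  cmp <- data.frame(
    locus_id = patterns1$locus_id[i1],
    chrom = patterns1$chrom[i1],
    start = patterns1$start[i1], end = patterns1$end[i1],
    positions = patterns1$positions[i1],
    s1 = s1, s2 = s2, delta_s = delta_s, is_elocus = is_elocus,
    meth1 = meth1, meth2 = meth2, meth_diff = meth_diff,
    direction = direction, category = category,
    stringsAsFactors = FALSE)
  E <- sum(is_elocus)
  structure(list(comparisons = cmp, E = as.integer(E), C = as.integer(C),
                 epm = epm(E, C)),
            class = "epishift_comparison")
}

#' @export
print.epishift_comparison <- function(x, ...) {
  cat(sprintf("epishift comparison: C = %d shared loci, E = %d eloci, EPM = %s\n",
              x$C, x$E, format(x$epm)))
  invisible(x)
}

#' Consensus eloci across the control comparisons
#'
#' A tumor locus is retained only when it is flagged as an elocus against
#' every one of the control samples (default 3).
#'
#' @param comparisons List of exactly `config$n_npc`
#'   [compare_samples()] results (control as stage 1, tumor as stage 2).
#' @param config [epishift_config()].
#' @return Sorted character vector of consensus elocus `locus_id`s.
#' @export
consensus_eloci <- function(comparisons, config = epishift_config()) {
  if (length(comparisons) != config$n_npc)
    stop(sprintf("consensus requires exactly %d control comparisons, got %d",
                 config$n_npc, length(comparisons)))
  sets <- lapply(comparisons, function(x) {
    cmp <- if (inherits(x, "epishift_comparison")) x$comparisons else x
    cmp$locus_id[cmp$is_elocus]
  })
  sort(Reduce(intersect, sets))
}

#' Pattern-change category fractions over eloci
#'
#' @param comparison An [compare_samples()] result or its per-locus
#'   data.frame.
#' @return Named numeric vector of proportions over the five categories
#'   (summing to 1), computed over eloci only.
#' @export
category_fractions <- function(comparison) {
  cmp <- if (inherits(comparison, "epishift_comparison"))
    comparison$comparisons else comparison
  el <- cmp[cmp$is_elocus, , drop = FALSE]
  if (nrow(el) == 0L) stop("no eloci: category fractions undefined")
  tab <- table(factor(el$category, levels = .CHANGE_CATEGORIES))
  stats::setNames(as.vector(tab) / nrow(el), .CHANGE_CATEGORIES)
}
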