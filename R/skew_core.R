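#' GC and TA skews
#'
#' `gc_skew()` computes (G-C)/(G+C) and `ta_skew()` computes
#' (T-A)/(T+A) from a base-count vector. `simple_skew()` computes the
#' one-sided forms G/(G+C) or T/(T+A), which relate to the full skews by
#' the exact identity `simple = (1 + full)/2`. A zero denominator yields
#' `NA` (never 0).
#'
#' @param counts Named numeric vector with elements `A`, `C`, `G`, `T`.
#' @return A skew value, or `NA_real_` when the denominator is zero.
#' @examples
#' gc_skew(c(A = 0, C = 1, G = 3, T = 0))   # 0.5
#' simple_skew(c(A = 0, C = 3, G = 7, T = 0), "GC")  # 0.7
#' @export
gc_skew <- function(counts) {
  counts <- .check_counts(counts)
  den <- counts[["G"]] + counts[["C"]]
  if (den == 0) return(NA_real_)
  (counts[["G"]] - counts[["C"]]) / den
}

#' @rdname gc_skew
#' @export
ta_skew <- function(counts) {
  counts <- .check_counts(counts)
  den <- counts[["T"]] + counts[["A"]]
  if (den == 0) return(NA_real_)
  (counts[["T"]] - counts[["A"]]) / den
}

#' @rdname gc_skew
#' @param kind `"GC"` for G/(G+C) or `"TA"` for T/(T+A).
#' @export
simple_skew <- function(counts, kind = c("GC", "TA")) {
  kind <- match.arg(kind)
  counts <- .check_counts(counts)
  if (kind == "GC") {
    den <- counts[["G"]] + counts[["C"]]
    if (den == 0) return(NA_real_)
    counts[["G"]] / den
  } else {
    den <- counts[["T"]] + counts[["A"]]
    if (den == 0) return(NA_real_)
    counts[["T"]] / den
  }
}

# vectorized skews from a count matrix (columns A,C,G,T)
.mat_gc_skew <- function(m) {
  den <- m[, "G"] + m[, "C"]
  ifelse(den > 0, (m[, "G"] - m[, "C"]) / den, NA_real_)
}
.mat_ta_skew <- function(m) {
  den <- m[, "T"] + m[, "A"]
  ifelse(den > 0, (m[, "T"] - m[, "A"]) / den, NA_real_)
}

#' Genome-wide pooled skew of a selection
#'
#' Pools all sites of a selection and returns the full GC and TA skews.
#' For a coding-class selection this is the genome-wide coding-strand
#' skew used for coding-mean subtraction in anchor-averaged profiles.
#'
#' @param selection A [site_selection()].
#' @return Named numeric vector `gc`, `ta`.
#' @export
pooled_skew <- function(selection) {
  tab <- table(factor(selection$sites$base, levels = BASES))
  cnt <- setNames(as.numeric(tab), BASES)
  c(gc = gc_skew(cnt), ta = ta_skew(cnt))
}

#' Sliding-window skew profile along chromosomes
#'
#' Computes GC and TA skews of a site selection in sliding windows along
#' each chromosome. At each evaluation point `x` (multiples of `step`
#' from 0 to the chromosome length) the skews are computed over all
#' selection sites in the half-open window `[x - window/2, x +
#' window/2)`. For coding classes, coding-strand bases are pooled across
#' genes of both strands.
#'
#' @param selection A [site_selection()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window Window width in bp (default 10000).
#' @param step Evaluation spacing in bp (default 500).
#' @return A `skew_profile` `data.frame` with columns `chrom`,
#'   `position`, `gc_skew`, `ta_skew`, `n_sites`. Windows with no
#'   countable sites have `NA` skews.
#' @export
windowed_profile <- function(selection, chrom_lengths,
                             window = 10000, step = 500) {
  stopifnot(window > 0, step > 0)
  idx <- .selection_index(selection)
  parts <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    if (window > len) {
      warning("window (", window, ") larger than chromosome ", cn,
              " (", len, "); empty profile")
      return(NULL)
    }
    x <- seq(0, len, by = step)
    cc <- idx[[cn]]
    if (is.null(cc)) cc <- .cumcounts(integer(), character())
    m <- .window_counts(cc, x - window / 2, x + window / 2)
    data.frame(chrom = cn, position = x,
               gc_skew = .mat_gc_skew(m), ta_skew = .mat_ta_skew(m),
               n_sites = as.integer(rowSums(m)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- data.frame(chrom = character(), position = numeric(),
                                      gc_skew = numeric(), ta_skew = numeric(),
                                      n_sites = integer())
  structure(out, window = window, step = step,
            site_class = selection$class,
            class = c("skew_profile", "data.frame"))
}

# swap count columns under reverse-complementation (G<->C, A<->T)
.complement_counts <- function(m) {
  out <- m[, c("T", "G", "C", "A"), drop = FALSE]
  colnames(out) <- BASES
  out
}

# validate/standardize an anchors data.frame
.check_anchors <- function(anchors) {
  stopifnot(all(c("chrom", "pos") %in% names(anchors)))
  if (is.null(anchors$strand)) anchors$strand <- "+"
  anchors$strand[is.na(anchors$strand) | anchors$strand == "."] <- "+"
  stopifnot(all(anchors$strand %in% c("+", "-")))
  anchors
}

# drop anchors too close to chromosome ends for the requested span
.usable_anchors <- function(anchors, chrom_lengths, reach) {
  len <- unlist(chrom_lengths)[anchors$chrom]
  ok <- !is.na(len) & anchors$pos >= reach & anchors$pos <= len - reach
  if (!all(ok)) {
    warning(sum(!ok), " anchor(s) closer than ", reach,
            " bp to a chromosome end were dropped")
  }
  anchors[ok, , drop = FALSE]
}

# per-anchor count accumulation on an offset grid; returns list of
# per-anchor matrices (n_offsets x 4), orientation applied
.anchor_count_list <- function(selection, anchors, offsets, window) {
  idx <- .selection_index(selection)
  lapply(seq_len(nrow(anchors)), function(i) {
    a <- anchors[i, ]
    cc <- idx[[a$chrom]]
    if (is.null(cc)) cc <- .cumcounts(integer(), character())
    if (a$strand == "+") {
      ctr <- a$pos + offsets
      m <- .window_counts(cc, ctr - window / 2, ctr + window / 2)
    } else {
      ctr <- a$pos - offsets   # mirrored offset axis
      m <- .window_counts(cc, ctr - window / 2, ctr + window / 2)
      m <- .complement_counts(m)  # strand-role swap
    }
    m
  })
}

#' Anchor-averaged skew profile around oriented loci
#'
#' Computes the average skew variation around a set of anchor loci
#' (e.g. replication origins oriented by their ACS, or termination-zone
#' midpoints). For each offset on the grid, base counts are pooled over
#' all anchors *before* computing skews (count pooling, not averaging of
#' per-anchor ratios). Anchors on the minus strand are mirrored: their
#' offset axis is flipped and base counts complemented (G with C, T with
#' A), so that all anchors point the same way. Anchors closer than
#' `half_span + window/2` to a chromosome end are dropped with a
#' warning.
#'
#' @param selection A [site_selection()].
#' @param anchors `data.frame` with columns `chrom`, `pos` and
#'   optionally `strand` (`"+"` assumed when absent).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param half_span Maximum |offset| in bp.
#' @param window Sliding-window width in bp.
#' @param step Offset grid spacing in bp.
#' @param subtract_coding_mean If `TRUE`, the genome-wide pooled skew of
#'   `coding_selection` (or of `selection` itself when no coding
#'   selection is given) is subtracted from every point, removing the
#'   constant protein-coding contribution.
#' @param coding_selection Optional coding-class [site_selection()] used
#'   for the subtraction scalar.
#' @return A `skew_profile` `data.frame` with columns `offset`,
#'   `gc_skew`, `ta_skew`, `n_sites`, `n_anchors`.
#' @export
anchor_averaged_profile <- function(selection, anchors, chrom_lengths,
                                    half_span = 15000, window = 10000,
                                    step = 500,
                                    subtract_coding_mean = FALSE,
                                    coding_selection = NULL) {
  stopifnot(half_span > 0, window > 0, step > 0)
  anchors <- .check_anchors(anchors)
  anchors <- .usable_anchors(anchors, chrom_lengths, half_span + window / 2)
  if (nrow(anchors) == 0L) stop("no usable anchors")
  offsets <- seq(-half_span, half_span, by = step)
  counts <- .anchor_count_list(selection, anchors, offsets, window)
  pooled <- Reduce(`+`, counts)
  gc <- .mat_gc_skew(pooled)
  ta <- .mat_ta_skew(pooled)
  if (subtract_coding_mean) {
    ref <- if (is.null(coding_selection)) selection else coding_selection
    ms <- pooled_skew(ref)
    gc <- gc - ms[["gc"]]
    ta <- ta - ms[["ta"]]
  }
  structure(
    data.frame(offset = offsets, gc_skew = gc, ta_skew = ta,
               n_sites = as.integer(rowSums(pooled)),
               n_anchors = nrow(anchors)),
    window = window, step = step, site_class = selection$class,
    subtracted = subtract_coding_mean,
    class = c("skew_profile", "data.frame"))
}

#' Per-anchor skew values on an offset grid
#'
#' Computes, for each anchor separately, the windowed skew at each
#' offset. Used for paired left/right significance testing.
#'
#' @inheritParams anchor_averaged_profile
#' @param kind `"GC"` or `"TA"`.
#' @return Numeric matrix, anchors in rows, offsets (named) in columns;
#'   `NA` where the window holds no countable sites.
#' @export
anchor_skew_matrix <- function(selection, anchors, chrom_lengths,
                               half_span = 15000, window = 10000,
                               step = 500, kind = c("GC", "TA")) {
  kind <- match.arg(kind)
  anchors <- .check_anchors(anchors)
  anchors <- .usable_anchors(anchors, chrom_lengths, half_span + window / 2)
  if (nrow(anchors) == 0L) stop("no usable anchors")
  offsets <- seq(-half_span, half_span, by = step)
  counts <- .anchor_count_list(selection, anchors, offsets, window)
  f <- if (kind == "GC") .mat_gc_skew else .mat_ta_skew
  m <- t(vapply(counts, f, numeric(length(offsets))))
  colnames(m) <- offsets
  m
}

#' Paired test of skew magnitude left vs right of anchors
#'
#' Compares the absolute skew values at offsets `-d` and `+d` across
#' anchors with a paired rank test (Wilcoxon signed-rank on the paired
#' differences; an unpaired rank-sum variant is available). Anchors with
#' an undefined value on either side are dropped.
#'
#' @param skew_matrix Matrix from [anchor_skew_matrix()].
#' @param d Offset distance in bp (a column `-d` and `d` must exist).
#' @param method `"signed_rank"` (paired, default) or `"rank_sum"`
#'   (unpaired).
#' @return List with `p_value`, `n` (anchors used) and `method`.
#' @export
paired_side_test <- function(skew_matrix, d,
                             method = c("signed_rank", "rank_sum")) {
  method <- match.arg(method)
  cl <- as.character(-d); cr <- as.character(d)
  if (!all(c(cl, cr) %in% colnames(skew_matrix))) {
    stop("offsets ", -d, " and ", d, " not on the profile grid")
  }
  left <- abs(skew_matrix[, cl])
  right <- abs(skew_matrix[, cr])
  ok <- !is.na(left) & !is.na(right)
  n <- sum(ok)
  if (n < 6L) stop("fewer than 6 anchors with defined values on both sides")
  left <- left[ok]; right <- right[ok]
  if (method == "signed_rank") {
    if (all(left == right)) return(list(p_value = 1, n = n, method = method))
    p <- suppressWarnings(
      wilcox.test(left, right, paired = TRUE, exact = FALSE)$p.value)
  } else {
    if (all(left == right)) return(list(p_value = 1, n = n, method = method))
    p <- suppressWarnings(
      wilcox.test(left, right, paired = FALSE, exact = FALSE)$p.value)
  }
  list(p_value = p, n = n, method = method)
}

#' Write a skew profile as TSV
#'
#' @param profile A `skew_profile` from [windowed_profile()] or
#'   [anchor_averaged_profile()].
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.skew_profile <- function(x, ...) {
  cat("skew_profile (", attr(x, "site_class"), "): ", nrow(x),
      " points, window ", attr(x, "window"), " bp, step ",
      attr(x, "step"), " bp\n", sep = "")
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
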