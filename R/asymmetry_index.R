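#' Skew direction sign convention
#'
#' Asymmetry indices are signed so that, knowing which strand (leading
#' or lagging) is enriched in which bases, efficient replication origins
#' give positive values and termination sites negative ones. With the
#' default convention the leading strand is enriched in adenines and
#' cytosines (`leading = c("A", "C")`), the situation observed in
#' budding yeasts; the opposite convention (`leading = c("G", "T")`)
#' flips the sign of every index.
#'
#' @param leading Character vector of the two bases enriched on the
#'   leading strand: `c("A","C")` or `c("G","T")`.
#' @return `+1` or `-1`, the multiplier applied to all indices.
#' @export
skew_direction <- function(leading = c("A", "C")) {
  key <- paste(sort(toupper(leading)), collapse = "")
  if (key == "AC") return(1)
  if (key == "GT") return(-1)
  stop("leading-strand enrichment must be {A,C} or {G,T}")
}

# --- segment counting -------------------------------------------------------

# Window bounds of the four strand segments around x with window length L,
# on 0-based integer positions: a base at position p lies in
#   segment 1/3 ([x-L, x))  iff x-L <= p <  x
#   segment 2/4 ((x, x+L])  iff x+1 <= p <= x+L
.seg_bounds <- function(x, L) {
  list(left_lo = x - L, left_hi = x, right_lo = x + 1, right_hi = x + L + 1)
}

#' Four-segment base counts at a position
#'
#' Counts the bases of a site selection on the four strand segments
#' around a focal position `x` with window length `L`: segment 1 is the
#' upper strand over `[x-L, x)`, segment 2 the upper strand over
#' `(x, x+L]`, and segments 3 and 4 the lower strand over the same two
#' intervals. For a coding-class selection, third-codon bases of
#' plus-strand genes accumulate into segments 1/2 and coding-strand
#' bases of minus-strand genes into segments 3/4, by genomic position;
#' genes straddling `x` or a window edge contribute only the positions
#' inside each segment. For an intergenic selection only segments 1 and
#' 2 are populated.
#'
#' @param selection A [site_selection()] of class `third_codon`,
#'   `fourfold_third` or `intergenic`.
#' @param chrom Chromosome name.
#' @param x Focal position (bp, 0-based).
#' @param L Window length (bp). `x` must satisfy
#'   `L <= x <= chrom_length - L`.
#' @param chrom_length Length of the chromosome.
#' @return A 4 x 4 integer matrix (rows: segments 1-4; columns A, C, G,
#'   T) with attributes `x`, `L` and `site_class`.
#' @export
segment_counts <- function(selection, chrom, x, L, chrom_length) {
  if (x < L || x > chrom_length - L) {
    stop("position ", x, " closer than L = ", L,
         " to an end of chromosome ", chrom)
  }
  b <- .seg_bounds(x, L)
  m <- matrix(0L, nrow = 4, ncol = 4,
              dimnames = list(paste0("seg", 1:4), BASES))
  if (selection$class %in% c("third_codon", "fourfold_third")) {
    idxP <- .selection_index(selection, strand = "+")[[chrom]]
    idxM <- .selection_index(selection, strand = "-")[[chrom]]
    if (is.null(idxP)) idxP <- .cumcounts(integer(), character())
    if (is.null(idxM)) idxM <- .cumcounts(integer(), character())
    m[1, ] <- .window_counts(idxP, b$left_lo, b$left_hi)
    m[2, ] <- .window_counts(idxP, b$right_lo, b$right_hi)
    m[3, ] <- .window_counts(idxM, b$left_lo, b$left_hi)
    m[4, ] <- .window_counts(idxM, b$right_lo, b$right_hi)
  } else if (selection$class == "intergenic") {
    idx <- .selection_index(selection)[[chrom]]
    if (is.null(idx)) idx <- .cumcounts(integer(), character())
    m[1, ] <- .window_counts(idx, b$left_lo, b$left_hi)
    m[2, ] <- .window_counts(idx, b$right_lo, b$right_hi)
  } else {
    stop("segment counts are defined for coding and intergenic classes")
  }
  structure(m, x = x, L = L, site_class = selection$class)
}

# simple skew per segment-count row; NA on zero denominator
.seg_simple <- function(m, kind) {
  if (kind == "GC") {
    den <- m[, "G"] + m[, "C"]
    ifelse(den > 0, m[, "G"] / den, NA_real_)
  } else {
    den <- m[, "T"] + m[, "A"]
    ifelse(den > 0, m[, "T"] / den, NA_real_)
  }
}

#' Coding asymmetry indices from segment counts
#'
#' The coding GC index is the difference between the simple skews
#' s(i) = G_i/(G_i+C_i) of segments 1 and 4 versus segments 2 and 3:
#' I = (s1 + s4) - (s2 + s3), multiplied by the direction sign; the TA
#' index uses T_i/(T_i+A_i). At an efficient origin segments 1 and 4
#' are both lagging-synthesized and segments 2 and 3 leading, so with
#' the default direction the indices peak positive there; far from
#' origins and termini they are centred on zero. An index whose four
#' segment denominators are not all positive is `NA`.
#'
#' @param counts Matrix from [segment_counts()] (coding class).
#' @param direction Direction sign from [skew_direction()].
#' @return Named numeric vector `I_GC_cod`, `I_TA_cod`.
#' @export
coding_indices <- function(counts, direction = skew_direction()) {
  sg <- .seg_simple(counts, "GC")
  st <- .seg_simple(counts, "TA")
  c(I_GC_cod = unname(direction * ((sg[1] + sg[4]) - (sg[2] + sg[3]))),
    I_TA_cod = unname(direction * ((st[1] + st[4]) - (st[2] + st[3]))))
}

#' Intergenic asymmetry indices from segment counts
#'
#' Intergenes need no strand separation, so only segments 1 and 2 are
#' used: I = s(1) - s(2) for each skew type, with the same sign
#' convention as [coding_indices()].
#'
#' @inheritParams coding_indices
#' @return Named numeric vector `I_GC_int`, `I_TA_int`.
#' @export
intergenic_indices <- function(counts, direction = skew_direction()) {
  sg <- .seg_simple(counts, "GC")
  st <- .seg_simple(counts, "TA")
  c(I_GC_int = unname(direction * (sg[1] - sg[2])),
    I_TA_int = unname(direction * (st[1] - st[2])))
}

#' Global asymmetry index
#'
#' The global index is the unweighted sum of the coding and intergenic
#' GC and TA indices. Missing components (undefined denominators)
#' contribute 0 and their number is recorded; the sum is `NA` only when
#' every component is missing.
#'
#' @param components Numeric vector of the four component indices
#'   (`I_GC_cod`, `I_TA_cod`, `I_GC_int`, `I_TA_int`), possibly `NA`.
#' @return List with `I_GC_TA` and `n_missing`.
#' @export
global_index <- function(components) {
  stopifnot(length(components) == 4L)
  n_miss <- sum(is.na(components))
  val <- if (n_miss == 4L) NA_real_ else sum(components, na.rm = TRUE)
  list(I_GC_TA = val, n_missing = n_miss)
}

# --- vectorized profiles ----------------------------------------------------

# indices at a vector of positions on one chromosome, from prebuilt
# cumcount structures (idxP/idxM coding by gene strand, idxI intergenic)
.indices_at <- function(x, L, idxP, idxM, idxI, direction) {
  b <- .seg_bounds(x, L)
  s1p <- .window_counts(idxP, b$left_lo, b$left_hi)
  s2p <- .window_counts(idxP, b$right_lo, b$right_hi)
  s3m <- .window_counts(idxM, b$left_lo, b$left_hi)
  s4m <- .window_counts(idxM, b$right_lo, b$right_hi)
  s1i <- .window_counts(idxI, b$left_lo, b$left_hi)
  s2i <- .window_counts(idxI, b$right_lo, b$right_hi)
  sgl <- function(m) { den <- m[, "G"] + m[, "C"]
                       ifelse(den > 0, m[, "G"] / den, NA_real_) }
  stl <- function(m) { den <- m[, "T"] + m[, "A"]
                       ifelse(den > 0, m[, "T"] / den, NA_real_) }
  igc_cod <- direction * ((sgl(s1p) + sgl(s4m)) - (sgl(s2p) + sgl(s3m)))
  ita_cod <- direction * ((stl(s1p) + stl(s4m)) - (stl(s2p) + stl(s3m)))
  igc_int <- direction * (sgl(s1i) - sgl(s2i))
  ita_int <- direction * (stl(s1i) - stl(s2i))
  comp <- cbind(I_GC_cod = igc_cod, I_TA_cod = ita_cod,
                I_GC_int = igc_int, I_TA_int = ita_int)
  n_miss <- rowSums(is.na(comp))
  tot <- rowSums(comp, na.rm = TRUE)
  tot[n_miss == 4L] <- NA_real_
  cbind(comp, I_GC_TA = tot, n_missing = n_miss)
}

.empty_cc <- function() .cumcounts(integer(), character())

# build the three per-chromosome index structures once
.index_structs <- function(coding_selection, intergenic_selection) {
  list(P = .selection_index(coding_selection, strand = "+"),
       M = .selection_index(coding_selection, strand = "-"),
       I = if (is.null(intergenic_selection)) list() else
             .selection_index(intergenic_selection))
}

.struct_for <- function(st, chrom) {
  g <- function(lst) if (is.null(lst[[chrom]])) .empty_cc() else lst[[chrom]]
  list(P = g(st$P), M = g(st$M), I = g(st$I))
}

#' Asymmetry indices at one position
#'
#' Computes the four component indices and the global index at a single
#' genomic position.
#'
#' @param coding_selection Coding-class [site_selection()].
#' @param intergenic_selection Intergenic [site_selection()], or `NULL`
#'   (intergenic components then `NA`).
#' @param chrom Chromosome name.
#' @param x Focal position (bp).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param L Window length in bp (default 20000, the scoring choice;
#'   profiles conventionally use 10000).
#' @param direction Direction sign from [skew_direction()].
#' @return One-row `data.frame` with `I_GC_cod`, `I_TA_cod`,
#'   `I_GC_int`, `I_TA_int`, `I_GC_TA`, `n_missing`.
#' @export
asymmetry_indices <- function(coding_selection, intergenic_selection,
                              chrom, x, chrom_lengths, L = 20000,
                              direction = skew_direction()) {
  len <- chrom_lengths[[chrom]]
  if (x < L || x > len - L) {
    stop("position ", x, " closer than L = ", L,
         " to an end of chromosome ", chrom)
  }
  st <- .struct_for(.index_structs(coding_selection, intergenic_selection),
                    chrom)
  m <- .indices_at(x, L, st$P, st$M, st$I, direction)
  out <- as.data.frame(m)
  out$chrom <- chrom; out$position <- x
  out[, c("chrom", "position", "I_GC_cod", "I_TA_cod", "I_GC_int",
          "I_TA_int", "I_GC_TA", "n_missing")]
}

#' Genome-wide asymmetry-index profile
#'
#' Evaluates the asymmetry indices on a regular grid along each
#' chromosome, at all grid positions at least `L` from the chromosome
#' ends.
#'
#' @inheritParams asymmetry_indices
#' @param step Grid spacing in bp (default 500).
#' @param L Window length in bp (default 10000 for profiles).
#' @return `data.frame` with columns `chrom`, `position`, the four
#'   component indices, `I_GC_TA` and `n_missing`.
#' @export
index_profile <- function(coding_selection, intergenic_selection,
                          chrom_lengths, L = 10000, step = 500,
                          direction = skew_direction()) {
  stopifnot(step > 0, L > 0)
  st <- .index_structs(coding_selection, intergenic_selection)
  parts <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    x <- seq(0, len, by = step)
    x <- x[x >= L & x <= len - L]
    if (length(x) == 0L) return(NULL)
    s <- .struct_for(st, cn)
    m <- .indices_at(x, L, s$P, s$M, s$I, direction)
    cbind(data.frame(chrom = cn, position = x, stringsAsFactors = FALSE),
          as.data.frame(m))
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), position = numeric(),
                      I_GC_cod = numeric(), I_TA_cod = numeric(),
                      I_GC_int = numeric(), I_TA_int = numeric(),
                      I_GC_TA = numeric(), n_missing = integer())
  }
  rownames(out) <- NULL
  structure(out, L = L, step = step,
            class = c("index_profile", "data.frame"))
}

#' Anchor-averaged asymmetry-index profile
#'
#' Averages the index profile across a set of anchor loci (origins or
#' termination midpoints), per offset on a regular grid. Minus-strand
#' anchors have their offset axis mirrored. Indices are computed per
#' anchor and averaged across anchors at each offset (each anchor's
#' four-segment construction is already strand-symmetric, so no base
#' complementation is involved).
#'
#' @inheritParams index_profile
#' @param anchors `data.frame` with `chrom`, `pos`, optional `strand`.
#' @param half_span Maximum |offset| in bp.
#' @return `data.frame` with `offset`, mean component indices, mean
#'   `I_GC_TA` and `n_anchors`.
#' @export
anchor_index_profile <- function(coding_selection, intergenic_selection,
                                 anchors, chrom_lengths, half_span = 15000,
                                 L = 10000, step = 500,
                                 direction = skew_direction()) {
  anchors <- .check_anchors(anchors)
  anchors <- .usable_anchors(anchors, chrom_lengths, half_span + L)
  if (nrow(anchors) == 0L) stop("no usable anchors")
  offsets <- seq(-half_span, half_span, by = step)
  st <- .index_structs(coding_selection, intergenic_selection)
  acc <- matrix(0, nrow = length(offsets), ncol = 5,
                dimnames = list(NULL, c("I_GC_cod", "I_TA_cod", "I_GC_int",
                                        "I_TA_int", "I_GC_TA")))
  nobs <- matrix(0L, nrow = length(offsets), ncol = 5)
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    s <- .struct_for(st, a$chrom)
    x <- if (a$strand == "+") a$pos + offsets else a$pos - offsets
    m <- .indices_at(x, L, s$P, s$M, s$I, direction)[, 1:5, drop = FALSE]
    ok <- !is.na(m)
    m[!ok] <- 0
    acc <- acc + m
    nobs <- nobs + ok
  }
  avg <- acc / nobs
  avg[nobs == 0L] <- NA_real_
  out <- data.frame(offset = offsets, avg, n_anchors = nrow(anchors))
  structure(out, L = L, step = step,
            class = c("index_profile", "data.frame"))
}

# --- intergene scoring ------------------------------------------------------

# evaluation positions for one intergene (0-based half-open interval):
# a single midpoint when shorter than `single_below`, else a grid of
# positions `grid_spacing` apart centred on the midpoint, inside the
# intergene
.intergene_eval_positions <- function(start, end, single_below = 1500,
                                      grid_spacing = 1000) {
  mid <- floor((start + end) / 2)
  len <- end - start
  if (len < single_below) return(mid)
  k <- 0:floor((len - 1) / grid_spacing)
  pos <- sort(unique(c(mid - k * grid_spacing, mid + k * grid_spacing)))
  pos[pos >= start & pos < end]
}

#' Score intergenes as candidate origin loci
#'
#' Evaluates an asymmetry index inside each intergene and returns the
#' best value as the intergene's score. Intergenes shorter than 1.5 kb
#' are evaluated at their midpoint only; longer ones on a grid of
#' positions 1 kb apart centred on the midpoint, keeping the maximum.
#' Evaluation positions closer than `L` to a chromosome end are
#' dropped; an intergene with no valid position gets an `NA` score and
#' a reason.
#'
#' @inheritParams asymmetry_indices
#' @param intergenes Intergene `data.frame` from [derive_intergenes()].
#' @param intergenic_selection Intergenic [site_selection()].
#' @param index Which index is the score: `"global"` (default) or one
#'   of `"I_GC_cod"`, `"I_TA_cod"`, `"I_GC_int"`, `"I_TA_int"`, or
#'   `"all"` to score on every column.
#' @param L Window length in bp (default 20000).
#' @return `data.frame` with one row per intergene: `chrom`, `start`,
#'   `end`, the component indices and `I_GC_TA` at the best position,
#'   `score`, `n_eval`, `n_missing`, `excluded` (reason or `NA`).
#' @export
intergene_score <- function(intergenes, coding_selection,
                            intergenic_selection, chrom_lengths,
                            L = 20000, index = "global",
                            direction = skew_direction()) {
  score_col <- switch(index, global = "I_GC_TA", I_GC_TA = "I_GC_TA",
                      I_GC_cod = "I_GC_cod", I_TA_cod = "I_TA_cod",
                      I_GC_int = "I_GC_int", I_TA_int = "I_TA_int",
                      stop("unknown index: ", index))
  st <- .index_structs(coding_selection, intergenic_selection)
  evals <- lapply(seq_len(nrow(intergenes)), function(i) {
    iv <- intergenes[i, ]
    pos <- .intergene_eval_positions(iv$start, iv$end)
    len <- chrom_lengths[[iv$chrom]]
    pos[pos >= L & pos <= len - L]
  })
  n_eval <- lengths(evals)
  res <- matrix(NA_real_, nrow = nrow(intergenes), ncol = 6,
                dimnames = list(NULL, c("I_GC_cod", "I_TA_cod", "I_GC_int",
                                        "I_TA_int", "I_GC_TA", "n_missing")))
  for (cn in unique(intergenes$chrom)) {
    rows <- which(intergenes$chrom == cn & n_eval > 0)
    if (length(rows) == 0L) next
    x <- unlist(evals[rows])
    grp <- rep(rows, n_eval[rows])
    s <- .struct_for(st, cn)
    m <- .indices_at(x, L, s$P, s$M, s$I, direction)
    for (r in rows) {
      mm <- m[grp == r, , drop = FALSE]
      sc <- mm[, score_col]
      if (all(is.na(sc))) next
      best <- which.max(sc)
      res[r, ] <- mm[best, ]
    }
  }
  out <- data.frame(intergenes[, c("chrom", "start", "end")],
                    as.data.frame(res), n_eval = n_eval,
                    stringsAsFactors = FALSE)
  out$score <- res[, score_col]
  out$excluded <- ifelse(n_eval == 0, "no valid evaluation position",
                         ifelse(is.na(out$score), "index undefined",
                                NA_character_))
  rownames(out) <- NULL
  out
}

#' Write intergene scores
#'
#' Writes the intergene score table as TSV, or its `chrom/start/end/
#' score` columns as BED5.
#'
#' @param scores `data.frame` from [intergene_score()].
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_scores <- function(scores, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(chrom = scores$chrom, start = scores$start,
                      end = scores$end,
                      name = paste0("intergene", seq_len(nrow(scores))),
                      score = scores$score)
    write_bed(bed, path)
  }
  invisible(path)
}
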