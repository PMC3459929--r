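#' Read an origin table
#'
#' Reads a replication-origin table from TSV (columns `chrom`, `start`,
#' `end`, 1-based inclusive, plus any of `status`, `active`,
#' `efficiency`, `replication_time`, `acs_position`, `acs_strand`) or
#' BED (0-based half-open; the strand column, when present, carries the
#' ACS orientation).
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"tsv"` or `"bed"`.
#' @return `data.frame` with 0-based half-open `start`/`end`, a
#'   `midpoint` column, and whatever optional columns were present.
#' @export
read_origins <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(tab)[1:min(6, ncol(tab))] <-
      c("chrom", "start", "end", "name", "score", "acs_strand")[1:min(6, ncol(tab))]
    ori <- data.frame(chrom = tab$chrom, start = as.integer(tab$start),
                      end = as.integer(tab$end), stringsAsFactors = FALSE)
    if (!is.null(tab$acs_strand)) ori$acs_strand <- tab$acs_strand
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end") %in% names(tab)))
    ori <- tab
    ori$start <- as.integer(ori$start) - 1L  # 1-based incl -> 0-based half-open
    ori$end <- as.integer(ori$end)
  }
  ori$midpoint <- (ori$start + ori$end) %/% 2L
  ori
}

#' Colocalize two origin sets
#'
#' Two origin loci colocalize when their intervals overlap or their
#' midpoints are less than 10 kb apart (strict). Matches are resolved
#' one-to-one by smallest midpoint distance, ties by leftmost midpoint
#' in the first set.
#'
#' @param set_a,set_b Origin `data.frame`s with `chrom`, `start`,
#'   `end`, `midpoint`.
#' @param max_distance Midpoint distance threshold in bp (default
#'   10000, strict `<`).
#' @return `data.frame` of matched pairs with columns `a` and `b` (row
#'   indices into each set) and `distance` (bp between midpoints).
#' @export
colocalize <- function(set_a, set_b, max_distance = 10000) {
  if (is.null(set_a$midpoint)) set_a$midpoint <- floor((set_a$start + set_a$end) / 2)
  if (is.null(set_b$midpoint)) set_b$midpoint <- floor((set_b$start + set_b$end) / 2)
  cand <- NULL
  for (i in seq_len(nrow(set_a))) {
    same <- which(set_b$chrom == set_a$chrom[i])
    if (length(same) == 0L) next
    dist <- abs(set_b$midpoint[same] - set_a$midpoint[i])
    ovl <- .overlaps(set_a$start[i], set_a$end[i],
                     set_b$start[same], set_b$end[same])
    hit <- same[ovl | dist < max_distance]
    if (length(hit)) {
      cand <- rbind(cand, data.frame(a = i, b = hit,
                                     distance = dist[match(hit, same)]))
    }
  }
  if (is.null(cand)) {
    return(data.frame(a = integer(), b = integer(), distance = numeric()))
  }
  cand <- cand[order(cand$distance, set_a$midpoint[cand$a]), , drop = FALSE]
  used_a <- logical(nrow(set_a)); used_b <- logical(nrow(set_b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$a[k]] && !used_b[cand$b[k]]) {
      keep[k] <- TRUE
      used_a[cand$a[k]] <- TRUE
      used_b[cand$b[k]] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label intergenes by origin overlap
#'
#' An intergene is labelled 1 when its (half-open) interval overlaps
#' any origin interval of the evaluation set; an origin spanning
#' several intergenes labels them all.
#'
#' @param intergenes Intergene `data.frame`.
#' @param origins Origin `data.frame` (already restricted upstream to
#'   the evaluation set, e.g. confirmed and active).
#' @return Integer vector of 0/1 labels, one per intergene.
#' @export
label_intergenes <- function(intergenes, origins) {
  vapply(seq_len(nrow(intergenes)), function(i) {
    same <- origins$chrom == intergenes$chrom[i]
    as.integer(any(.overlaps(intergenes$start[i], intergenes$end[i],
                             origins$start[same], origins$end[same])))
  }, integer(1))
}

#' ROC curve and AUC for a score
#'
#' Builds the receiver operating characteristic of a score against
#' binary labels, sweeping thresholds from high to low. Equal scores
#' collapse into a single threshold step (a diagonal segment), making
#' the curve invariant under strictly increasing transforms of the
#' score. The area under the curve is computed by the trapezoid rule,
#' which equals the concordance-pair estimator
#' (concordant + ties/2) / (n_pos * n_neg).
#'
#' @param scores Numeric scores (`NA` excluded, count reported).
#' @param labels Binary labels (0/1), same length.
#' @return Object of class `roc`: list with `thresholds`, `fpr`, `tpr`
#'   (each starting at 0,0 and ending at 1,1), `auc`, `n_pos`, `n_neg`,
#'   `n_missing`.
#' @export
roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  ok <- !is.na(scores)
  n_missing <- sum(!ok)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to build a ROC curve")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- !duplicated(grp, fromLast = TRUE)
  thr <- s[last]
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr), fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg, n_missing = n_missing),
            class = "roc")
}

#' @export
print.roc <- function(x, ...) {
  cat("ROC: AUC =", format(x$auc, digits = 4),
      sprintf("(%d positives, %d negatives", x$n_pos, x$n_neg))
  if (x$n_missing > 0) cat(",", x$n_missing, "missing scores excluded")
  cat(")\n")
  invisible(x)
}

#' Write a ROC curve as TSV
#'
#' @param x A `roc` object.
#' @param path Output path.
#' @export
write_roc_tsv <- function(x, path) {
  write.table(data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enrichment of positives among the top-ranked items
#'
#' Counts label positives among the `k` highest-scoring items and
#' compares the count with the expectation `k * prevalence` under
#' random selection, using the exact binomial tail
#' P(X >= observed | n = k, p = prevalence) (or its two-sided
#' counterpart).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @param k Number of top items.
#' @param prevalence Baseline positive fraction; defaults to the
#'   prevalence among the scored items.
#' @param alternative `"greater"` (default, upper tail) or
#'   `"two.sided"` (exact binomial test).
#' @return List with `observed`, `expected`, `k`, `prevalence`,
#'   `p_value`.
#' @export
topk_enrichment <- function(scores, labels, k, prevalence = NULL,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!.is_count(k) || k == 0) stop("k must be a positive count")
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  if (k > length(scores)) stop("k exceeds the number of scored items")
  if (is.null(prevalence)) prevalence <- mean(labels == 1L)
  top <- order(scores, decreasing = TRUE)[seq_len(k)]
  observed <- sum(labels[top] == 1L)
  p <- if (alternative == "greater") {
    pbinom(observed - 1L, size = k, prob = prevalence, lower.tail = FALSE)
  } else {
    binom.test(observed, k, p = prevalence,
               alternative = "two.sided")$p.value
  }
  list(observed = observed, expected = k * prevalence, k = k,
       prevalence = prevalence, p_value = p)
}

#' Logistic combination of asymmetry-index components
#'
#' Fits, by maximum likelihood, the logistic regression of the
#' origin-containing label on the four component indices plus an
#' intercept, giving the linear combination of the components that best
#' separates origin-containing from origin-lacking intergenes.
#' Complete separation and unidentifiable (constant) columns are
#' reported explicitly rather than returned as silently divergent
#' estimates.
#'
#' @param components `data.frame` or matrix with columns `I_GC_cod`,
#'   `I_TA_cod`, `I_GC_int`, `I_TA_int` (rows = intergenes).
#' @param labels Binary labels (0/1).
#' @return List with `coefficients`, `se`, `converged`, `separation`
#'   (logical), `aliased` (names of unidentifiable columns), and the
#'   underlying `fit` object.
#' @export
fit_logistic <- function(components, labels) {
  components <- as.data.frame(components)
  need <- c("I_GC_cod", "I_TA_cod", "I_GC_int", "I_TA_int")
  stopifnot(all(need %in% names(components)))
  dat <- cbind(components[, need], label = as.integer(labels))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 50L) stop("need at least 50 complete observations")
  fit <- suppressWarnings(
    glm(label ~ I_GC_cod + I_TA_cod + I_GC_int + I_TA_int,
        data = dat, family = binomial()))
  sm <- summary(fit)
  ali <- names(which(is.na(coef(fit))))
  eps <- 1e-8
  probs <- fitted(fit)
  separation <- all(probs[dat$label == 1] > 1 - eps) &&
    all(probs[dat$label == 0] < eps)
  list(coefficients = coef(fit), se = sm$coefficients[, "Std. Error"],
       converged = fit$converged, separation = separation,
       aliased = ali, fit = fit)
}

#' Spearman correlation between scores and an origin covariate
#'
#' Rank correlation (tie-corrected p-value) between index scores and a
#' covariate such as origin efficiency or replication time, on complete
#' pairs.
#'
#' @param scores Numeric scores.
#' @param covariate Numeric covariate, same length.
#' @return List with `rho`, `p_value`, `n`.
#' @export
correlate <- function(scores, covariate) {
  ok <- !is.na(scores) & !is.na(covariate)
  if (sum(ok) < 10L) stop("need at least 10 complete pairs")
  ct <- suppressWarnings(
    cor.test(scores[ok], covariate[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Compare index values between two origin groups
#'
#' Two-sided unpaired Wilcoxon rank-sum test between two groups of
#' scores (e.g. confirmed vs likely origins), with group medians for
#' box-plot style reporting.
#'
#' @param scores_a,scores_b Numeric vectors (each of length >= 3 after
#'   removing `NA`).
#' @return List with `p_value`, `median_a`, `median_b`, `n_a`, `n_b`.
#' @export
group_compare <- function(scores_a, scores_b) {
  scores_a <- scores_a[!is.na(scores_a)]
  scores_b <- scores_b[!is.na(scores_b)]
  stopifnot(length(scores_a) >= 3L, length(scores_b) >= 3L)
  if (length(unique(c(scores_a, scores_b))) == 1L) {
    p <- 1
  } else {
    p <- suppressWarnings(
      wilcox.test(scores_a, scores_b, exact = FALSE)$p.value)
  }
  list(p_value = p, median_a = median(scores_a), median_b = median(scores_b),
       n_a = length(scores_a), n_b = length(scores_b))
}
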