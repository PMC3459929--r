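#' Read a replication-timing profile
#'
#' Reads a TSV with columns `chrom`, `position`, `value` (one
#' replication-time value per position at a fixed spacing). The spacing
#' is auto-detected as the most common positive position difference.
#'
#' @param path Input path.
#' @return A `timing_profile` `data.frame` with columns `chrom`,
#'   `position`, `rep` and attribute `spacing`.
#' @export
read_timing <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "position", "value") %in% names(tab)))
  timing_profile(tab$chrom, tab$position, tab$value)
}

#' Construct a timing profile
#'
#' @param chrom Chromosome names.
#' @param position Positions in bp (evenly spaced per chromosome).
#' @param rep Replication-time values (arbitrary units).
#' @return A `timing_profile` `data.frame`.
#' @export
timing_profile <- function(chrom, position, rep) {
  out <- data.frame(chrom = as.character(chrom),
                    position = as.numeric(position), rep = as.numeric(rep),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  d <- unlist(tapply(out$position, out$chrom, diff))
  spacing <- if (length(d)) as.numeric(names(sort(table(d), decreasing = TRUE))[1]) else NA_real_
  structure(out, spacing = spacing,
            class = c("timing_profile", "data.frame"))
}

#' Bin a raw timing profile into 500-bp windows
#'
#' Averages a raw profile (conventionally one value every 50 bp) over
#' non-overlapping windows to derive a restricted dataset at the bin
#' spacing. Each bin's value is the mean of the raw values it contains
#' (partial trailing bins keep the mean of what is present); empty bins
#' are dropped. The binned position is the bin start.
#'
#' @param raw A `timing_profile`.
#' @param bin Bin width in bp (default 500).
#' @return A `timing_profile` at `bin` spacing.
#' @export
bin_timing <- function(raw, bin = 500) {
  parts <- lapply(split(as.data.frame(raw), raw$chrom), function(d) {
    b <- floor(d$position / bin) * bin
    agg <- tapply(d$rep, b, mean)
    data.frame(chrom = d$chrom[1], position = as.numeric(names(agg)),
               rep = as.numeric(agg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  timing_profile(out$chrom, out$position, out$rep)
}

#' Call origins as strict peaks of a timing profile
#'
#' All positions `x` of a binned profile such that
#' `rep(x - bin) < rep(x)` and `rep(x) > rep(x + bin)` — strict local
#' maxima with both neighbours present — are called as origin
#' positions. Chromosome ends are never called, plateau points (ties)
#' are not called, and the calls are invariant under adding a constant
#' to `rep` or rescaling it by a positive factor. For timing data where
#' early replication corresponds to small values, set `invert = TRUE`
#' to call local minima instead.
#'
#' @param binned A `timing_profile` (conventionally 500-bp spacing).
#' @param invert Call local minima instead of maxima.
#' @return `data.frame` with columns `chrom`, `position`, `rep` (one
#'   row per called origin).
#' @export
call_origins <- function(binned, invert = FALSE) {
  parts <- lapply(split(as.data.frame(binned), binned$chrom), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    v <- if (invert) -d$rep else d$rep
    n <- length(v)
    if (n < 3L) {
      warning("profile on ", d$chrom[1], " shorter than 3 bins; no calls")
      return(NULL)
    }
    i <- 2:(n - 1)
    peak <- i[v[i] > v[i - 1] & v[i] > v[i + 1]]
    if (!length(peak)) return(NULL)
    data.frame(chrom = d$chrom[1], position = d$position[peak],
               rep = d$rep[peak], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- data.frame(chrom = character(),
                                      position = numeric(), rep = numeric())
  rownames(out) <- NULL
  out
}

#' Pool a site selection across interorigin intervals in fractional bins
#'
#' Divides each interval between consecutive called origins into
#' `n_bins` fractional subintervals and pools the base counts of all
#' intervals per subinterval, so that intervals of different lengths
#' contribute comparably. A site at genomic position `g` in the
#' half-open interval `[o_i, o_{i+1})` maps to bin
#' `floor(n_bins * (g - o_i) / (o_{i+1} - o_i))`. Bins run left origin
#' to right origin on the upper strand. Per-bin simple skews are
#' computed on the pooled counts, not averaged across intervals.
#'
#' @param origins Origin calls (`data.frame` with `chrom`, `position`),
#'   e.g. from [call_origins()].
#' @param selection A [site_selection()].
#' @param n_bins Number of fractional bins (default 20).
#' @return An `interorigin_bins` `data.frame` with columns `bin`
#'   (1-based), `fractional_position` (bin midpoint in (0,1)), `A`,
#'   `C`, `G`, `T`, `n_sites`, `gc` (G/(G+C)), `ta` (T/(T+A)); the
#'   number of pooled intervals is in attribute `n_intervals`.
#' @export
interorigin_bins <- function(origins, selection, n_bins = 20) {
  counts <- matrix(0, nrow = n_bins, ncol = 4,
                   dimnames = list(NULL, BASES))
  n_intervals <- 0L
  sites <- selection$sites
  for (cn in unique(origins$chrom)) {
    o <- sort(origins$position[origins$chrom == cn])
    if (length(o) < 2L) next
    s <- sites[sites$chrom == cn, , drop = FALSE]
    for (k in seq_len(length(o) - 1L)) {
      len <- o[k + 1L] - o[k]
      if (len < n_bins) {
        warning("interorigin interval shorter than ", n_bins,
                " bp on ", cn, "; skipped")
        next
      }
      n_intervals <- n_intervals + 1L
      inside <- s$pos >= o[k] & s$pos < o[k + 1L]
      if (!any(inside)) next
      bin <- floor(n_bins * (s$pos[inside] - o[k]) / len) + 1L
      tab <- table(factor(bin, levels = seq_len(n_bins)),
                   factor(s$base[inside], levels = BASES))
      counts <- counts + unclass(tab)
    }
  }
  gc_den <- counts[, "G"] + counts[, "C"]
  ta_den <- counts[, "T"] + counts[, "A"]
  out <- data.frame(bin = seq_len(n_bins),
                    fractional_position = (seq_len(n_bins) - 0.5) / n_bins,
                    counts,
                    n_sites = as.integer(rowSums(counts)),
                    gc = ifelse(gc_den > 0, counts[, "G"] / gc_den, NA_real_),
                    ta = ifelse(ta_den > 0, counts[, "T"] / ta_den, NA_real_))
  structure(out, n_intervals = n_intervals,
            class = c("interorigin_bins", "data.frame"))
}

#' Test the skew trend across interorigin position
#'
#' Models the per-bin proportion G/(G+C) (or T/(T+A)) against
#' fractional interorigin position with a binomial-family generalized
#' linear model with multiplicative overdispersion (quasibinomial by
#' default), weighted by the per-bin denominator counts. A positive
#' GC-skew slope under the A/C-leading direction convention is the
#' signature of replication-associated skew.
#'
#' @param bins An `interorigin_bins` `data.frame`.
#' @param kind `"GC"` or `"TA"`.
#' @param family `"quasibinomial"` (default) or `"binomial"`.
#' @return List with `slope`, `se`, `p_value`, `dispersion`, `family`,
#'   `converged`, and the underlying `fit`.
#' @export
glm_trend <- function(bins, kind = c("GC", "TA"),
                      family = c("quasibinomial", "binomial")) {
  kind <- match.arg(kind)
  family <- match.arg(family)
  if (kind == "GC") {
    succ <- bins$G; fail <- bins$C
  } else {
    succ <- bins$`T`; fail <- bins$A
  }
  ok <- (succ + fail) > 0
  if (sum(ok) < 10L) stop("need at least 10 bins with nonzero denominators")
  dat <- data.frame(succ = succ[ok], fail = fail[ok],
                    x = bins$fractional_position[ok])
  fam <- if (family == "quasibinomial") quasibinomial() else binomial()
  fit <- glm(cbind(succ, fail) ~ x, family = fam, data = dat)
  if (!fit$converged) warning("GLM did not converge")
  sm <- summary(fit)
  co <- sm$coefficients
  list(slope = co["x", "Estimate"], se = co["x", "Std. Error"],
       p_value = co["x", 4], dispersion = sm$dispersion, family = family,
       converged = fit$converged, fit = fit)
}

# --- codon adaptation index -------------------------------------------------

# codons excluded from the geometric mean: single-codon families and stops
.CAI_EXCLUDED <- c("ATG", "TGG", "TAA", "TAG", "TGA")

.codon_split <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# synonymous families over the standard genetic code, minus excluded codons
.cai_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- setdiff(names(gc), .CAI_EXCLUDED)
  split(codons, gc[codons])
}

# weight table from a reference set of codon-count vectors; zero counts get
# a 0.5 pseudo-count before normalizing each family to max 1
.cai_weights <- function(codon_counts, families) {
  w <- numeric(0)
  for (fam in families) {
    cnt <- codon_counts[fam]
    cnt[cnt == 0] <- 0.5
    w <- c(w, setNames(cnt / max(cnt), fam))
  }
  w
}

#' Iterative (self-consistent) codon adaptation index
#'
#' Computes CAI values with an iteratively refined reference set:
#' codon weights are the within-family relative frequencies in the
#' current reference set (most frequent synonymous codon = 1, zero
#' counts replaced by 0.5 before normalizing); each gene's CAI is the
#' geometric mean of the weights of its codons, excluding ATG, TGG and
#' stop codons; the reference set is then replaced by the top
#' `reference_fraction` of genes by CAI. Iteration starts from the
#' all-genes reference and stops when the reference membership is
#' stable or after `n_iterations`. In highly expressed genomes the
#' converged reference is dominated by ribosomal-protein-like genes,
#' i.e. CAI tracks expression-linked codon bias.
#'
#' @param cds Named character vector of coding sequences (coding
#'   strand; length a multiple of 3).
#' @param reference_fraction Fraction of genes forming the reference
#'   set; the effective size is `max(30, ceiling(fraction * n))`,
#'   capped at `n`. Default 0.01.
#' @param n_iterations Iteration cap (default 20).
#' @return `data.frame` with columns `id`, `cai`, `reference_member`,
#'   plus attributes `iterations` and `weights` (the converged weight
#'   table).
#' @export
cai_compute <- function(cds, reference_fraction = 0.01, n_iterations = 20) {
  stopifnot(reference_fraction > 0, reference_fraction < 1)
  n <- length(cds)
  if (n == 0L) stop("no coding sequences")
  if (is.null(names(cds))) names(cds) <- paste0("gene", seq_len(n))
  families <- .cai_families()
  codon_levels <- unlist(families, use.names = FALSE)
  gene_codons <- lapply(cds, function(s) {
    cod <- .codon_split(toupper(s))
    cod[cod %in% codon_levels]
  })
  if (any(lengths(gene_codons) == 0L)) {
    warning("gene(s) with no scorable codons get NA CAI")
  }
  gene_tabs <- lapply(gene_codons, function(cod)
    table(factor(cod, levels = codon_levels)))
  ref_size <- min(n, max(30L, ceiling(reference_fraction * n)))
  ref <- seq_len(n)
  cai <- rep(NA_real_, n)
  w <- NULL
  iterations <- 0L
  for (it in seq_len(n_iterations)) {
    iterations <- it
    if (length(ref) == 0L) stop("empty reference set")
    counts <- Reduce(`+`, gene_tabs[ref])
    w <- .cai_weights(as.numeric(counts) |> setNames(codon_levels), families)
    cai <- vapply(gene_codons, function(cod) {
      if (length(cod) == 0L) return(NA_real_)
      exp(mean(log(w[cod])))
    }, numeric(1))
    new_ref <- order(cai, decreasing = TRUE)[seq_len(ref_size)]
    new_ref <- new_ref[!is.na(cai[new_ref])]
    if (setequal(new_ref, ref)) { ref <- new_ref; break }
    ref <- new_ref
  }
  out <- data.frame(id = names(cds), cai = cai,
                    reference_member = seq_len(n) %in% ref,
                    stringsAsFactors = FALSE)
  structure(out, iterations = iterations, weights = w)
}

#' Exclude the most codon-biased genes
#'
#' Removes the `exclude_top` fraction of genes with the highest CAI
#' values (ties with the cut-off value are all removed), the standard
#' guard against expression-related skew contamination.
#'
#' @param genes Gene `data.frame` (or any object subsettable by row).
#' @param cai Numeric CAI values aligned with `genes` rows.
#' @param exclude_top Fraction to remove (default 0.20).
#' @return `genes` restricted to the retained rows; the number removed
#'   is in attribute `n_removed`.
#' @export
cai_filter <- function(genes, cai, exclude_top = 0.20) {
  stopifnot(exclude_top >= 0, exclude_top < 1)
  n <- nrow(genes)
  stopifnot(length(cai) == n)
  k <- floor(exclude_top * n)
  if (k == 0L) return(structure(genes, n_removed = 0L))
  thr <- sort(cai, decreasing = TRUE, na.last = TRUE)[k]
  drop <- !is.na(cai) & cai >= thr
  structure(genes[!drop, , drop = FALSE], n_removed = sum(drop))
}
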