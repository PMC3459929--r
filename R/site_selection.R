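#' Build a site selection for skew analysis
#'
#' A site selection is the set of genomic positions, with the base read
#' at each, over which skews are computed. Four classes are supported:
#'
#' * `"third_codon"`: third codon positions of every retained gene,
#'   bases read on the coding strand (minus-strand genes contribute the
#'   complement of the upper-strand base).
#' * `"fourfold_third"`: as above, restricted to fourfold-degenerate
#'   codon families.
#' * `"intergenic"`: every base of every intergene, read on the upper
#'   strand.
#' * `"all_bases"`: every base of the genome, upper strand.
#'
#' `N` bases are skipped everywhere.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param genes Gene `data.frame` (required for coding classes).
#' @param intergenes Intergene `data.frame` (required for
#'   `"intergenic"`).
#' @param class Site class, see above.
#' @return An object of class `site_selection`: a list with elements
#'   `sites` (`data.frame` with `chrom`, `pos` (0-based), `base`
#'   (as-read), `strand` (strand of read)) and `class`.
#' @export
site_selection <- function(genome, genes = NULL, intergenes = NULL,
                           class = c("third_codon", "fourfold_third",
                                     "intergenic", "all_bases")) {
  class <- match.arg(class)
  sites <- switch(class,
    third_codon = ,
    fourfold_third = {
      if (is.null(genes)) stop("genes required for coding site classes")
      ff <- class == "fourfold_third"
      parts <- lapply(seq_len(nrow(genes)), function(i) {
        g <- genes[i, , drop = FALSE]
        tp <- third_codon_positions(g, genome[[g$chrom]], fourfold_only = ff)
        if (nrow(tp) == 0L) return(NULL)
        data.frame(chrom = g$chrom, pos = tp$pos, base = tp$base,
                   strand = g$strand, stringsAsFactors = FALSE)
      })
      do.call(rbind, parts)
    },
    intergenic = {
      if (is.null(intergenes)) stop("intergenes required for intergenic class")
      parts <- lapply(seq_len(nrow(intergenes)), function(i) {
        iv <- intergenes[i, , drop = FALSE]
        ch <- .seq_chars(substr(genome[[iv$chrom]], iv$start + 1L, iv$end))
        keep <- ch %in% BASES
        if (!any(keep)) return(NULL)
        data.frame(chrom = iv$chrom,
                   pos = (iv$start + seq_along(ch) - 1L)[keep],
                   base = ch[keep], strand = "+", stringsAsFactors = FALSE)
      })
      do.call(rbind, parts)
    },
    all_bases = {
      parts <- lapply(names(genome), function(cn) {
        ch <- .seq_chars(genome[[cn]])
        keep <- ch %in% BASES
        data.frame(chrom = cn, pos = (seq_along(ch) - 1L)[keep],
                   base = ch[keep], strand = "+", stringsAsFactors = FALSE)
      })
      do.call(rbind, parts)
    }
  )
  if (is.null(sites)) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        base = character(), strand = character(),
                        stringsAsFactors = FALSE)
  }
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites, class = class), class = "site_selection")
}

#' @export
print.site_selection <- function(x, ...) {
  cat("site_selection (", x$class, "): ", nrow(x$sites), " sites on ",
      length(unique(x$sites$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

# split selection sites into per-chromosome cumulative count structures,
# optionally keeping only sites from genes on one strand
.selection_index <- function(selection, strand = NULL) {
  sites <- selection$sites
  if (!is.null(strand)) sites <- sites[sites$strand == strand, , drop = FALSE]
  lapply(split(sites, sites$chrom), function(s) .cumcounts(s$pos, s$base))
}

#' Count bases of a selection within an interval
#'
#' Tallies the bases (as read on the selection's strand of read) at
#' selection positions inside a 0-based half-open interval.
#'
#' @param selection A [site_selection()].
#' @param chrom Chromosome name.
#' @param start,end Interval bounds, 0-based half-open: positions `p`
#'   with `start <= p < end` are counted.
#' @return Named integer vector `A, C, G, T`.
#' @export
count_bases <- function(selection, chrom, start, end) {
  s <- selection$sites
  keep <- s$chrom == chrom & s$pos >= start & s$pos < end
  tab <- table(factor(s$base[keep], levels = BASES))
  setNames(as.integer(tab), BASES)
}
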