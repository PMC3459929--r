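# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# complement map including N
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.complement_bases <- function(b) unname(.COMPLEMENT[b])

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# chromosome string -> per-position character vector (upper strand)
.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

.clamp01 <- function(x, eps = 1e-9) pmin(pmax(x, eps), 1 - eps)

#' @keywords internal
.check_counts <- function(counts) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(counts)))
  counts[BASES]
}

# Cumulative per-base counts over a sorted position vector, enabling
# O(log n) window queries. pos is 0-based; bases in {A,C,G,T}.
.cumcounts <- function(pos, bases) {
  o <- order(pos)
  pos <- pos[o]
  bases <- bases[o]
  cum <- sapply(BASES, function(b) cumsum(bases == b))
  if (length(pos) == 0L) cum <- matrix(0L, nrow = 0, ncol = 4,
                                       dimnames = list(NULL, BASES))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1, dimnames = list(NULL, BASES))
  list(pos = pos, cum = cum, n = length(pos))
}

# Counts of each base at selection positions p with lo <= p < hi.
# lo, hi may be vectors (one window each); returns matrix n_windows x 4.
.window_counts <- function(cc, lo, hi) {
  if (cc$n == 0L) {
    return(matrix(0L, nrow = length(lo), ncol = 4, dimnames = list(NULL, BASES)))
  }
  i_lo <- findInterval(lo - 0.5, cc$pos)   # index of last pos < lo
  i_hi <- findInterval(hi - 0.5, cc$pos)   # index of last pos < hi
  top <- rbind(0L, cc$cum)                 # prepend zero row
  top[i_hi + 1L, , drop = FALSE] - top[i_lo + 1L, , drop = FALSE]
}

# half-open interval overlap on 0-based coordinates
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0
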