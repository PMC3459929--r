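# Shared toy builders and independent oracles for the test suite.

# write a named character vector as a temporary FASTA file
write_fasta_tmp <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  writeLines(lines, path)
  path
}

# random toy chromosome of given length
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# random non-overlapping genes (multiples of 3) on a toy chromosome
random_genes <- function(len, n, chrom = "c1") {
  width <- 3 * sample(2:6, n, replace = TRUE)
  starts <- sort(sample.int(len - max(width) - 1, n))
  # push apart to avoid overlap (keeps the oracle simple where wanted)
  for (i in seq_len(n)[-1]) {
    starts[i] <- max(starts[i], starts[i - 1] + width[i - 1])
  }
  keep <- starts + width <= len
  data.frame(chrom = chrom, start = starts[keep],
             end = (starts + width)[keep],
             strand = sample(c("+", "-"), sum(keep), replace = TRUE),
             status = "verified",
             id = paste0("g", seq_len(sum(keep))),
             stringsAsFactors = FALSE)
}

# brute-force segment assignment: walk every selection site and place it
# in segments 1-4 by position and gene strand
brute_segment_counts <- function(selection, chrom, x, L) {
  m <- matrix(0L, 4, 4, dimnames = list(paste0("seg", 1:4),
                                        c("A", "C", "G", "T")))
  s <- selection$sites[selection$sites$chrom == chrom, ]
  for (i in seq_len(nrow(s))) {
    p <- s$pos[i]
    side <- if (p >= x - L && p < x) "left" else
            if (p >= x + 1 && p <= x + L) "right" else next
    seg <- if (selection$class == "intergenic") {
      if (side == "left") 1L else 2L
    } else if (s$strand[i] == "+") {
      if (side == "left") 1L else 2L
    } else {
      if (side == "left") 3L else 4L
    }
    m[seg, s$base[i]] <- m[seg, s$base[i]] + 1L
  }
  m
}

# concordance-pair AUC oracle: (concordant + ties/2) / (n_pos * n_neg)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- conc <- ties <- 0
  for (p in pos) {
    conc <- conc + sum(p > neg)
    ties <- ties + sum(p == neg)
    tot <- tot + length(neg)
  }
  (conc + ties / 2) / tot
}

# segment-count fixture used in the index arithmetic tests
seg_matrix <- function(A, C, G, T) {
  matrix(c(A, C, G, T), nrow = 4,
         dimnames = list(paste0("seg", 1:4), c("A", "C", "G", "T")))
}

# small synthetic genome reused by several test files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(chromosome_length = 400000, seed = 101)
      cache <<- generate_genome(spec)
    }
    cache
  }
})
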