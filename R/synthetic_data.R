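#' Specification of a synthetic genome with replication skews
#'
#' Describes a genome in which base composition carries a programmable
#' replication-associated strand skew (G/T enrichment switching between
#' leading- and lagging-replicated regions) and a transcription-
#' associated skew confined to coding strands. Origins are placed at
#' regular spacing; their firing is simulated per replication round so
#' that passive replication emerges from fork convergence, mirroring
#' the notion of origin efficiency as the frequency of active firing.
#'
#' Defaults emulate a compact yeast-like genome: ~40 kb interorigin
#' spacing, 1.5 kb genes alternating with 0.6 kb intergenes (~70%
#' coding), genomic G+C fraction 0.38, replication skew amplitude 0.1
#' (the order of magnitude of observed yeast skew jumps) and
#' transcription skew 0.05 on coding strands.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome (bp).
#' @param origin_spacing Interorigin distance (bp, default 40000).
#' @param origin_efficiencies Firing probability per replication round,
#'   recycled across origins (fractions in (0,1]).
#' @param replication_skew Amplitude `s_rep` of the replication-
#'   associated simple-skew displacement, in [0,1).
#' @param transcription_skew Amplitude `s_txn` of the coding-strand
#'   skew, in [0,1).
#' @param gene_length Gene length (bp, multiple of 3).
#' @param intergene_length Intergene length (bp).
#' @param strand_assignment Probability that a gene lies on the plus
#'   strand.
#' @param base_gc_content Genomic G+C fraction.
#' @param leading Bases enriched on the leading strand (direction
#'   convention), default `c("A","C")`.
#' @param n_rounds Replication rounds simulated to estimate the
#'   per-position leading/lagging exposure.
#' @param snap_origins_to_intergenes Move each origin to the midpoint
#'   of its nearest intergene, emulating the near-exclusive intergenic
#'   localization of yeast origins (default `FALSE`: origins stay on
#'   the regular spacing grid).
#' @param seed Integer seed; the whole genome is a deterministic
#'   function of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chromosomes = 1,
                           chromosome_length = 1200000,
                           origin_spacing = 40000,
                           origin_efficiencies = 1,
                           replication_skew = 0.1,
                           transcription_skew = 0.05,
                           gene_length = 1500,
                           intergene_length = 600,
                           strand_assignment = 0.5,
                           base_gc_content = 0.38,
                           leading = c("A", "C"),
                           n_rounds = 100,
                           snap_origins_to_intergenes = FALSE,
                           seed = 1) {
  stopifnot(replication_skew >= 0, replication_skew < 1,
            transcription_skew >= 0, transcription_skew < 1,
            all(origin_efficiencies > 0), all(origin_efficiencies <= 1),
            gene_length %% 3 == 0,
            origin_spacing > gene_length + intergene_length,
            chromosome_length >= origin_spacing,
            strand_assignment >= 0, strand_assignment <= 1,
            base_gc_content > 0, base_gc_content < 1,
            n_rounds >= 1)
  structure(list(n_chromosomes = n_chromosomes,
                 chromosome_length = chromosome_length,
                 origin_spacing = origin_spacing,
                 origin_efficiencies = origin_efficiencies,
                 replication_skew = replication_skew,
                 transcription_skew = transcription_skew,
                 gene_length = gene_length,
                 intergene_length = intergene_length,
                 strand_assignment = strand_assignment,
                 base_gc_content = base_gc_content,
                 leading = leading,
                 n_rounds = n_rounds,
                 snap_origins_to_intergenes = snap_origins_to_intergenes,
                 seed = seed),
            class = "synthetic_spec")
}

# one replication round: per-position sign of the strand role on the upper
# strand (+1 when the nearest fired origin lies to the right, i.e. upper
# strand lagging-templated; -1 when to the left; 0 at exact fork meeting)
.round_sign <- function(pos, fired) {
  idx <- findInterval(pos, fired)
  left <- c(-Inf, fired)[idx + 1L]
  right <- c(fired, Inf)[idx + 1L]
  dl <- pos - left
  dr <- right - pos
  sign(dl - dr)
}

# average leading/lagging exposure over simulated rounds
.simulate_flag <- function(origins, eff, len, n_rounds) {
  pos <- seq_len(len) - 1
  if (all(eff == 1)) {
    return(.round_sign(pos, origins))
  }
  acc <- numeric(len)
  for (r in seq_len(n_rounds)) {
    fired <- origins[runif(length(origins)) < eff]
    while (length(fired) == 0L) {
      fired <- origins[runif(length(origins)) < eff]
    }
    acc <- acc + .round_sign(pos, fired)
  }
  acc / n_rounds
}

#' Generate a synthetic genome with programmed skews
#'
#' Builds the genome described by a [synthetic_spec()]: origins are
#' placed every `origin_spacing` bp (the first at half a spacing from
#' the chromosome start); per-position leading/lagging exposure `f_lag`
#' on the upper strand is estimated over `n_rounds` simulated
#' replication rounds with independent per-origin firing; genes and
#' intergenes tile the chromosome alternately; and upper-strand bases
#' are drawn with
#' `P(G)/(P(G)+P(C)) = (1 + f_lag * s_rep * sigma + g * s_txn) / 2`
#' (and the analogous form for T/(T+A)), where `sigma` is the direction
#' sign and `g` is +1/-1/0 on plus-gene / minus-gene / intergenic
#' positions. With the default A/C-leading direction, the region left
#' of a fully efficient origin is G- and T-enriched on the upper strand
#' and the region to its right A- and C-enriched, switching back at the
#' interorigin midpoints where converging forks meet.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_genome`: list with `genome`
#'   (named character vector), `genes`, `intergenes`, `origins`
#'   (`data.frame` with `chrom`, `start`, `end`, `midpoint`,
#'   `efficiency`, `acs_strand`, `status`, `active`), `f_lag` (list of
#'   per-position exposures per chromosome) and `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  sigma <- skew_direction(spec$leading)
  len <- spec$chromosome_length
  genome <- character(0)
  genes_all <- list(); origins_all <- list(); flag_all <- list()
  for (ci in seq_len(spec$n_chromosomes)) {
    cn <- paste0("chr", ci)
    n_ori <- floor(len / spec$origin_spacing)
    ori_pos <- spec$origin_spacing %/% 2 + (seq_len(n_ori) - 1) * spec$origin_spacing
    eff <- rep_len(spec$origin_efficiencies, n_ori)

    # alternate intergene/gene tiling from position 0
    unit <- spec$intergene_length + spec$gene_length
    n_unit <- floor(len / unit)
    g_start <- as.integer((seq_len(n_unit) - 1) * unit + spec$intergene_length)
    g_end <- as.integer(g_start + spec$gene_length)
    keep <- g_end <= len
    g_start <- g_start[keep]; g_end <- g_end[keep]

    if (isTRUE(spec$snap_origins_to_intergenes)) {
      # intergene k spans [unit*k, unit*k + intergene_length)
      k <- pmax(0, pmin(n_unit - 1,
                        round((ori_pos - spec$intergene_length / 2) / unit)))
      ori_pos <- k * unit + spec$intergene_length %/% 2
    }
    f_lag <- .simulate_flag(ori_pos, eff, len, spec$n_rounds)
    g_strand <- ifelse(runif(length(g_start)) < spec$strand_assignment,
                       "+", "-")
    genes <- data.frame(chrom = cn, start = g_start, end = g_end,
                        strand = g_strand, status = "verified",
                        id = sprintf("%s_g%04d", cn, seq_along(g_start)),
                        stringsAsFactors = FALSE)

    gsign <- numeric(len)
    for (k in seq_along(g_start)) {
      gsign[(g_start[k] + 1):g_end[k]] <- if (g_strand[k] == "+") 1 else -1
    }

    theta_gc <- .clamp01(0.5 * (1 + f_lag * spec$replication_skew * sigma +
                                  gsign * spec$transcription_skew))
    theta_ta <- .clamp01(0.5 * (1 + f_lag * spec$replication_skew * sigma +
                                  gsign * spec$transcription_skew))
    is_gc <- runif(len) < spec$base_gc_content
    u <- runif(len)
    base <- ifelse(is_gc, ifelse(u < theta_gc, "G", "C"),
                   ifelse(u < theta_ta, "T", "A"))
    genome[cn] <- paste(base, collapse = "")

    origins_all[[cn]] <- data.frame(
      chrom = cn, start = ori_pos - 100, end = ori_pos + 100,
      midpoint = ori_pos, efficiency = eff, acs_strand = "+",
      status = "confirmed", active = TRUE, stringsAsFactors = FALSE)
    genes_all[[cn]] <- genes
    flag_all[[cn]] <- f_lag
  }
  genes <- do.call(rbind, genes_all); rownames(genes) <- NULL
  origins <- do.call(rbind, origins_all); rownames(origins) <- NULL
  intergenes <- derive_intergenes(genes, chrom_lengths(genome))
  structure(list(genome = genome, genes = genes, intergenes = intergenes,
                 origins = origins, f_lag = flag_all, spec = spec),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome:", length(x$genome), "chromosome(s) of",
      x$spec$chromosome_length, "bp;", nrow(x$origins), "origins;",
      nrow(x$genes), "genes\n")
  invisible(x)
}

#' Generate a replication-timing profile for a synthetic genome
#'
#' Produces a smooth profile with one value every `spacing` bp (default
#' 50): triangular peaks at the true origins whose heights scale with
#' origin efficiency and which decay to zero at the interorigin
#' midpoints, plus seeded Gaussian noise expressed as a fraction of the
#' maximal peak height.
#'
#' @param sim A `synthetic_genome` from [generate_genome()].
#' @param noise_sd Noise standard deviation as a fraction of the
#'   maximal peak height (default 0.05).
#' @param spacing Sampling interval in bp (default 50).
#' @param seed Seed for the noise; defaults to `spec$seed + 1`.
#' @return A `timing_profile` at `spacing` bp.
#' @export
generate_timing <- function(sim, noise_sd = 0.05, spacing = 50,
                            seed = NULL) {
  stopifnot(inherits(sim, "synthetic_genome"))
  if (is.null(seed)) seed <- sim$spec$seed + 1L
  set.seed(seed)
  half <- sim$spec$origin_spacing / 2
  parts <- lapply(names(sim$genome), function(cn) {
    len <- nchar(sim$genome[[cn]])
    x <- seq(0, len - 1, by = spacing)
    ori <- sim$origins[sim$origins$chrom == cn, ]
    rep_val <- numeric(length(x))
    for (k in seq_len(nrow(ori))) {
      rep_val <- pmax(rep_val, ori$efficiency[k] *
                        pmax(0, 1 - abs(x - ori$midpoint[k]) / half))
    }
    if (noise_sd > 0) {
      rep_val <- rep_val + rnorm(length(x), 0, noise_sd * max(ori$efficiency))
    }
    data.frame(chrom = cn, position = x, rep = rep_val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  timing_profile(out$chrom, out$position, out$rep)
}

#' Write a synthetic genome to files
#'
#' Writes the genome as FASTA, the gene models as GFF3 (1-based
#' inclusive, with `orf_classification` attributes), the true origins
#' as both BED and a TSV truth table (1-based inclusive, with
#' efficiency and status columns matching [read_origins()]), and the
#' per-position leading/lagging exposure subsampled every
#' `flag_stride` bp as TSV.
#'
#' @param sim A `synthetic_genome`.
#' @param dir Output directory (created if needed).
#' @param flag_stride Subsampling stride for the exposure table.
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic <- function(sim, dir, flag_stride = 500) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff = file.path(dir, "genes.gff3"),
             origins_bed = file.path(dir, "origins.bed"),
             origins_tsv = file.path(dir, "origins.tsv"),
             flag = file.path(dir, "f_lag.tsv"))
  ss <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(ss, paths[["fasta"]])
  gr <- GenomicRanges::GRanges(
    seqnames = sim$genes$chrom,
    ranges = IRanges::IRanges(start = sim$genes$start + 1L,
                              end = sim$genes$end),
    strand = sim$genes$strand)
  gr$type <- "gene"
  gr$ID <- sim$genes$id
  gr$orf_classification <- sim$genes$status
  rtracklayer::export(gr, paths[["gff"]], format = "gff3")
  write_bed(data.frame(chrom = sim$origins$chrom, start = sim$origins$start,
                       end = sim$origins$end,
                       name = paste0("ori", seq_len(nrow(sim$origins))),
                       score = sim$origins$efficiency,
                       strand = sim$origins$acs_strand),
            paths[["origins_bed"]])
  tsv <- sim$origins
  tsv$start <- tsv$start + 1L            # TSV convention: 1-based inclusive
  write.table(tsv, paths[["origins_tsv"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  flag <- do.call(rbind, lapply(names(sim$f_lag), function(cn) {
    i <- seq(1, length(sim$f_lag[[cn]]), by = flag_stride)
    data.frame(chrom = cn, position = i - 1, f_lag = sim$f_lag[[cn]][i])
  }))
  write.table(flag, paths[["flag"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
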