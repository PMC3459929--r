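#' Read a genome from a FASTA file
#'
#' Parses a (multi-)FASTA file into a named character vector of
#' upper-strand sequences, one element per chromosome. Sequences are
#' upper-cased and RNA-style `U` is mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of chromosome sequences, in file
#'   order. Names are the first whitespace-delimited token of each
#'   record header.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate record names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", toupper(as.character(ss)))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- nm
  seqs
}

#' Chromosome lengths of a genome
#'
#' @param genome Named character vector as returned by [read_genome()].
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  setNames(nchar(genome), names(genome))
}

#' Read gene annotation (GFF3 or tabular)
#'
#' Reads gene models with strand and curation status. Input coordinates
#' are 1-based inclusive (the GFF convention); returned intervals are
#' 0-based half-open. Only genes whose status is in `statuses` are
#' retained, which mirrors restricting an analysis to verified and
#' uncharacterized ORFs.
#'
#' @param path Path to a GFF3 file (`.gff`/`.gff3`) or a tab-separated
#'   file with columns `chrom, start, end, strand, status, id`.
#' @param statuses Character vector of statuses to retain.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @param status_attr GFF3 attribute key carrying the curation status
#'   (default `"orf_classification"`); records lacking it get status
#'   `"other"`.
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   if supplied, a gene extending past its chromosome end is an error.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `status`, `id`.
#' @export
read_annotation <- function(path,
                            statuses = c("verified", "uncharacterized"),
                            feature_type = "gene",
                            status_attr = "orf_classification",
                            chrom_lengths = NULL,
                            format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == feature_type]
    status <- if (status_attr %in% names(S4Vectors::mcols(gr)))
      as.character(S4Vectors::mcols(gr)[[status_attr]]) else
      rep(NA_character_, length(gr))
    id <- if ("ID" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$ID) else paste0("gene", seq_along(gr))
    genes <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # 1-based incl -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      status = status,
      id = id,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand", "status", "id")
    if (!all(need %in% names(tab))) {
      stop("tabular annotation must have columns: ",
           paste(need, collapse = ", "))
    }
    genes <- data.frame(
      chrom = as.character(tab$chrom),
      start = as.integer(tab$start) - 1L,
      end = as.integer(tab$end),
      strand = as.character(tab$strand),
      status = as.character(tab$status),
      id = as.character(tab$id),
      stringsAsFactors = FALSE
    )
  }
  genes$status[is.na(genes$status)] <- "other"
  genes$status[!genes$status %in% c("verified", "uncharacterized")] <- "other"
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[genes$chrom]
    bad <- which(is.na(len) | genes$end > len | genes$start < 0)
    if (length(bad)) {
      stop("gene(s) outside chromosome bounds: ",
           paste(genes$id[bad], collapse = ", "))
    }
  }
  genes <- genes[genes$status %in% statuses, , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Derive intergenes from gene annotation
#'
#' Intergenes are the intervals strictly between consecutive retained
#' translated regions on a chromosome. Overlapping gene intervals are
#' merged first, so no intergenic position lies inside any retained
#' gene; zero-length gaps (abutting genes) are omitted, and the regions
#' before the first and after the last gene are not intergenes.
#'
#' @param genes Gene `data.frame` as from [read_annotation()]
#'   (0-based half-open coordinates).
#' @param chrom_lengths Named vector of chromosome lengths (used only
#'   for validation), e.g. from [chrom_lengths()]. May be `NULL`.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `left_gene`, `right_gene`.
#' @export
derive_intergenes <- function(genes, chrom_lengths = NULL) {
  out <- lapply(split(genes, genes$chrom), function(g) {
    if (!is.null(chrom_lengths)) {
      len <- chrom_lengths[[g$chrom[1]]]
      if (!is.null(len) && any(g$end > len)) {
        stop("gene beyond end of chromosome ", g$chrom[1])
      }
    }
    ir <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
    if (length(ir) < 2L) return(NULL)
    blk_start <- IRanges::start(ir) - 1L
    blk_end <- IRanges::end(ir)
    gap_start <- blk_end[-length(blk_end)]
    gap_end <- blk_start[-1L]
    keep <- gap_end > gap_start
    if (!any(keep)) return(NULL)
    # representative flanking gene ids: rightmost-ending gene of the left
    # block, leftmost-starting gene of the right block
    left_id <- vapply(gap_start, function(gs) {
      cand <- g$id[g$end <= gs]
      cand[which.max(g$end[g$end <= gs])]
    }, character(1))
    right_id <- vapply(gap_end, function(ge) {
      cand <- g$id[g$start >= ge]
      cand[which.min(g$start[g$start >= ge])]
    }, character(1))
    data.frame(chrom = g$chrom[1], start = gap_start[keep],
               end = gap_end[keep], left_gene = left_id[keep],
               right_gene = right_id[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), left_gene = character(),
                      right_gene = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# fourfold-degenerate codon families: first two coding bases that make the
# third position fully synonymous under the standard genetic code
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' Third codon positions of a gene
#'
#' Returns the genomic coordinates of every third codon position of a
#' gene together with the base at each position read on the coding
#' strand (reverse-complemented for minus-strand genes). With
#' `fourfold_only`, only third positions of codons whose first two
#' coding-strand bases define a fourfold-degenerate family (CTn, GTn,
#' TCn, CCn, ACn, GCn, CGn, GGn) are retained.
#'
#' @param gene A single-row gene `data.frame` (0-based half-open).
#' @param chrom_seq Upper-strand sequence of the gene's chromosome.
#' @param fourfold_only Restrict to fourfold-degenerate codon families.
#' @return `data.frame` with columns `pos` (0-based genomic coordinate,
#'   strictly increasing) and `base` (coding-strand base), or a
#'   zero-row frame (with a warning) when the gene length is not a
#'   multiple of 3.
#' @export
third_codon_positions <- function(gene, chrom_seq, fourfold_only = FALSE) {
  s <- gene$start; e <- gene$end
  len <- e - s
  empty <- data.frame(pos = integer(), base = character(),
                      stringsAsFactors = FALSE)
  if (len %% 3L != 0L) {
    warning("gene ", gene$id,
            " length not divisible by 3; excluded from codon analyses")
    return(empty)
  }
  if (len == 0L) return(empty)
  coding <- substr(chrom_seq, s + 1L, e)
  if (gene$strand == "-") coding <- .revcomp(coding)
  ch <- .seq_chars(coding)
  n_codon <- len %/% 3L
  third_idx <- 3L * seq_len(n_codon)        # 1-based index into coding seq
  base <- ch[third_idx]
  if (gene$strand == "+") {
    pos <- s + third_idx - 1L
  } else {
    # codon k of a minus gene occupies genomic [e-3k, e-3k+3); its third
    # base sits at genomic position e-3k
    pos <- e - 3L * seq_len(n_codon)
  }
  if (fourfold_only) {
    pre <- paste0(ch[third_idx - 2L], ch[third_idx - 1L])
    keep <- pre %in% FOURFOLD_PREFIXES
    pos <- pos[keep]; base <- base[keep]
  }
  keep <- base %in% BASES                    # drop N and ambiguity codes
  o <- order(pos[keep])
  data.frame(pos = pos[keep][o], base = base[keep][o],
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' Writes 0-based half-open intervals (e.g. intergenes or called
#' origins) in BED format.
#'
#' @param x `data.frame` with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(x$name)) {
    cols <- c(cols, list(x$name))
    if (!is.null(x$score)) {
      cols <- c(cols, list(x$score))
      if (!is.null(x$strand)) cols <- c(cols, list(x$strand))
    }
  }
  write.table(do.call(data.frame, cols), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
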