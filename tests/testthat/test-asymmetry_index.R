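test_that("index arithmetic follows the four-segment definitions", {
  # s(1)=s(4)=0.7, s(2)=s(3)=0.3 -> coding index 0.8
  m <- seg_matrix(A = c(3, 7, 7, 3), C = c(3, 7, 7, 3),
                  G = c(7, 3, 3, 7), T = c(7, 3, 3, 7))
  ci <- coding_indices(m)
  expect_equal(unname(ci["I_GC_cod"]), 0.8)
  expect_equal(unname(ci["I_TA_cod"]), 0.8)

  # all four segment skews equal -> zero (far from origins and termini)
  m0 <- seg_matrix(A = rep(5, 4), C = rep(5, 4), G = rep(5, 4), T = rep(5, 4))
  expect_equal(unname(coding_indices(m0)), c(0, 0))

  # independently hand-computed case
  mh <- seg_matrix(A = rep(1, 4), C = c(4, 9, 11, 3),
                   G = c(12, 3, 5, 9), T = rep(1, 4))
  expect_equal(unname(coding_indices(mh)["I_GC_cod"]), 0.9375)

  # intergenic indices use segments 1 and 2 only
  mi <- seg_matrix(A = c(10, 10, 0, 0), C = c(20, 40, 0, 0),
                   G = c(30, 10, 0, 0), T = c(10, 10, 0, 0))
  ii <- intergenic_indices(mi)
  expect_equal(unname(ii["I_GC_int"]), 0.4)
  expect_equal(unname(ii["I_TA_int"]), 0)

  # direction convention flips every sign
  expect_equal(unname(coding_indices(mh, direction = skew_direction(c("G", "T")))["I_GC_cod"]),
               -0.9375)
  expect_error(skew_direction(c("A", "G")), "leading")

  # zero denominator in any segment leaves that index missing
  mz <- seg_matrix(A = c(5, 5, 5, 5), C = c(0, 5, 5, 5),
                   G = c(0, 5, 5, 5), T = c(5, 5, 5, 5))
  cz <- coding_indices(mz)
  expect_true(is.na(cz["I_GC_cod"]))
  expect_false(is.na(cz["I_TA_cod"]))
})

test_that("the global index sums defined components and tracks missing ones", {
  expect_equal(global_index(c(0.8, 0.4, 0.2, 0.1))$I_GC_TA, 1.5)
  expect_equal(global_index(c(0, 0, 0, 0))$I_GC_TA, 0)
  g <- global_index(c(NA, 0.3, 0.2, 0.1))
  expect_equal(g$I_GC_TA, 0.6)
  expect_identical(g$n_missing, 1L)
  expect_true(is.na(global_index(rep(NA_real_, 4))$I_GC_TA))
})

test_that("segment counts equal per-position brute-force assignment", {
  set.seed(21)
  for (rep in 1:8) {
    seqs <- c(c1 = random_seq(200))
    genes <- random_genes(200, 4)
    sel <- site_selection(seqs, genes = genes, class = "third_codon")
    ig <- derive_intergenes(genes, c(c1 = 200))
    x <- sample(60:140, 1); L <- 50
    got <- segment_counts(sel, "c1", x, L, 200)
    expect_identical(unclass(got)[1:4, 1:4],
                     brute_segment_counts(sel, "c1", x, L))
    if (nrow(ig) > 0) {
      seli <- site_selection(seqs, intergenes = ig, class = "intergenic")
      goti <- segment_counts(seli, "c1", x, L, 200)
      expect_identical(unclass(goti)[1:4, 1:4],
                       brute_segment_counts(seli, "c1", x, L))
      expect_true(all(goti[3:4, ] == 0))
    }
  }
  # position too close to an end is refused
  seqs <- c(c1 = random_seq(200))
  genes <- random_genes(200, 3)
  sel <- site_selection(seqs, genes = genes, class = "third_codon")
  expect_error(segment_counts(sel, "c1", 10, 50, 200), "closer than L")
})

test_that("coding indices are invariant under reverse complement with strand swap", {
  set.seed(31)
  for (rep in 1:5) {
    len <- 240
    seqs <- c(c1 = random_seq(len))
    genes <- random_genes(len, 4)
    sel <- site_selection(seqs, genes = genes, class = "third_codon")
    rc <- c(c1 = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqs[["c1"]]))))
    genes_rc <- data.frame(chrom = "c1", start = len - genes$end,
                           end = len - genes$start,
                           strand = ifelse(genes$strand == "+", "-", "+"),
                           status = genes$status, id = genes$id,
                           stringsAsFactors = FALSE)
    sel_rc <- site_selection(rc, genes = genes_rc, class = "third_codon")
    x <- 120; L <- 60
    a <- coding_indices(segment_counts(sel, "c1", x, L, len))
    b <- coding_indices(segment_counts(sel_rc, "c1", len - x, L, len))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("intergene scoring picks evaluation points by length", {
  grid <- skewori:::.intergene_eval_positions
  expect_identical(grid(0, 1200), 600)                 # single midpoint
  expect_identical(grid(1000, 4500), c(1750, 2750, 3750))
  expect_true(length(grid(0, 1500)) >= 1)              # multi-point branch
  expect_identical(grid(0, 1500), 750)                 # only midpoint inside

  sim <- small_sim()
  cl <- chrom_lengths(sim$genome)
  selC <- site_selection(sim$genome, genes = sim$genes, class = "third_codon")
  selI <- site_selection(sim$genome, intergenes = sim$intergenes,
                         class = "intergenic")
  ig <- sim$intergenes[1:25, ]
  sc <- intergene_score(ig, selC, selI, cl, L = 20000)
  expect_identical(nrow(sc), 25L)
  # intergenes within L of the chromosome start are excluded with a reason
  near_start <- sc$end <= 20000
  expect_true(all(is.na(sc$score[near_start])))
  expect_true(all(sc$excluded[near_start] == "no valid evaluation position"))
  ok <- !is.na(sc$score)
  expect_true(any(ok))
  # the score is the chosen index at the best evaluated position
  expect_equal(sc$score[ok], sc$I_GC_TA[ok])
})

test_that("index profiles peak at origins and dip at termination midpoints", {
  spec <- synthetic_spec(chromosome_length = 800000, replication_skew = 0.3,
                         seed = 9)
  sim <- generate_genome(spec)
  cl <- chrom_lengths(sim$genome)
  selC <- site_selection(sim$genome, genes = sim$genes, class = "third_codon")
  selI <- site_selection(sim$genome, intergenes = sim$intergenes,
                         class = "intergenic")
  anchors <- data.frame(chrom = sim$origins$chrom, pos = sim$origins$midpoint)
  ap <- anchor_index_profile(selC, selI, anchors, cl, half_span = 10000,
                             L = 10000, step = 500)
  peak <- ap$offset[which.max(ap$I_GC_cod)]
  expect_lte(abs(peak), 500)
  expect_gt(max(ap$I_GC_cod), 0.4)     # ~2 * s_rep at a fully efficient origin

  # termination midpoints: troughs of the same depth, negative sign
  term <- data.frame(chrom = "chr1",
                     pos = head(sim$origins$midpoint, -1) + 20000)
  tp <- anchor_index_profile(selC, selI, term, cl, half_span = 5000,
                             L = 10000, step = 500)
  expect_lt(tp$I_GC_cod[tp$offset == 0], -0.4)
})

test_that("coding indices are centred on zero without replication skew", {
  spec <- synthetic_spec(chromosome_length = 400000, replication_skew = 0,
                         transcription_skew = 0.1, seed = 13)
  sim <- generate_genome(spec)
  cl <- chrom_lengths(sim$genome)
  selC <- site_selection(sim$genome, genes = sim$genes, class = "third_codon")
  selI <- site_selection(sim$genome, intergenes = sim$intergenes,
                         class = "intergenic")
  prof5 <- index_profile(selC, selI, cl, L = 5000, step = 2000)
  prof20 <- index_profile(selC, selI, cl, L = 20000, step = 2000)
  expect_lt(abs(mean(prof20$I_GC_cod, na.rm = TRUE)), 0.02)
  expect_lt(abs(mean(prof20$I_TA_cod, na.rm = TRUE)), 0.02)
  # fluctuations shrink as L grows
  expect_lt(sd(prof20$I_GC_cod, na.rm = TRUE), sd(prof5$I_GC_cod, na.rm = TRUE))
})

test_that("index magnitude at origins rises with origin efficiency", {
  effs <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  means <- vapply(seq_along(effs), function(i) {
    spec <- synthetic_spec(chromosome_length = 2000000,
                           origin_efficiencies = effs[i],
                           transcription_skew = 0, seed = 40 + i)
    sim <- generate_genome(spec)
    cl <- chrom_lengths(sim$genome)
    selC <- site_selection(sim$genome, genes = sim$genes,
                           class = "third_codon")
    anchors <- data.frame(chrom = sim$origins$chrom,
                          pos = sim$origins$midpoint)
    ap <- anchor_index_profile(selC, NULL, anchors, cl, half_span = 0,
                               L = 10000, step = 500)
    ap$I_GC_cod[1]
  }, numeric(1))
  expect_gt(cor(means, effs, method = "spearman"), 0.9)
})
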