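test_that("colocalization uses overlap or midpoint distance under 10 kb", {
  a <- data.frame(chrom = "c1", start = c(1000, 50000, 100000),
                  end = c(2000, 51000, 101000))
  a$midpoint <- floor((a$start + a$end) / 2)
  # disjoint but 9 kb apart -> matched; exactly 10 kb -> not matched;
  # overlapping with distant midpoints -> matched
  b <- data.frame(chrom = "c1",
                  start = c(10000, 60500, 100500),
                  end = c(11000, 61500, 131500))
  b$midpoint <- c(10500, 60500, 116000)
  m <- colocalize(a, b)
  expect_identical(m$a, c(1L, 3L))
  expect_identical(m$b, c(1L, 3L))

  # one-to-one resolution by smallest midpoint distance
  a2 <- data.frame(chrom = "c1", start = c(0, 6200), end = c(1000, 7200))
  b2 <- data.frame(chrom = "c1", start = 3000, end = 4000)
  m2 <- colocalize(a2, b2)
  expect_identical(nrow(m2), 1L)
  expect_identical(m2$a, 1L)  # midpoint 500 is 3000 from 3500, 6700 is 3200
})

test_that("intergene labelling follows half-open interval overlap", {
  ig <- data.frame(chrom = "c1", start = c(200, 300, 600),
                   end = c(300, 400, 700))
  ori <- data.frame(chrom = "c1", start = c(250), end = c(400))
  expect_identical(label_intergenes(ig, ori), c(1L, 1L, 0L))
  # abutting half-open intervals do not overlap
  ori2 <- data.frame(chrom = "c1", start = 300, end = 400)
  expect_identical(label_intergenes(ig, ori2), c(0L, 1L, 0L))
})

test_that("ROC construction handles perfect, tied and mixed rankings", {
  expect_equal(roc(c(4, 3, 2, 1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  r <- roc(c(4, 3, 2, 1), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_identical(r$n_pos, 2L)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  expect_equal(tail(r$tpr, 1), 1)
  expect_error(roc(1:4, c(1, 1, 1, 1)), "both classes")
  # missing scores are excluded and counted
  expect_identical(roc(c(4, NA, 2, 1, 0), c(1, 1, 0, 1, 0))$n_missing, 1L)
})

test_that("trapezoid AUC equals the concordance-pair oracle", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n, mean = labels), sample(0:2, 1))  # induce ties
    expect_equal(roc(scores, labels)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("rank statistics are invariant under increasing transforms", {
  set.seed(19)
  labels <- rbinom(80, 1, 0.4)
  scores <- rnorm(80) + labels
  trans <- function(x) exp(2 * x) + 1
  expect_equal(roc(trans(scores), labels)$auc, roc(scores, labels)$auc)
  expect_equal(correlate(trans(scores), seq_along(scores))$rho,
               correlate(scores, seq_along(scores))$rho)
  k <- 15
  top1 <- order(scores, decreasing = TRUE)[1:k]
  top2 <- order(trans(scores), decreasing = TRUE)[1:k]
  expect_identical(sort(top1), sort(top2))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  labels <- rbinom(150, 1, 0.3)
  scores <- rnorm(150) + 0.8 * labels
  ours <- roc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("top-rank enrichment uses the exact binomial tail", {
  res <- topk_enrichment(scores = seq(300, 1), labels = rep(0:1, 150),
                         k = 200, prevalence = 0.046)
  expect_equal(res$expected, 9.2)
  # expected counts for k = 100, 200, 300 round to 5, 9, 14
  expect_identical(round(c(100, 200, 300) * 0.046), c(5, 9, 14))

  # all top-20 positive at prevalence 0.5: closed-form tail 0.5^20
  scores <- seq(40, 1); labels <- c(rep(1, 20), rep(0, 20))
  res2 <- topk_enrichment(scores, labels, k = 20, prevalence = 0.5)
  expect_identical(res2$observed, 20L)
  expect_equal(res2$p_value, 0.5^20, tolerance = 1e-12)

  # observation at the expectation carries no evidence
  set.seed(5)
  lab <- c(rep(1, 5), rep(0, 95))
  res3 <- topk_enrichment(seq(100, 1), lab, k = 100, prevalence = 0.05,
                          alternative = "two.sided")
  expect_gt(res3$p_value, 0.99)

  expect_error(topk_enrichment(1:10, rep(0:1, 5), k = 0), "positive count")
  expect_error(topk_enrichment(1:10, rep(0:1, 5), k = 11), "exceeds")
})

test_that("logistic combination recovers known coefficients", {
  set.seed(29)
  n <- 2000
  X <- data.frame(I_GC_cod = rnorm(n, 0, 0.1), I_TA_cod = rnorm(n, 0, 0.1),
                  I_GC_int = rnorm(n, 0, 0.1), I_TA_int = rnorm(n, 0, 0.1))
  beta <- c(19, 18, 11, 13); intercept <- -4
  eta <- intercept + as.matrix(X) %*% beta
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(X, y)
  expect_true(fit$converged)
  expect_false(fit$separation)
  est <- fit$coefficients[-1]; se <- fit$se[-1]
  expect_true(all(abs(est - beta) < 2 * se))

  # labels independent of the indices: slopes within 2 SE of zero
  y0 <- rbinom(n, 1, 0.3)
  fit0 <- fit_logistic(X, y0)
  expect_true(all(abs(fit0$coefficients[-1]) < 2.5 * fit0$se[-1]))

  # a constant column is reported as unidentifiable
  Xc <- X; Xc$I_TA_int <- 0.2
  fitc <- fit_logistic(Xc, y)
  expect_true("I_TA_int" %in% fitc$aliased)

  expect_error(fit_logistic(X[1:30, ], y[1:30]), "at least 50")
})

test_that("logistic fit flags complete separation", {
  set.seed(31)
  X <- data.frame(I_GC_cod = c(rnorm(40, -2, 0.1), rnorm(40, 2, 0.1)),
                  I_TA_cod = rnorm(80), I_GC_int = rnorm(80),
                  I_TA_int = rnorm(80))
  y <- rep(c(0, 1), each = 40)
  fit <- fit_logistic(X, y)
  expect_true(fit$separation)
})

test_that("Spearman correlation handles monotone and hand-checked cases", {
  expect_equal(correlate(1:12, (1:12)^2)$rho, 1)
  expect_equal(correlate(1:12, -(1:12))$rho, -1)
  # frozen value from the hand rank formula: squared rank differences all
  # 1 for adjacent swaps -> rho = 1 - 6*10/(10*99)
  x <- 1:10; y <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  expect_equal(correlate(x, y)$rho, 1 - 60 / 990)
  expect_error(correlate(1:5, 5:1), "at least 10")
})

test_that("group comparison reports rank-sum p and medians", {
  expect_equal(group_compare(rep(1, 5), rep(1, 8))$p_value, 1)
  res <- group_compare(rnorm(20) + 100, rnorm(20))
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$median_a, res$median_b)
  # power at a one-SD shift, n = 100 per group
  set.seed(37)
  hits <- vapply(1:20, function(i) {
    group_compare(rnorm(100) + 1, rnorm(100))$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(group_compare(1:2, 1:5))
})

test_that("global index discriminates better than single components end-to-end", {
  pipeline_aucs <- function(effs, seed) {
    spec <- synthetic_spec(chromosome_length = 1200000,
                           origin_efficiencies = effs,
                           snap_origins_to_intergenes = TRUE, seed = seed)
    sim <- generate_genome(spec)
    cl <- chrom_lengths(sim$genome)
    selC <- site_selection(sim$genome, genes = sim$genes,
                           class = "third_codon")
    selI <- site_selection(sim$genome, intergenes = sim$intergenes,
                           class = "intergenic")
    sc <- intergene_score(sim$intergenes, selC, selI, cl, L = 20000)
    labels <- label_intergenes(sim$intergenes, sim$origins)
    ok <- !is.na(sc$score)
    vapply(c("I_GC_TA", "I_GC_cod", "I_TA_cod", "I_GC_int", "I_TA_int"),
           function(col) roc(sc[[col]][ok], labels[ok])$auc, numeric(1))
  }
  # efficient origins: the combination's sampling-noise advantage resolves
  # and the global index tops every single component in most replicates
  wins <- 0L
  for (s in 402:404) {
    a <- pipeline_aucs(1, s)
    expect_gt(a[["I_GC_TA"]], 0.9)
    if (a[["I_GC_TA"]] >= max(a[-1])) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
  # mixed efficiencies add origin-usage fluctuations shared by all four
  # components; the global index still at least matches their average
  am <- pipeline_aucs(c(0.4, 1), 405)
  expect_gt(am[["I_GC_TA"]], 0.6)
  expect_gte(am[["I_GC_TA"]], mean(am[-1]))
})

test_that("origin tables round-trip through TSV and BED readers", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstatus\tactive\tefficiency",
               "c1\t101\t300\tconfirmed\tTRUE\t0.8",
               "c1\t1001\t1200\tlikely\tFALSE\t0.2"), tsv)
  ori <- read_origins(tsv)
  expect_identical(ori$start, c(100L, 1000L))
  expect_identical(ori$midpoint[1], 200L)
  expect_identical(ori$status, c("confirmed", "likely"))

  bed <- tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t300\tori1\t0\t+", "c1\t1000\t1200\tori2\t0\t-"), bed)
  orib <- read_origins(bed)
  expect_identical(orib$start, c(100L, 1000L))
  expect_identical(orib$acs_strand, c("+", "-"))
})
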