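test_that("consensus voting uses a strict greater-than rule", {
  cm <- matrix(FALSE, 3, 100, dimnames = list(c("a", "b", "c"), NULL))
  cm["a", 1:11] <- TRUE   # 11% of runs -> discarded
  cm["b", 1:10] <- TRUE   # exactly 10% -> kept
  kept <- consensus_doublet_filter(cm, vote_fraction = 0.10)
  expect_setequal(kept, c("b", "c"))
  expect_setequal(consensus_doublet_filter(matrix(FALSE, 4, 5,
    dimnames = list(letters[1:4], NULL))), letters[1:4])
  expect_error(consensus_doublet_filter(matrix(logical(), 3, 0)), "run")
})

test_that("consensus voting equals a brute-force count on random matrices", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1); runs <- sample(3:30, 1)
    cm <- matrix(runif(n * runs) < 0.2, n, runs,
                 dimnames = list(sprintf("c%02d", 1:n), NULL))
    vf <- runif(1, 0.05, 0.4)
    brute <- rownames(cm)[vapply(seq_len(n), function(i)
      sum(cm[i, ]) / runs <= vf, TRUE)]
    expect_identical(consensus_doublet_filter(cm, vf), brute)
  }
})

test_that("basic count filter keeps cells sitting exactly on the bounds", {
  genes <- c("MT-1", "G1", "G2")
  counts <- rbind(
    c(0, 499, 0),      # 499 UMIs -> removed ("less than 500")
    c(0, 498, 2),      # exactly 500 UMIs, 2 genes -> kept
    c(50, 450, 0),     # exactly 10% mito -> kept
    c(51, 449, 0))     # 10.2% mito -> removed
  cm <- count_matrix(counts, sprintf("c%d", 1:4), genes,
                     data.frame(sample_id = "s", region = "CN",
                                cells = 1:4)[, 1:2])
  t <- qc_thresholds(min_genes = 2, max_genes = 10)
  expect_setequal(basic_count_filter(cm, t), c("c2", "c3"))
})

test_that("gene-UMI polynomial recovers an exact quadratic relation", {
  # cells constructed so that log(n_genes) = 0.5 * log(n_umis) exactly
  gs <- 10:40
  n_genes_univ <- 50
  rows <- lapply(gs, function(g) {
    x <- numeric(n_genes_univ)
    x[seq_len(g - 1)] <- 1
    x[g] <- g^2 - (g - 1)
    x
  })
  cm <- count_matrix(do.call(rbind, rows), sprintf("c%d", gs),
                     sprintf("G%02d", 1:n_genes_univ),
                     data.frame(sample_id = "s", region = "CN",
                                i = gs)[, 1:2])
  co <- fit_gene_umi_polynomial(cm)
  expect_equal(co, c(0, 0.5, 0), tolerance = 1e-8)
  # permutation invariance
  perm <- sample(length(gs))
  cm2 <- subset_cells(cm, cm$cell_ids[perm])
  expect_equal(fit_gene_umi_polynomial(cm2), co, tolerance = 1e-10)
})

test_that("polynomial outliers are judged in gene-count units", {
  # constant prediction of 5000 genes
  coeffs <- c(log(5000), 0, 0)
  mk_cell <- function(g) {
    x <- integer(8000); x[seq_len(g)] <- 1L; x
  }
  cm <- count_matrix(rbind(mk_cell(7100), mk_cell(6900), mk_cell(5000)),
                     c("far", "near", "exact"), sprintf("G%04d", 1:8000),
                     data.frame(sample_id = "s", region = "CN",
                                i = 1:3)[, 1:2])
  kept <- polynomial_outlier_filter(cm, coeffs, delta = 2000)
  expect_setequal(kept, c("near", "exact"))   # |7100-5000| > 2000 removed
})

test_that("marker scores are panel means with missing markers dropped", {
  mat <- matrix(0, 3, 4, dimnames = list(
    c("z", "one", "two"), c("AQP4", "ADGRV1", "MEG3", "Gx")))
  mat["one", "MEG3"] <- 1.7
  mat["two", c("AQP4", "ADGRV1")] <- c(2, 4)
  norm <- fake_norm(mat)
  panel <- list(astrocytes = c("AQP4", "ADGRV1"), neurons = "MEG3")
  sc <- marker_score(norm, panel)
  expect_equal(sc["z", ], c(astrocytes = 0, neurons = 0))
  expect_equal(sc["one", "neurons"], 1.7)
  expect_equal(sc["two", "astrocytes"], 3)
  # permutation of the marker list does not change the score
  sc2 <- marker_score(norm, list(astrocytes = c("ADGRV1", "AQP4"),
                                 neurons = "MEG3"))
  expect_equal(sc2, sc[, colnames(sc2)])
  expect_warning(marker_score(norm, list(neurons = c("MEG3", "NOPE"))),
                 "missing")
  expect_error(suppressWarnings(marker_score(norm, list(ghost = "NOPE2"))),
               "ghost")
})

test_that("mixture threshold recovers mu_low + 4 sigma_low", {
  set.seed(1)
  scores <- c(rnorm(4500, 1, 0.2), rnorm(500, 6, 0.5))
  th <- mixture_threshold(scores)
  expect_false(th$fallback)
  expect_gt(th$threshold, 1.6)
  expect_lt(th$threshold, 2.2)
  expect_lt(abs(th$mu_low - 1), 0.1)
  expect_lt(abs(th$sigma_low - 0.2), 0.02)
  expect_lte(th$mu_low, th$mu_high)
})

test_that("mixture threshold parameter recovery within 10% at 4-sigma separation", {
  set.seed(2)
  mu1 <- 2; s1 <- 0.5; mu2 <- mu1 + 5 * s1
  scores <- c(rnorm(4000, mu1, s1), rnorm(1000, mu2, 0.4))
  th <- mixture_threshold(scores)
  expect_lt(abs(th$mu_low / mu1 - 1), 0.1)
  expect_lt(abs(th$sigma_low / s1 - 1), 0.1)
})

test_that("degenerate score distributions fall back gracefully", {
  th <- mixture_threshold(rep(2.5, 200))
  expect_true(th$fallback)
  expect_equal(th$threshold, 2.5)
})

test_that("multi-identity filter excludes cells above several thresholds", {
  sc <- rbind(both = c(astro = 5, micro = 5), one = c(2, 0), none = c(0, 0))
  colnames(sc) <- c("astro", "micro")
  thr <- list(astro = list(threshold = 1), micro = list(threshold = 1))
  out <- multi_identity_doublet_filter(sc, thr)
  expect_setequal(out$kept, c("one", "none"))
  expect_equal(unname(out$type["one"]), "astro")
  expect_equal(unname(out$type["none"]), "none")
})

test_that("regional marker filter removes any detection by default", {
  mat <- matrix(0, 3, 5, dimnames = list(
    c("contaminated", "clean", "high"),
    c("NEUROD2", "TMEM155", "CARTPT", "SLC17A7", "G1")))
  mat["contaminated", "SLC17A7"] <- 2.1
  mat["high", "G1"] <- 9
  norm <- fake_norm(mat)
  expect_setequal(regional_marker_filter(norm), c("clean", "high"))
  expect_setequal(regional_marker_filter(norm, min_expr = Inf),
                  rownames(mat))
})

test_that("doublet scorer is deterministic and skips tiny samples", {
  d <- generate_dataset(two_pop_config(seed = 31, n_cells = 120))
  c1 <- run_doublet_scorer(d$counts, n_runs = 3, seed = 5)
  c2 <- run_doublet_scorer(d$counts, n_runs = 3, seed = 5)
  expect_identical(c1, c2)
  small <- subset_cells(d$counts, d$counts$cell_ids[1:20])
  expect_warning(calls <- run_doublet_scorer(small, n_runs = 2, seed = 1),
                 "fewer than")
  expect_false(any(calls))
})

test_that("the QC cascade is monotone and its funnel conserves cells", {
  cfg <- default_qc_config(seed = 3, n_cells_per_sample = 150,
                           doublet_rate = 0.05)
  cfg$samples <- cfg$samples[1:2, ]
  d <- generate_dataset(cfg)
  qc <- qc_cascade(d$counts, qc_thresholds(n_doublet_runs = 5), seed = 2)
  f <- qc$funnel
  expect_true(all(f$cells_removed >= 0))
  expect_equal(f$cells_in[-1], (f$cells_in - f$cells_removed)[-nrow(f)])
  expect_equal(nrow(d$counts$counts) - sum(f$cells_removed),
               length(qc$kept))
  expect_true(all(qc$kept %in% d$counts$cell_ids))
})
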