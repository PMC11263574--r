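test_that("pseudobulk aggregation sums counts and enforces min_cells", {
  counts <- rbind(c(1, 2), c(3, 4), c(5, 6))
  cm <- count_matrix(counts, c("c1", "c2", "c3"), c("g1", "g2"),
                     data.frame(sample_id = c("s1", "s1", "s2"),
                                region = c("CN", "CN", "Pu"),
                                i = 1:3)[, 1:2])
  labels <- stats::setNames(rep("A", 3), c("c1", "c2", "c3"))
  pb <- aggregate_pseudobulk(cm, labels, min_cells = 1)
  grp <- pb$meta$sample_id == "s1"
  expect_equal(unname(pb$counts[grp, ]), c(4, 6))
  expect_equal(sum(pb$counts), sum(counts))
  pb2 <- aggregate_pseudobulk(cm, labels, min_cells = 2)
  expect_equal(nrow(pb2$counts), 1)  # the 1-cell s2 group is dropped
})

test_that("DEG selection applies strict thresholds", {
  res <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    log2_fold = c(0.6, 0.6, 0.5, -0.8, -0.3),
                    p_adj = c(0.01, 0.06, 0.01, 0.01, 0.01))
  degs <- select_degs(res)
  expect_identical(degs$up, "a")      # b fails alpha, c fails strict > 0.5
  expect_identical(degs$down, "d")
})

test_that("hypergeometric ORA matches exact enumeration", {
  # worked example: universe 100, term 10, list 10, overlap 5
  universe <- sprintf("u%03d", 1:100)
  term <- universe[1:10]
  deg <- c(universe[1:5], universe[90:94])
  coll <- list(sets = list(T1 = term), universe = universe)
  res <- ora_hypergeometric(deg, coll)
  exact <- sum(vapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k), 0)) / choose(100, 10)
  expect_equal(res$p, exact, tolerance = 1e-12)
  expect_equal(res$p, 6.35e-4, tolerance = 2e-2)
  # enumeration oracle over random small cases (N <= 60)
  set.seed(6)
  for (rep in 1:25) {
    N <- sample(10:60, 1)
    uni <- sprintf("g%02d", seq_len(N))
    K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    tset <- sample(uni, K); dl <- sample(uni, n)
    ov <- length(intersect(tset, dl))
    res <- ora_hypergeometric(dl, list(sets = list(t = tset), universe = uni))
    brute <- sum(vapply(ov:min(K, n), function(k)
      choose(K, k) * choose(N - K, n - k), 0)) / choose(N, n)
    expect_equal(res$p, brute, tolerance = 1e-10)
  }
})

test_that("ORA edge cases: disjoint term, saturated list, empty list", {
  uni <- sprintf("g%02d", 1:40)
  coll <- list(sets = list(t = uni[1:8]), universe = uni)
  disj <- ora_hypergeometric(uni[30:39], coll)
  expect_equal(disj$p, 1, tolerance = 1e-12)
  expect_false(disj$selected)
  sat <- ora_hypergeometric(uni, coll)
  expect_equal(sat$overlap, 8)
  expect_equal(sat$p, 1, tolerance = 1e-12)
  empty <- ora_hypergeometric(character(), coll)
  expect_equal(nrow(empty), 0)
  expect_warning(ora_hypergeometric(c(uni[1], "NOT_A_GENE"), coll), "dropped")
})

test_that("BH adjustment equals the textbook step-up", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:1000, 1)
    p <- runif(n)^sample(1:3, 1)
    ours <- stats::p.adjust(p, "BH")
    o <- order(p)
    stepup <- numeric(n)
    stepup[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
    stepup <- pmin(stepup, 1)
    expect_equal(ours, stepup, tolerance = 1e-12)
  }
})

test_that("NB GLM LRT finds a strong planted fold and skips zero genes", {
  set.seed(9)
  n_s <- 12; n_g <- 60
  lib <- rep(1e5, n_s)
  region <- rep(c("CN", "Pu"), each = n_s / 2)
  mu <- matrix(rep(rgamma(n_g, 2, scale = 20), each = n_s), n_s, n_g)
  mu[region == "CN", 1:5] <- mu[region == "CN", 1:5] * 2^1.5
  cnt <- matrix(rnbinom(n_s * n_g, mu = mu, size = 8), n_s, n_g)
  cnt[, n_g] <- 0   # all-zero gene
  colnames(cnt) <- sprintf("g%02d", seq_len(n_g))
  rownames(cnt) <- sprintf("s%02d", seq_len(n_s))
  pb <- list(counts = cnt,
             meta = data.frame(class = "A", sample_id = rownames(cnt),
                               region = region, n_cells = 50))
  res <- nb_glm_lrt(pb)
  expect_false(sprintf("g%02d", n_g) %in% res$gene)
  degs <- select_degs(res)
  expect_gte(length(intersect(degs$up, sprintf("g%02d", 1:5))), 4)
  expect_lte(length(setdiff(degs$up, sprintf("g%02d", 1:5))), 1)
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
})

test_that("LRT p-values track edgeR's on a common dataset", {
  skip_if_not_installed("edgeR")
  set.seed(10)
  n_s <- 12; n_g <- 150
  region <- rep(c("CN", "Pu"), each = n_s / 2)
  mu <- matrix(rep(rgamma(n_g, 2, scale = 30), each = n_s), n_s, n_g)
  mu[region == "CN", 1:15] <- mu[region == "CN", 1:15] * 2.5
  cnt <- matrix(rnbinom(n_s * n_g, mu = mu, size = 10), n_s, n_g,
                dimnames = list(sprintf("s%02d", 1:n_s),
                                sprintf("g%03d", 1:n_g)))
  pb <- list(counts = cnt,
             meta = data.frame(class = "A", sample_id = rownames(cnt),
                               region = region, n_cells = 50))
  res <- nb_glm_lrt(pb)
  y <- edgeR::DGEList(counts = t(cnt))
  y <- edgeR::calcNormFactors(y, method = "none")
  design <- stats::model.matrix(~ factor(region, levels = c("Pu", "CN")))
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmFit(y, design)
  lrt <- edgeR::glmLRT(fit)
  ref_p <- lrt$table[res$gene, "PValue"]
  expect_gt(stats::cor(-log10(res$p), -log10(ref_p)), 0.85)
  ref_lfc <- lrt$table[res$gene, "logFC"]
  expect_gt(stats::cor(res$log2_fold, ref_lfc), 0.98)
})

test_that("GMT gene sets round-trip", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tg1\tg2\tg3", "T2\tdesc\tg2\tg9"), path)
  coll <- read_gmt(path, universe = c("g1", "g2", "g3", "g4"))
  expect_equal(coll$sets$T1, c("g1", "g2", "g3"))
  res <- ora_hypergeometric(c("g1", "g2"), coll)
  expect_equal(res$term_size[res$term == "T2"], 1)  # g9 outside universe
})
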