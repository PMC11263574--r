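test_that("normalization matches its closed form and is scale invariant", {
  counts <- rbind(c(100, 0, 0), c(4, 6, 0), c(8, 12, 0))
  cm <- count_matrix(counts, c("solo", "a", "a2x"), c("G1", "G2", "G3"),
                     data.frame(sample_id = "s", region = "CN", i = 1:3)[, 1:2])
  norm <- normalize_log(cm)
  expect_equal(norm$mat["solo", "G1"], log1p(10000))
  expect_equal(norm$mat["solo", "G2"], 0)
  # doubling all counts of a cell leaves the normalized vector unchanged
  expect_equal(as.numeric(norm$mat["a", ]), as.numeric(norm$mat["a2x", ]))
  zero <- count_matrix(rbind(c(1, 1, 1), c(0, 0, 0)), c("ok", "empty"),
                       c("G1", "G2", "G3"),
                       data.frame(sample_id = "s", region = "CN", i = 1:2)[, 1:2])
  expect_error(normalize_log(zero), "empty")
})

test_that("HVG selection drops constant genes and flagged categories", {
  set.seed(8)
  n <- 200
  mat <- cbind(const = rep(1, n),
               flat = rnorm(n, 5, 0.01),
               noisy1 = rexp(n, 1 / 2),
               noisy2 = rexp(n, 1 / 2),
               `MT-x` = rexp(n, 1 / 5),
               RPL1 = rexp(n, 1 / 5),
               XIST = rexp(n, 1 / 5))
  mat <- pmax(mat, 0)
  norm <- fake_norm(mat)
  top <- select_hvg(norm, n = 2, n_bins = 2)
  expect_false("const" %in% top)
  expect_false(any(c("MT-x", "RPL1", "XIST") %in% top))
  all4 <- select_hvg(norm, n = 4, n_bins = 2)
  expect_setequal(all4, c("flat", "noisy1", "noisy2", "const"))
  expect_error(select_hvg(norm, n = 5), "eligible")
})

test_that("two well-separated populations cluster perfectly at resolution 0.2", {
  d <- generate_dataset(two_pop_config(seed = 17, n_cells = 200))
  norm <- normalize_log(d$counts)
  hv <- select_hvg(norm, n = 100)
  lab <- embed_cluster(norm, hv, n_pcs = 10, resolution = 0.2, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(mclust::adjustedRandIndex(
    lab, d$truth$population[match(names(lab), d$truth$cell_id)]), 1)
  lab2 <- embed_cluster(norm, hv, n_pcs = 10, resolution = 0.2, seed = 1)
  expect_identical(lab, lab2)
})

test_that("clusters are labeled by their best marker panel with a margin", {
  mat <- matrix(0, 6, 4,
                dimnames = list(sprintf("c%d", 1:6),
                                c("AQP4", "ADGRV1", "MEG3", "G1")))
  mat[1:2, c("AQP4", "ADGRV1")] <- 3       # astrocyte cluster
  mat[3:4, "MEG3"] <- 2                    # neuron cluster
  norm <- fake_norm(mat)
  labels <- stats::setNames(c(1L, 1L, 2L, 2L, 3L, 3L), rownames(mat))
  out <- label_clusters_by_markers(norm, labels,
                                   panel = list(astrocytes = c("AQP4", "ADGRV1"),
                                                neurons = "MEG3"))
  expect_equal(unname(out[c("1", "2", "3")]),
               c("astrocytes", "neurons", "unassigned"))
})

test_that("neuron refilter keeps boundary cells and ignores non-neurons", {
  mk <- function(n_genes_detected, extra = 0) {
    x <- integer(13000)
    x[seq_len(n_genes_detected)] <- 1L
    x[1] <- x[1] + extra
    x
  }
  counts <- rbind(low_umi = mk(3000, extra = 4999 - 3000),    # 4999 UMIs
                  ok = mk(3000, extra = 5000 - 3000),         # 5000 UMIs
                  many_genes = mk(12000))                     # exactly 12000
  cm <- count_matrix(counts, rownames(counts), sprintf("G%05d", 1:13000),
                     data.frame(sample_id = "s", region = "CN", i = 1:3)[, 1:2])
  kept <- neuron_quality_refilter(cm, c("low_umi", "ok", "many_genes"))
  expect_setequal(kept, c("ok", "many_genes"))
  # cells not passed in are never judged
  kept2 <- neuron_quality_refilter(cm, c("ok"))
  expect_identical(kept2, "ok")
})

test_that("interneuron gating follows the and/or marker rules", {
  genes <- c("GAD1", "GAD2", "CHAT", "PPP1R1B", "DRD1", "DRD2",
             "MEIS2", "RORB", "G1")
  mat <- matrix(0, 6, length(genes),
                dimnames = list(sprintf("c%d", 1:6), genes))
  mat[1:2, "GAD1"] <- 2                       # inhibitory, clean
  mat[3:4, c("GAD1", "PPP1R1B")] <- 2         # inhibitory but MSN
  mat[5:6, "CHAT"] <- 2                       # cholinergic only
  norm <- fake_norm(mat)
  labels <- stats::setNames(rep(1:3, each = 2), rownames(mat))
  out <- select_interneurons(norm, labels)
  expect_setequal(out, c("c1", "c2", "c5", "c6"))
})

test_that("Wilcoxon marker ranking matches wilcox.test on small instances", {
  set.seed(20)
  n <- 40
  mat <- matrix(rpois(n * 15, 3) + rep(c(0, 2), each = n / 2), n, 15)
  colnames(mat) <- sprintf("g%02d", 1:15)
  rownames(mat) <- sprintf("c%02d", 1:n)
  norm <- fake_norm(log1p(mat))
  labels <- stats::setNames(rep(c("A", "B"), each = n / 2), rownames(mat))
  res <- rank_marker_genes(norm, labels)
  for (g in c("g01", "g07", "g15")) {
    x <- log1p(mat[labels == "A", g]); y <- log1p(mat[labels == "B", g])
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    got <- res[res$group == "A" & res$gene == g, ]
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(rank_marker_genes(norm, stats::setNames(rep("A", n),
                                                       rownames(mat))),
               "two groups")
})

test_that("permuted labels give a near-uniform adjusted-p distribution", {
  set.seed(33)
  n <- 100
  mat <- matrix(rpois(n * 200, 4), n, 200)
  rownames(mat) <- sprintf("c%03d", 1:n)
  norm <- fake_norm(log1p(mat))
  labels <- stats::setNames(sample(rep(c("A", "B"), each = n / 2)),
                            rownames(mat))
  res <- rank_marker_genes(norm, labels)
  frac_sig <- mean(res$p[res$group == "A"] < 0.05)
  expect_lte(frac_sig, 0.07)
})

test_that("merging respects the strict r > 0.49 rule", {
  # construct mean profiles with exact correlations via orthonormal parts
  p <- 200
  z1 <- scale(rnorm(p)); z2 <- scale(stats::resid(lm(rnorm(p) ~ z1)))
  mk <- function(r) r * z1 + sqrt(1 - r^2) * z2
  build_norm <- function(r) {
    prof <- cbind(a = as.numeric(z1), b = as.numeric(mk(r)))
    mat <- t(prof[, c("a", "a", "b", "b")]) + 5
    rownames(mat) <- sprintf("c%d", 1:4)
    colnames(mat) <- sprintf("g%03d", seq_len(p))
    fake_norm(pmax(mat, 0))
  }
  labels <- stats::setNames(c(1L, 1L, 2L, 2L), sprintf("c%d", 1:4))
  hi <- merge_subclasses(build_norm(0.70), labels, r_threshold = 0.49)
  expect_equal(length(unique(hi$class_of)), 1)
  lo <- merge_subclasses(build_norm(0.10), labels, r_threshold = 0.49)
  expect_equal(length(unique(lo$class_of)), 2)
})

test_that("component merging equals a brute-force reachability oracle", {
  set.seed(55)
  for (rep in 1:10) {
    k <- sample(4:10, 1)
    prof <- matrix(rnorm(k * 60), 60, k) +
      matrix(rnorm(60), 60, k) * sample(0:1, 1) * 1.5
    mat <- t(prof) + 8
    rownames(mat) <- sprintf("c%d", seq_len(k))
    norm <- fake_norm(pmax(mat, 0))
    labels <- stats::setNames(seq_len(k), rownames(mat))
    mg <- merge_subclasses(norm, labels, r_threshold = 0.49)
    # oracle: BFS over the thresholded correlation matrix
    r <- mg$cor_matrix
    adj <- r > 0.49; diag(adj) <- FALSE
    comp <- rep(0L, k); cur <- 0L
    for (i in seq_len(k)) {
      if (comp[i] > 0) next
      cur <- cur + 1L; queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[v] > 0) next
        comp[v] <- cur
        queue <- c(queue, which(adj[v, ] & comp == 0))
      }
    }
    expect_equal(unname(tapply(seq_len(k), mg$class_of, length)),
                 unname(tapply(seq_len(k), comp, length)))
    # same partition up to renaming
    expect_true(all(tapply(comp, mg$class_of,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("classes are a coarsening of subclasses and dendrogram is valid", {
  d <- generate_dataset(two_pop_config(seed = 19, n_cells = 100))
  norm <- normalize_log(d$counts)
  truth <- stats::setNames(d$truth$population, d$truth$cell_id)
  mg <- merge_subclasses(norm, truth, r_threshold = 0.49)
  split_classes <- tapply(mg$classes, truth[names(mg$classes)],
                          function(v) length(unique(v)))
  expect_true(all(split_classes == 1))
  expect_match(mg$newick, "^\\(")
  tree <- ape::read.tree(text = mg$newick)
  expect_setequal(tree$tip.label, unique(as.character(truth)))
})

test_that("subclass clustering removes MSN-contaminated clusters post hoc", {
  cfg <- two_pop_config(seed = 23, n_cells = 300)
  cfg$populations[[2]]$markers <- c("PPP1R1B", "DRD1")
  cfg$silenced_genes <- c("PPP1R1B", "DRD1")
  d <- generate_dataset(cfg)
  norm <- normalize_log(d$counts)
  sc <- subclass_clustering(norm, n_hvg = 100, n_pcs = 10, seed = 1)
  truth <- stats::setNames(d$truth$population, d$truth$cell_id)
  expect_true(all(truth[sc$removed] == "B"))
  expect_true(all(truth[names(sc$labels)] == "A"))
})
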