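#' Total-count normalization and log transform
#'
#' Scales each cell's counts to `target_sum` total and applies
#' `log1p`, the normalization used throughout the pipeline.
#'
#' @param cm A [count_matrix()].
#' @param target_sum Per-cell total after scaling (default 10,000).
#' @return A `norm_matrix`: list with `mat` (sparse cell x gene matrix
#'   of `log1p(count * target_sum / cell_total)`), `target_sum`, and
#'   `gene_flags` (see [gene_category_flags()]).
#' @export
normalize_log <- function(cm, target_sum = 10000) {
  stopifnot(inherits(cm, "count_matrix"))
  tot <- Matrix::rowSums(cm$counts)
  if (any(tot == 0))
    stop("all-zero cells cannot be normalized: ",
         paste(utils::head(cm$cell_ids[tot == 0], 5), collapse = ", "))
  mat <- methods::as(Matrix::Diagonal(x = target_sum / tot) %*% cm$counts,
                     "CsparseMatrix")
  mat@x <- log1p(mat@x)
  dimnames(mat) <- dimnames(cm$counts)
  structure(list(mat = mat, target_sum = target_sum,
                 gene_flags = gene_category_flags(cm$gene_names),
                 cell_meta = cm$cell_meta),
            class = "norm_matrix")
}

#' Restrict a normalized matrix to a subset of cells
#' @param norm A [normalize_log()] matrix.
#' @param cell_ids Cells to keep.
#' @return A `norm_matrix` over those cells.
#' @export
subset_norm <- function(norm, cell_ids) {
  stopifnot(inherits(norm, "norm_matrix"))
  idx <- match(cell_ids, rownames(norm$mat))
  if (anyNA(idx)) stop("unknown cell ids")
  structure(list(mat = norm$mat[idx, , drop = FALSE],
                 target_sum = norm$target_sum,
                 gene_flags = norm$gene_flags,
                 cell_meta = norm$cell_meta[idx, , drop = FALSE]),
            class = "norm_matrix")
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Computes per-gene mean and dispersion (variance/mean) of the
#' normalized log values, z-scores the dispersion within 20 equal-count
#' mean bins, and returns the `n` genes with the highest normalized
#' dispersion, after removing sex-linked, mitochondrial and
#' riboprotein genes.  Ties break lexicographically by gene name.
#'
#' @param norm A [normalize_log()] matrix.
#' @param n Number of genes to return.
#' @param exclude Character subset of `c("sex", "mito", "ribo")`.
#' @param n_bins Number of mean bins.
#' @return Character vector of gene names ordered by decreasing
#'   normalized dispersion.
#' @export
select_hvg <- function(norm, n = 1500, exclude = c("sex", "mito", "ribo"),
                       n_bins = 20) {
  stopifnot(inherits(norm, "norm_matrix"))
  flags <- norm$gene_flags
  drop <- rep(FALSE, ncol(norm$mat))
  for (cat in exclude) drop <- drop | flags[, cat]
  genes <- colnames(norm$mat)[!drop]
  m <- norm$mat[, !drop, drop = FALSE]
  mu <- Matrix::colMeans(m)
  v <- (Matrix::colSums(m^2) - nrow(m) * mu^2) / (nrow(m) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  if (n > length(genes))
    stop("n exceeds the number of eligible genes (", length(genes), ")")
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  zdisp <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    zdisp[i] <- if (is.finite(s) && s > 0) (disp[i] - mean(disp[i])) / s
                else 0
  }
  ord <- order(-zdisp, genes)
  genes[ord][seq_len(n)]
}

# PCA scores via the eigendecomposition of the (centered) gene-space
# crossproduct; x must already be centered (and scaled if desired).
.pca_scores <- function(x, k) {
  k <- min(k, ncol(x), nrow(x) - 1)
  e <- eigen(crossprod(x), symmetric = TRUE)
  x %*% e$vectors[, seq_len(k), drop = FALSE]
}

# Symmetrized (union) k-nearest-neighbour graph on an embedding;
# distances are computed in row blocks to bound memory.
.knn_graph <- function(x, k = 15, block = 1024L) {
  n <- nrow(x)
  if (n <= k) stop("fewer cells than k + 1 neighbours")
  sq <- rowSums(x^2)
  edges <- matrix(0L, n * k, 2)
  for (start in seq(1, n, by = block)) {
    rows <- start:min(start + block - 1, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(x[rows, , drop = FALSE], x)
    for (j in seq_along(rows)) {
      i <- rows[j]
      nn <- order(d2[j, ])[2:(k + 1)]
      edges[((i - 1) * k + 1):(i * k), ] <- cbind(i, nn)
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' PCA embedding and Louvain graph clustering
#'
#' Standardizes the HVG-restricted normalized matrix, projects onto the
#' first `n_pcs` principal components, builds a symmetrized k-NN graph
#' and runs Louvain community detection at the given resolution.
#' Cluster labels are contiguous integers ordered by decreasing size.
#'
#' @param norm A [normalize_log()] matrix.
#' @param hvgs Genes to embed on (from [select_hvg()]).
#' @param n_pcs Number of principal components.
#' @param resolution Louvain resolution.
#' @param seed Integer seed (Louvain is randomized).
#' @param k Neighbours of the k-NN graph.
#' @return Named integer vector of per-cell cluster labels.
#' @export
embed_cluster <- function(norm, hvgs, n_pcs = 30, resolution = 0.2,
                          seed = 0L, k = 15) {
  stopifnot(inherits(norm, "norm_matrix"))
  x <- scale(as.matrix(norm$mat[, hvgs, drop = FALSE]))
  x[is.na(x)] <- 0
  pcs <- .pca_scores(x, n_pcs)
  g <- .knn_graph(pcs, k = k)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  raw <- igraph::membership(cl)
  sizes <- sort(table(raw), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relab[as.character(raw)])
  names(out) <- rownames(norm$mat)
  out
}

#' Label clusters by their best-scoring marker panel
#'
#' Each cluster receives the cell type whose panel has the highest
#' cluster-mean marker score, provided it beats the runner-up by
#' `margin`; otherwise the cluster is `"unassigned"`.
#'
#' @param norm A [normalize_log()] matrix.
#' @param labels Per-cell cluster labels (named, aligned with `norm`).
#' @param panel Named list of marker gene vectors.
#' @param margin Required lead over the runner-up score.
#' @return Named character vector: cluster id -> type.
#' @export
label_clusters_by_markers <- function(norm, labels,
                                      panel = default_marker_panel(),
                                      margin = 0.1) {
  sc <- marker_score(norm, panel)
  clusters <- sort(unique(labels))
  out <- vapply(clusters, function(cl) {
    cs <- colMeans(sc[labels == cl, , drop = FALSE])
    o <- order(cs, decreasing = TRUE)
    if (cs[o[1]] <= 0) return("unassigned")
    if (length(cs) > 1 && cs[o[1]] - cs[o[2]] < margin) return("unassigned")
    names(cs)[o[1]]
  }, "")
  stats::setNames(out, clusters)
}

#' Re-filter neuronal nuclei on stricter count thresholds
#'
#' Neurons with fewer than `neuron_min_umis` UMIs, fewer than
#' `neuron_min_genes` genes or more than `neuron_max_genes` genes are
#' discarded (strict-exceedance bounds); only the given neuron cells are
#' judged.
#'
#' @param cm A [count_matrix()] (the full dataset).
#' @param neuron_ids Cells labeled as neurons.
#' @param t A [qc_thresholds()].
#' @return Character vector of kept neuron ids.
#' @export
neuron_quality_refilter <- function(cm, neuron_ids, t = qc_thresholds()) {
  m <- cell_metrics(subset_cells(cm, neuron_ids))
  keep <- m$n_umis >= t$neuron_min_umis &
    m$n_genes >= t$neuron_min_genes & m$n_genes <= t$neuron_max_genes
  m$cell_id[keep]
}

#' Select interneuron clusters by inhibitory / MSN / excitatory gating
#'
#' Cluster-level gating: a cluster is an interneuron cluster iff the
#' cluster mean of any positive marker (GAD1, GAD2, CHAT) exceeds
#' `pos_threshold` and the cluster means of all negative markers (MSN:
#' PPP1R1B, DRD1, DRD2, MEIS2; excitatory: RORB) stay below
#' `neg_threshold`.
#'
#' @param norm A [normalize_log()] matrix.
#' @param labels Per-cell cluster labels aligned with `norm`.
#' @param positive,negative Marker gene sets.
#' @param pos_threshold,neg_threshold Cluster-mean gates in normalized
#'   log units.
#' @return Character vector of interneuron cell ids.
#' @export
select_interneurons <- function(norm, labels,
                                positive = c("GAD1", "GAD2", "CHAT"),
                                negative = c("PPP1R1B", "DRD1", "DRD2",
                                             "MEIS2", "RORB"),
                                pos_threshold = 0.25, neg_threshold = 0.1) {
  stopifnot(inherits(norm, "norm_matrix"))
  pos <- intersect(positive, colnames(norm$mat))
  neg <- intersect(negative, colnames(norm$mat))
  keep <- character()
  for (cl in sort(unique(labels))) {
    cells <- names(labels)[labels == cl]
    sub <- norm$mat[cells, , drop = FALSE]
    pos_mean <- if (length(pos)) apply(sub[, pos, drop = FALSE], 2, mean) else 0
    neg_mean <- if (length(neg)) apply(sub[, neg, drop = FALSE], 2, mean) else 0
    if (any(pos_mean > pos_threshold) && all(neg_mean < neg_threshold))
      keep <- c(keep, cells)
  }
  keep
}

#' Subclass clustering of the interneuron subset
#'
#' Composition of [select_hvg()] (1500 genes) and [embed_cluster()]
#' (20 principal components) on the interneuron-restricted matrix,
#' followed by a post-hoc gate removing clusters that still express MSN
#' or excitatory markers above `neg_threshold` (cluster mean).
#'
#' @param norm A [normalize_log()] matrix restricted to interneurons.
#' @param n_hvg,n_pcs,resolution,seed,k Clustering parameters.
#' @param gate_markers Markers whose cluster-mean expression disqualifies
#'   a cluster.
#' @param neg_threshold Cluster-mean gate.
#' @return A list with `labels` (named integer vector over surviving
#'   cells, relabeled contiguously by decreasing size) and
#'   `removed` (cell ids of gated-out clusters).
#' @export
subclass_clustering <- function(norm, n_hvg = 1500, n_pcs = 20,
                                resolution = 1.0, seed = 0L, k = 15,
                                gate_markers = c("PPP1R1B", "DRD1", "DRD2",
                                                 "MEIS2", "RORB"),
                                neg_threshold = 0.1) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (nrow(norm$mat) < 100)
    stop("need at least 100 interneurons for subclass clustering")
  hv <- select_hvg(norm, n = min(n_hvg, sum(!rowSums(norm$gene_flags) > 0)))
  labels <- embed_cluster(norm, hv, n_pcs = n_pcs, resolution = resolution,
                          seed = seed, k = k)
  gate <- intersect(gate_markers, colnames(norm$mat))
  removed <- character()
  for (cl in unique(labels)) {
    cells <- names(labels)[labels == cl]
    if (length(gate)) {
      gm <- apply(norm$mat[cells, gate, drop = FALSE], 2, mean)
      if (any(gm >= neg_threshold)) removed <- c(removed, cells)
    }
  }
  keep <- setdiff(names(labels), removed)
  lab <- labels[keep]
  sizes <- sort(table(lab), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  list(labels = stats::setNames(as.integer(relab[as.character(lab)]), keep),
       removed = removed)
}

# One-vs-rest Wilcoxon rank-sum (normal approximation, tie-corrected,
# two-sided).  Ranks and tie terms are computed once per gene and shared
# across groups; `ranks` is the column-ranked matrix and `tie_term` the
# per-gene sum of (t^3 - t) over tied values.
.wilcox_from_ranks <- function(ranks, tie_term, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  u <- colSums(ranks[in_group, , drop = FALSE]) - n1 * (n1 + 1) / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(sig2 > 0, (u - n1 * n2 / 2) / sqrt(pmax(sig2, 1e-300)), 0)
  list(z = z, p = ifelse(sig2 > 0, 2 * stats::pnorm(-abs(z)), 1))
}

#' Rank marker genes per group by Wilcoxon rank-sum
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per gene and group on
#' the normalized log values, with Benjamini-Hochberg adjustment within
#' each group; rows sorted by decreasing score (the signed z statistic).
#'
#' @param norm A [normalize_log()] matrix.
#' @param labels Per-cell group labels aligned with `norm`.
#' @return A `data.frame`: `group`, `gene`, `score`, `log2_fold`, `p`,
#'   `p_adj`.
#' @export
rank_marker_genes <- function(norm, labels) {
  stopifnot(inherits(norm, "norm_matrix"))
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least two groups to rank markers")
  if (any(table(labels) < 3)) stop("every group needs at least 3 cells")
  m <- norm$mat[names(labels), , drop = FALSE]
  n_genes <- ncol(m)
  gene_names <- colnames(m)
  # per-group statistics accumulated over gene blocks to bound memory
  z_mat <- matrix(0, n_genes, length(groups))
  p_mat <- matrix(1, n_genes, length(groups))
  lf_mat <- matrix(0, n_genes, length(groups))
  in_group <- lapply(groups, function(g) labels == g)
  for (start in seq(1, n_genes, by = 1000L)) {
    cols <- start:min(start + 999L, n_genes)
    mat <- as.matrix(m[, cols, drop = FALSE])
    ranks <- apply(mat, 2, rank)
    tie_term <- apply(mat, 2, function(x) {
      t <- rle(sort(x))$lengths
      sum(t^3 - t)
    })
    ex <- expm1(mat)
    ex_tot <- colSums(ex)
    for (gi in seq_along(groups)) {
      ing <- in_group[[gi]]
      wt <- .wilcox_from_ranks(ranks, tie_term, ing)
      mu1 <- colSums(ex[ing, , drop = FALSE]) / sum(ing)
      mu2 <- (ex_tot - mu1 * sum(ing)) / sum(!ing)
      z_mat[cols, gi] <- wt$z
      p_mat[cols, gi] <- wt$p
      lf_mat[cols, gi] <- log2((mu1 + 1e-9) / (mu2 + 1e-9))
    }
  }
  out <- lapply(seq_along(groups), function(gi) {
    df <- data.frame(group = groups[gi], gene = gene_names,
                     score = z_mat[, gi], log2_fold = lf_mat[, gi],
                     p = p_mat[, gi],
                     p_adj = stats::p.adjust(p_mat[, gi], "BH"),
                     stringsAsFactors = FALSE)
    df[order(-df$score), ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Merge subclasses into main classes by mean-profile correlation
#'
#' Computes the mean normalized-log expression profile of each subclass
#' over all genes and the pairwise Pearson correlation matrix between
#' profiles.  Subclasses joined by correlations strictly above
#' `r_threshold` are merged: by connected components (default) or, in
#' `"clique"` mode, into groups whose members all correlate pairwise
#' above the threshold (complete-linkage cut).  Also returns the
#' average-linkage dendrogram on distance `1 - r`.
#'
#' @param norm A [normalize_log()] matrix.
#' @param labels Per-cell subclass labels aligned with `norm`.
#' @param r_threshold Merge threshold on Pearson r (strict `>`).
#' @param mode `"components"` or `"clique"`.
#' @return A list with `class_of` (subclass -> class id), `classes`
#'   (per-cell class labels), `cor_matrix`, `dendrogram` (an `hclust`),
#'   and `newick` (the dendrogram in Newick format).
#' @export
merge_subclasses <- function(norm, labels, r_threshold = 0.49,
                             mode = c("components", "clique")) {
  mode <- match.arg(mode)
  stopifnot(inherits(norm, "norm_matrix"))
  subs <- sort(unique(labels))
  if (length(subs) < 2) stop("need at least two subclasses to merge")
  prof <- vapply(subs, function(s)
    Matrix::colMeans(norm$mat[names(labels)[labels == s], , drop = FALSE]),
    numeric(ncol(norm$mat)))
  colnames(prof) <- as.character(subs)
  r <- stats::cor(prof)
  if (mode == "components") {
    adj <- r > r_threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
  } else {
    hc <- stats::hclust(stats::as.dist(1 - r), method = "complete")
    comp <- stats::cutree(hc, h = 1 - r_threshold - 1e-12)
  }
  # class ids contiguous in order of first appearance
  comp <- stats::setNames(match(comp, unique(comp)), colnames(r))
  hc_avg <- stats::hclust(stats::as.dist(1 - r), method = "average")
  phy <- ape::as.phylo(hc_avg)
  classes <- stats::setNames(comp[as.character(labels)], names(labels))
  list(class_of = comp, classes = classes, cor_matrix = r,
       dendrogram = hc_avg, newick = ape::write.tree(phy))
}
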