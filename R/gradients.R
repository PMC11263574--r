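#' Single-latent-factor analysis of a subclass in one region
#'
#' Fits the linear Gaussian factor model `x = w z + eps`,
#' `eps ~ N(0, diag(psi))`, with one latent dimension, by EM on the
#' centered (not variance-scaled) matrix of the 1200 most variable
#' genes (sex-linked, mitochondrial and riboprotein genes removed).
#' Initialization is deterministic from the top principal component;
#' the sign convention makes the gene with the largest absolute weight
#' positive.
#'
#' @param norm A [normalize_log()] matrix restricted to the cells of
#'   one subclass and region.
#' @param n_hvg Number of highly variable genes to fit on.
#' @param exclude Gene categories removed before HVG selection.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param scale. If `TRUE`, genes are variance-scaled before fitting.
#' @return A `factor_result`: list with `scores` (named per-cell factor
#'   values), `weights` (named per-gene loadings), `psi` (noise
#'   variances), `genes`, `n_iter`.
#' @export
factor_analysis_single <- function(norm, n_hvg = 1200,
                                   exclude = c("sex", "mito", "ribo"),
                                   max_iter = 500, tol = 1e-6,
                                   scale. = FALSE) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (nrow(norm$mat) < 50) stop("need at least 50 cells for factor analysis")
  hv <- select_hvg(norm, n = min(n_hvg, .n_eligible(norm, exclude)),
                   exclude = exclude)
  x <- as.matrix(norm$mat[, hv, drop = FALSE])
  keep <- apply(x, 2, stats::sd) > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant gene(s) dropped before factor fitting")
    x <- x[, keep, drop = FALSE]
  }
  x <- scale(x, center = TRUE, scale = scale.)
  n <- nrow(x); p <- ncol(x)
  # deterministic init from the top PC of the centered data
  sv <- svd(x, nu = 1, nv = 1)
  w <- sv$v[, 1] * sv$d[1] / sqrt(n)
  gene_var <- apply(x, 2, stats::var)
  # relative floor on the noise variances prevents Heywood collapse onto
  # single genes when genes outnumber cells
  psi_floor <- pmax(0.05 * gene_var, 1e-10)
  psi <- pmax(gene_var - w^2, psi_floor)
  it <- 0
  xtx_col <- colMeans(x^2)
  ez <- numeric(n)
  for (it in seq_len(max_iter)) {
    # E-step: posterior of z given x (1-D latent, prior z ~ N(0,1))
    a <- sum(w^2 / psi)
    m_var <- 1 / (1 + a)
    ez <- as.numeric(x %*% (w / psi)) * m_var        # E[z_i]
    ez2 <- m_var + ez^2                              # E[z_i^2]
    # M-step
    sum_ez2 <- sum(ez2)
    w_new <- as.numeric(crossprod(x, ez)) / sum_ez2
    psi <- pmax(xtx_col - 2 * w_new * colMeans(x * ez) +
                  w_new^2 * sum_ez2 / n, psi_floor)
    delta <- sqrt(sum((w_new - w)^2) / max(sum(w^2), 1e-12))
    w <- w_new
    if (delta < tol) break
  }
  scores <- ez / stats::sd(ez)
  w_out <- w * stats::sd(ez)
  if (w_out[which.max(abs(w_out))] < 0) { w_out <- -w_out; scores <- -scores }
  structure(list(scores = stats::setNames(scores, rownames(x)),
                 weights = stats::setNames(w_out, colnames(x)),
                 psi = stats::setNames(psi, colnames(x)),
                 genes = colnames(x), n_iter = it),
            class = "factor_result")
}

.n_eligible <- function(norm, exclude) {
  drop <- rep(FALSE, ncol(norm$mat))
  for (cat in exclude) drop <- drop | norm$gene_flags[, cat]
  sum(!drop)
}

#' Genes with the most extreme factor weights
#'
#' @param result A [factor_analysis_single()] result.
#' @param k Number of genes per extreme.
#' @return A list with `top` and `bottom` gene-name vectors (ties break
#'   by name).
#' @export
top_weight_genes <- function(result, k) {
  stopifnot(inherits(result, "factor_result"),
            k <= length(result$weights))
  w <- result$weights
  ord <- order(-w, names(w))
  list(top = names(w)[ord][seq_len(k)],
       bottom = rev(names(w)[ord])[seq_len(k)])
}

#' Rule for selecting functional gene subsets
#'
#' Defaults mirror the neurotransmitter-receptor selection: prefixes
#' DRD (dopamine), GABR (GABA), CHRN/CHRM (acetylcholine),
#' GRIA/GRIN/GRIK/GRM/GRID/GRIP (glutamate), plus the three glutamate
#' receptors whose names break the pattern (PEPL1, POLR2M, GCOM1); an
#' explicit id list (e.g. the genes under ion-channel GO term
#' GO:0005216) can be supplied instead of or on top of the prefixes.
#'
#' @param prefixes Uppercase gene-name prefixes (prefix-anchored match).
#' @param extra_genes Explicit extra gene names.
#' @param id_list Optional explicit gene-name list.
#' @return A `gene_subset_rule` list.
#' @export
gene_subset_rule <- function(prefixes = c("DRD", "GABR", "CHRN", "CHRM",
                                          "GRIA", "GRIN", "GRIK", "GRM",
                                          "GRID", "GRIP"),
                             extra_genes = c("PEPL1", "POLR2M", "GCOM1"),
                             id_list = NULL) {
  if (!length(prefixes) && !length(extra_genes) && !length(id_list))
    stop("rule must name at least one prefix, gene or id list")
  structure(list(prefixes = toupper(prefixes), extra_genes = extra_genes,
                 id_list = id_list), class = "gene_subset_rule")
}

#' Select a functional gene subset from the universe
#'
#' Union of prefix-anchored matches, explicit extra genes, and the
#' intersection of the id list with the universe; reports (via message)
#' how many listed ids were not found.
#'
#' @param gene_names Gene universe.
#' @param rule A [gene_subset_rule()].
#' @return Character vector of selected gene names (universe order).
#' @export
select_gene_subset <- function(gene_names, rule = gene_subset_rule()) {
  stopifnot(inherits(rule, "gene_subset_rule"))
  up <- toupper(gene_names)
  hit <- rep(FALSE, length(gene_names))
  for (pf in rule$prefixes) hit <- hit | startsWith(up, pf)
  hit <- hit | gene_names %in% rule$extra_genes
  if (!is.null(rule$id_list)) {
    found <- rule$id_list %in% gene_names
    if (any(!found))
      message(sum(!found), " of ", length(rule$id_list),
              " listed ids not found in the gene universe")
    hit <- hit | gene_names %in% rule$id_list
  }
  gene_names[hit]
}
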