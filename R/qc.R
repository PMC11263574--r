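#' Consensus doublet voting over repeated scorer runs
#'
#' A cell is discarded iff it was flagged as a doublet on strictly more
#' than `vote_fraction` of the runs (the 10\% consensus rule); a cell
#' flagged on exactly the threshold fraction of runs is kept.
#'
#' @param call_matrix Logical cell x run matrix of per-run doublet calls
#'   (rownames are cell ids).
#' @param vote_fraction Fraction of runs above which a cell is discarded.
#' @return Character vector of kept cell ids.
#' @export
consensus_doublet_filter <- function(call_matrix, vote_fraction = 0.10) {
  if (is.null(dim(call_matrix)) || ncol(call_matrix) < 1)
    stop("call_matrix must have at least one run (column)")
  frac <- rowMeans(call_matrix)
  rownames(call_matrix)[frac <= vote_fraction]
}

# Density-valley threshold between the two dominant modes; NULL if the
# distribution is unimodal.
.valley_threshold <- function(x) {
  if (length(unique(x)) < 3) return(NULL)
  d <- stats::density(x, n = 512)
  dy <- diff(d$y)
  peaks <- which(diff(sign(dy)) == -2) + 1
  peaks <- peaks[d$y[peaks] > 0.05 * max(d$y)]
  if (length(peaks) < 2) return(NULL)
  top2 <- sort(peaks[order(d$y[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  d$x[between[which.min(d$y[between])]]
}

#' Simulated-doublet k-NN scorer, run repeatedly per sample
#'
#' For each run (fresh seed derived from the base seed) and each sample
#' independently: synthetic doublets are simulated by summing random
#' cell pairs; observed and simulated cells are log-normalized,
#' restricted to the sample's highly variable genes (computed once per
#' sample on the observed cells), embedded by PCA (with one extra
#' standardized log-library-size coordinate, so same-population doublets
#' remain detectable by their doubled molecule content); each observed
#' cell is scored by the fraction of simulated doublets among its k
#' nearest neighbours; the run's call threshold is the minimum-density
#' valley between the two modes of the simulated doublets' own score
#' distribution, falling back to the `1 - expected_rate` quantile of the
#' observed scores when that distribution is unimodal.
#'
#' @param cm A [count_matrix()].
#' @param n_runs Number of independent runs.
#' @param expected_rate Expected doublet rate, used only by the
#'   unimodal fallback threshold.
#' @param seed Integer base seed.
#' @param n_hvg,n_pcs Genes and principal components per run.
#' @param min_cells Samples with fewer cells get all-FALSE calls.
#' @return Logical cell x run matrix of doublet calls.
#' @export
run_doublet_scorer <- function(cm, n_runs = 100, expected_rate = 0.06,
                               seed = 0L, n_hvg = 300, n_pcs = 10,
                               min_cells = 50) {
  stopifnot(inherits(cm, "count_matrix"))
  n <- nrow(cm$counts)
  calls <- matrix(FALSE, n, n_runs, dimnames = list(cm$cell_ids, NULL))
  samples <- unique(cm$cell_meta$sample_id)
  for (si in seq_along(samples)) {
    idx <- which(cm$cell_meta$sample_id == samples[si])
    n_obs <- length(idx)
    if (n_obs < min_cells) {
      warning("sample ", samples[si], " has fewer than ", min_cells,
              " cells; doublet scorer skipped (all-FALSE calls)")
      next
    }
    # per-sample preparation shared by all runs: library sizes and the
    # highly variable genes of the observed cells
    tot_obs <- Matrix::rowSums(cm$counts[idx, , drop = FALSE])
    lognorm_obs <- methods::as(Matrix::Diagonal(x = 1e4 / tot_obs) %*%
                                 cm$counts[idx, , drop = FALSE],
                               "CsparseMatrix")
    lognorm_obs@x <- log1p(lognorm_obs@x)
    v <- .col_vars_sparse(lognorm_obs)
    hv <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, ncol(lognorm_obs)))]
    obs_cnt <- as.matrix(cm$counts[idx, hv, drop = FALSE])
    is_sim <- c(rep(FALSE, n_obs), rep(TRUE, n_obs))
    for (r in seq_len(n_runs)) {
      set.seed((seed + 104729L * si + r) %% .Machine$integer.max)
      i1 <- sample(n_obs, n_obs, replace = TRUE)
      i2 <- sample(n_obs, n_obs, replace = TRUE)
      cnt <- rbind(obs_cnt, obs_cnt[i1, , drop = FALSE] +
                     obs_cnt[i2, , drop = FALSE])
      tot <- c(tot_obs, tot_obs[i1] + tot_obs[i2])
      x <- scale(log1p(cnt * (1e4 / tot)))
      x[is.na(x)] <- 0
      pcs <- .pca_scores(x, min(n_pcs, ncol(x), nrow(x) - 1))
      size_feat <- as.numeric(scale(log(tot)))
      alpha <- mean(apply(pcs, 2, stats::sd))
      feat <- cbind(pcs, alpha * size_feat)
      k <- max(3L, ceiling(0.5 * sqrt(nrow(feat))))
      sq <- rowSums(feat^2)
      d2 <- outer(sq, sq, "+") - 2 * tcrossprod(feat)
      scores <- vapply(seq_len(2 * n_obs), function(i) {
        nn <- order(d2[i, ])[2:(k + 1)]
        mean(is_sim[nn])
      }, 0)
      obs_scores <- scores[!is_sim]
      thr <- .valley_threshold(scores[is_sim])
      if (is.null(thr))
        thr <- stats::quantile(obs_scores, 1 - expected_rate, names = FALSE)
      calls[idx, r] <- obs_scores > thr
    }
  }
  calls
}

.col_vars_sparse <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colMeans(m)
  (Matrix::colSums(m^2) - n * mu^2) / (n - 1)
}

#' Basic per-cell count filters
#'
#' Keeps cells with `n_umis` in \[min_umis, max_umis\], `n_genes` in
#' \[min_genes, max_genes\] and `mito_fraction <= max_mito`; all bounds
#' are strict-exceedance ("less than 500 UMIs" removes 499 but keeps
#' 500; "more than 10\%" removes 0.1001 but keeps 0.10).
#'
#' @param cm A [count_matrix()].
#' @param t A [qc_thresholds()].
#' @return Character vector of kept cell ids.
#' @export
basic_count_filter <- function(cm, t = qc_thresholds()) {
  m <- cell_metrics(cm)
  keep <- m$n_umis >= t$min_umis & m$n_umis <= t$max_umis &
    m$n_genes >= t$min_genes & m$n_genes <= t$max_genes &
    m$mito_fraction <= t$max_mito
  m$cell_id[keep]
}

#' Fit the gene--UMI relationship as a degree-2 polynomial in log space
#'
#' Least-squares fit of `log(n_genes)` on `log(n_umis)` and its square,
#' on the cells of `cm` (which should already have passed the basic
#' count filters).
#'
#' @param cm A [count_matrix()].
#' @return Numeric coefficients `(intercept, linear, quadratic)`.
#' @export
fit_gene_umi_polynomial <- function(cm) {
  m <- cell_metrics(cm)
  if (nrow(m) < 10) stop("need at least 10 cells to fit the gene-UMI polynomial")
  if (any(m$n_umis <= 0)) stop("all cells must have positive UMI counts")
  lu <- log(m$n_umis); lg <- log(m$n_genes)
  if (stats::sd(lu) < 1e-12) stop("degenerate design: all cells have identical UMI counts")
  fit <- stats::lm(lg ~ lu + I(lu^2))
  co <- unname(stats::coef(fit))
  co[is.na(co)] <- 0
  co
}

#' Remove cells deviating from the fitted gene--UMI polynomial
#'
#' A cell is an outlier iff its deviation from the fitted prediction
#' exceeds `delta`.  With `unit = "genes"` (default) the deviation is
#' `|n_genes - exp(predicted log n_genes)|`, i.e. measured in gene-count
#' units after back-transforming the prediction — the only physically
#' sensible reading of a 2000-unit tolerance; `unit = "log"` applies the
#' tolerance to `|log(n_genes) - predicted|` literally.
#'
#' @param cm A [count_matrix()].
#' @param coeffs Coefficients from [fit_gene_umi_polynomial()].
#' @param delta Maximum allowed deviation.
#' @param unit `"genes"` or `"log"`.
#' @return Character vector of kept cell ids.
#' @export
polynomial_outlier_filter <- function(cm, coeffs, delta = 2000,
                                      unit = c("genes", "log")) {
  unit <- match.arg(unit)
  m <- cell_metrics(cm)
  lu <- log(m$n_umis)
  pred <- coeffs[1] + coeffs[2] * lu + coeffs[3] * lu^2
  dev <- if (unit == "genes") abs(m$n_genes - exp(pred))
         else abs(log(m$n_genes) - pred)
  m$cell_id[dev <= delta]
}

#' Per-cell marker scores for broad cell types
#'
#' The score of a cell for a type is the arithmetic mean of the
#' normalized log expression of that type's canonical markers.
#'
#' @param norm A [normalize_log()] matrix.
#' @param panel Named list of marker gene vectors
#'   (default [default_marker_panel()]).
#' @return Numeric cell x type score matrix.
#' @export
marker_score <- function(norm, panel = default_marker_panel()) {
  stopifnot(inherits(norm, "norm_matrix"))
  scores <- matrix(0, nrow(norm$mat), length(panel),
                   dimnames = list(rownames(norm$mat), names(panel)))
  for (ty in names(panel)) {
    present <- intersect(panel[[ty]], colnames(norm$mat))
    missing <- setdiff(panel[[ty]], colnames(norm$mat))
    if (length(missing))
      warning("markers missing from gene universe for type ", ty, ": ",
              paste(missing, collapse = ", "))
    if (!length(present))
      stop("no markers of type '", ty, "' are present in the gene universe")
    scores[, ty] <- Matrix::rowMeans(norm$mat[, present, drop = FALSE])
  }
  scores
}

# EM for a univariate two-component Gaussian mixture with unequal
# variances.  Deterministic initialization: 2-means started from the
# 10th and 90th percentiles.  Returns NULL on failure.
.gmm2_em <- function(x, max_iter = 200, tol = 1e-6) {
  n <- length(x)
  starts <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  if (diff(starts) < 1e-12) return(NULL)
  km <- tryCatch(stats::kmeans(x, centers = matrix(starts, 2, 1)),
                 error = function(e) NULL)
  if (is.null(km)) return(NULL)
  mu <- as.numeric(km$centers)
  sig <- vapply(1:2, function(g) {
    xs <- x[km$cluster == g]
    max(stats::sd(xs), 1e-3 * stats::sd(x), 1e-12)
  }, 0)
  if (anyNA(sig)) return(NULL)
  w <- tabulate(km$cluster, 2) / n
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sig[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sig[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    r <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    sig <- sqrt(c(sum(r * (x - mu[1])^2) / n1,
                  sum((1 - r) * (x - mu[2])^2) / n2))
    sig <- pmax(sig, 1e-6 * stats::sd(x))
    w <- c(n1, n2) / n
  }
  list(mu = mu, sigma = sig, w = w)
}

#' Two-Gaussian mixture threshold on a marker-score distribution
#'
#' Fits a two-component Gaussian mixture with unequal variances by EM
#' (deterministic 2-means initialization, components sorted by mean)
#' and sets the calling threshold at `mu_low + 4 * sigma_low`.  If the
#' fit fails or the scores are (near-)degenerate, falls back to a single
#' Gaussian: `threshold = mean + 4 * sd`.
#'
#' @param scores Numeric vector of per-cell scores for one type.
#' @return A list with `mu_low`, `sigma_low`, `mu_high`, `sigma_high`,
#'   `weights`, `threshold`, `fallback`.
#' @export
mixture_threshold <- function(scores) {
  stopifnot(is.numeric(scores))
  s <- stats::sd(scores)
  if (!is.finite(s) || s < 1e-10)
    return(list(mu_low = mean(scores), sigma_low = 0,
                mu_high = mean(scores), sigma_high = 0,
                weights = c(1, 0), threshold = mean(scores),
                fallback = TRUE))
  fit <- .gmm2_em(scores)
  if (is.null(fit) || any(!is.finite(fit$sigma))) {
    warning("mixture fit failed; falling back to single-Gaussian threshold")
    return(list(mu_low = mean(scores), sigma_low = s,
                mu_high = mean(scores), sigma_high = s,
                weights = c(1, 0), threshold = mean(scores) + 4 * s,
                fallback = TRUE))
  }
  o <- order(fit$mu)
  list(mu_low = fit$mu[o[1]], sigma_low = fit$sigma[o[1]],
       mu_high = fit$mu[o[2]], sigma_high = fit$sigma[o[2]],
       weights = fit$w[o], threshold = fit$mu[o[1]] + 4 * fit$sigma[o[1]],
       fallback = FALSE)
}

#' Exclude cells that pass the marker-score threshold for several types
#'
#' Cells above exactly one type's threshold are assigned that type;
#' cells above two or more are considered doublets and excluded; cells
#' above none are kept untyped (`"none"`).
#'
#' @param score_table Cell x type score matrix from [marker_score()].
#' @param thresholds Named list of [mixture_threshold()] records, one
#'   per scored type.
#' @return A list with `kept` (cell ids) and `type` (named character
#'   vector over kept cells).
#' @export
multi_identity_doublet_filter <- function(score_table, thresholds) {
  types <- colnames(score_table)
  if (!all(types %in% names(thresholds)))
    stop("missing thresholds for types: ",
         paste(setdiff(types, names(thresholds)), collapse = ", "))
  thr <- vapply(types, function(ty) thresholds[[ty]]$threshold, 0)
  above <- sweep(score_table, 2, thr, ">")
  n_above <- rowSums(above)
  kept <- rownames(score_table)[n_above <= 1]
  type <- rep("none", length(kept)); names(type) <- kept
  one <- kept[n_above[kept] == 1]
  type[one] <- types[apply(above[one, , drop = FALSE], 1, which)]
  list(kept = kept, type = type)
}

#' Remove cells expressing markers of neighbouring brain regions
#'
#' Cells expressing any of the listed regional contamination markers
#' (claustrum/amygdala: NEUROD2, TMEM155, CARTPT, SLC17A7) above
#' `min_expr` in normalized log units are removed; the default 0 removes
#' any detection.
#'
#' @param norm A [normalize_log()] matrix.
#' @param region_markers Character vector of contamination markers.
#' @param min_expr Normalized-log expression above which a cell is
#'   considered contaminated.
#' @return Character vector of kept cell ids.
#' @export
regional_marker_filter <- function(norm,
                                   region_markers = c("NEUROD2", "TMEM155",
                                                      "CARTPT", "SLC17A7"),
                                   min_expr = 0) {
  stopifnot(inherits(norm, "norm_matrix"))
  present <- intersect(region_markers, colnames(norm$mat))
  if (length(present) < length(region_markers))
    warning("regional markers missing from gene universe: ",
            paste(setdiff(region_markers, present), collapse = ", "))
  if (!length(present)) return(rownames(norm$mat))
  hit <- Matrix::rowSums(norm$mat[, present, drop = FALSE] > min_expr) > 0
  rownames(norm$mat)[!hit]
}

#' Run the full QC cascade
#'
#' Applies, in order: consensus doublet voting, basic count filters, the
#' gene--UMI polynomial outlier filter, the mixture-model marker-score
#' multi-identity filter, and the regional contamination filter.  Each
#' stage sees only the survivors of the previous one.
#'
#' @param cm A [count_matrix()].
#' @param t A [qc_thresholds()].
#' @param panel Marker panel for the score stage.
#' @param seed Integer seed for the doublet scorer.
#' @param target_sum Normalization target for the score stages.
#' @return A list with `kept` (cell ids), `type` (marker-score type of
#'   kept cells), `funnel` (`data.frame`: stage, cells_in,
#'   cells_removed), and `thresholds` (fitted mixture records).
#' @export
qc_cascade <- function(cm, t = qc_thresholds(), panel = default_marker_panel(),
                       seed = 0L, target_sum = 10000) {
  funnel <- data.frame(stage = character(), cells_in = integer(),
                       cells_removed = integer(), stringsAsFactors = FALSE)
  log_stage <- function(stage, n_in, n_out)
    rbind(funnel, data.frame(stage = stage, cells_in = n_in,
                             cells_removed = n_in - n_out))
  calls <- run_doublet_scorer(cm, n_runs = t$n_doublet_runs,
                              expected_rate = t$doublet_expected_rate,
                              seed = seed)
  kept <- consensus_doublet_filter(calls, t$doublet_vote_fraction)
  funnel <- log_stage("doublet_consensus", nrow(cm$counts), length(kept))
  cur <- subset_cells(cm, kept)

  kept <- basic_count_filter(cur, t)
  funnel <- log_stage("count_filters", nrow(cur$counts), length(kept))
  cur <- subset_cells(cur, kept)

  co <- fit_gene_umi_polynomial(cur)
  kept <- polynomial_outlier_filter(cur, co, t$poly_outlier_delta,
                                    unit = t$poly_delta_unit)
  funnel <- log_stage("gene_umi_polynomial", nrow(cur$counts), length(kept))
  cur <- subset_cells(cur, kept)

  norm <- normalize_log(cur, target_sum = target_sum)
  sc <- marker_score(norm, panel)
  thrs <- lapply(seq_len(ncol(sc)), function(j) mixture_threshold(sc[, j]))
  names(thrs) <- colnames(sc)
  mi <- multi_identity_doublet_filter(sc, thrs)
  funnel <- log_stage("multi_identity_scores", nrow(cur$counts), length(mi$kept))
  cur <- subset_cells(cur, mi$kept)
  norm <- normalize_log(cur, target_sum = target_sum)

  kept <- regional_marker_filter(norm)
  funnel <- log_stage("regional_markers", nrow(cur$counts), length(kept))

  list(kept = kept, type = mi$type[kept], funnel = funnel,
       thresholds = thrs, poly_coeffs = co)
}
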