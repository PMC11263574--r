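#' Aggregate cells into pseudobulk profiles
#'
#' Sums raw counts over all cells of each (class, sample, region)
#' group; groups with fewer than `min_cells` cells are dropped.
#'
#' @param cm A [count_matrix()].
#' @param labels Named vector: cell id -> class.
#' @param min_cells Minimum cells per retained pseudobulk group.
#' @return A list with `counts` (group x gene dense integer matrix),
#'   `meta` (`data.frame`: class, sample_id, region, n_cells).
#' @export
aggregate_pseudobulk <- function(cm, labels, min_cells = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  cells <- intersect(names(labels), cm$cell_ids)
  meta <- cm$cell_meta[cells, , drop = FALSE]
  key <- paste(labels[cells], meta$sample_id, sep = "||")
  groups <- unique(key)
  mat <- matrix(0, length(groups), ncol(cm$counts),
                dimnames = list(groups, cm$gene_names))
  n_cells <- integer(length(groups))
  idx <- match(cells, cm$cell_ids)
  for (gi in seq_along(groups)) {
    rows <- idx[key == groups[gi]]
    mat[gi, ] <- Matrix::colSums(cm$counts[rows, , drop = FALSE])
    n_cells[gi] <- length(rows)
  }
  parts <- do.call(rbind, strsplit(groups, "||", fixed = TRUE))
  gmeta <- data.frame(class = parts[, 1], sample_id = parts[, 2],
                      region = meta$region[match(parts[, 2], meta$sample_id)],
                      n_cells = n_cells, stringsAsFactors = FALSE)
  keep <- gmeta$n_cells >= min_cells
  list(counts = mat[keep, , drop = FALSE], meta = gmeta[keep, , drop = FALSE])
}

# Maximum-likelihood NB mean fit for one group with offsets: solves the
# score equation sum (y - mu)/(1 + phi mu) = 0 for mu = s * exp(b) by
# Newton iteration on b.  Returns the fitted means.
.nb_fit_group <- function(y, s, phi, max_iter = 50, tol = 1e-10) {
  if (sum(y) == 0) return(rep(1e-8, length(y)))
  b <- log(sum(y) / sum(s))
  for (it in seq_len(max_iter)) {
    mu <- s * exp(b)
    f <- sum((y - mu) / (1 + phi * mu))
    fp <- -sum(mu * (1 + phi * y) / (1 + phi * mu)^2)
    if (abs(fp) < 1e-300) break
    step <- f / fp
    b <- b - step
    if (abs(step) < tol) break
  }
  s * exp(b)
}

# Cox-Reid adjusted profile log-likelihood of the NB dispersion phi for
# one gene under the region (two-group) design: the information matrix
# is block diagonal over groups, so its log-determinant is the sum of
# log summed working weights per group.
.nb_apl <- function(y, s, groups, log_phi) {
  phi <- exp(log_phi)
  theta <- 1 / phi
  mu <- numeric(length(y))
  logdet <- 0
  for (g in levels(groups)) {
    i <- groups == g
    mu[i] <- .nb_fit_group(y[i], s[i], phi)
    w <- mu[i] / (1 + phi * mu[i])
    logdet <- logdet + log(max(sum(w), 1e-300))
  }
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE)) - 0.5 * logdet
}

#' Pseudobulk differential expression by NB GLM likelihood-ratio test
#'
#' For one class, compares CN vs Pu pseudobulk profiles with a
#' negative-binomial GLM per gene: log link, library-size offsets
#' (optionally median-ratio scaled), genewise dispersion estimated by
#' Cox-Reid adjusted profile likelihood and shrunk toward the common
#' dispersion (log-scale weighted average, weight `shrink_weight`), and
#' a 1-df likelihood-ratio chi-square test of the region effect (the
#' two-group design makes the GLM separable into per-group mean fits).
#' Genes with all-zero counts are excluded; non-converging genes get
#' `p = NA` and are excluded from the BH denominator.
#'
#' @param pb A pseudobulk list from [aggregate_pseudobulk()], already
#'   restricted to one class.
#' @param shrink_weight Weight of the common dispersion in the
#'   log-scale shrinkage (0 = pure genewise, 1 = pure common).
#' @param median_ratio If `TRUE`, offsets are median-ratio scaled
#'   library sizes rather than raw totals.
#' @param prior_count Prior count used in the reported log2 fold change.
#' @return A `data.frame`: `gene`, `log2_fold` (CN vs Pu), `lrt`,
#'   `p`, `p_adj`, `dispersion`.
#' @export
nb_glm_lrt <- function(pb, shrink_weight = 0.5, median_ratio = FALSE,
                       prior_count = 0.5) {
  meta <- pb$meta
  if (length(unique(meta$class)) != 1)
    stop("nb_glm_lrt expects pseudobulk of a single class")
  if (any(table(meta$region) < 2) || length(unique(meta$region)) < 2)
    stop("need at least 2 samples per region")
  y_mat <- pb$counts
  lib <- rowSums(y_mat)
  sf <- rep(1, nrow(y_mat))
  if (median_ratio) {
    lg <- log(y_mat + 0.5)
    ref <- colMeans(lg)
    sf <- exp(apply(lg - matrix(ref, nrow(y_mat), ncol(y_mat), byrow = TRUE),
                    1, stats::median))
    sf <- sf / exp(mean(log(sf)))
  }
  sz <- lib * sf
  region <- factor(meta$region, levels = c("Pu", "CN"))
  nonzero <- colSums(y_mat) > 0
  genes <- colnames(y_mat)[nonzero]

  # genewise Cox-Reid APL dispersion under the full (two-group) model
  log_phi <- vapply(genes, function(g) {
    y <- y_mat[, g]
    opt <- tryCatch(
      stats::optimize(function(lp) -.nb_apl(y, sz, region, lp),
                      interval = c(log(1e-4), log(10)), tol = 1e-3),
      error = function(e) NULL)
    if (is.null(opt)) NA_real_ else opt$minimum
  }, 0)
  # common dispersion maximizes the APL summed over (a thinned subset
  # of) genes — much less biased than averaging noisy genewise values
  sub <- genes[seq(1, length(genes),
                   by = max(1L, floor(length(genes) / 500)))]
  common_opt <- stats::optimize(function(lp)
    -sum(vapply(sub, function(g) .nb_apl(y_mat[, g], sz, region, lp), 0)),
    interval = c(log(1e-4), log(10)), tol = 1e-3)
  common <- common_opt$minimum
  log_phi_shrunk <- (1 - shrink_weight) * log_phi + shrink_weight * common
  log_phi_shrunk[is.na(log_phi_shrunk)] <- common

  res <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    y <- y_mat[, g]
    phi <- exp(log_phi_shrunk[i])
    theta <- 1 / phi
    mu_full <- numeric(length(y))
    for (lev in levels(region)) {
      sel <- region == lev
      mu_full[sel] <- .nb_fit_group(y[sel], sz[sel], phi)
    }
    mu_null <- .nb_fit_group(y, sz, phi)
    ll <- function(mu) sum(stats::dnbinom(y, size = theta, mu = mu,
                                          log = TRUE))
    lrt <- 2 * (ll(mu_full) - ll(mu_null))
    if (!is.finite(lrt))
      return(data.frame(gene = g, log2_fold = NA_real_, lrt = NA_real_,
                        p = NA_real_, dispersion = phi,
                        stringsAsFactors = FALSE))
    cpm <- (y + prior_count) / sz
    mu_cn <- mean(cpm[region == "CN"]); mu_pu <- mean(cpm[region == "Pu"])
    data.frame(gene = g, log2_fold = log2(mu_cn / mu_pu),
               lrt = max(lrt, 0),
               p = stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
               dispersion = phi, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- NA_real_
  ok <- !is.na(res$p)
  res$p_adj[ok] <- stats::p.adjust(res$p[ok], "BH")
  rownames(res) <- NULL
  res
}

#' Select differentially expressed genes at the pipeline thresholds
#'
#' Up: adjusted p < `alpha` and log2 fold change > `lfc_min` (strict);
#' down symmetric with fold < `-lfc_min`.
#'
#' @param results A [nb_glm_lrt()] table.
#' @param lfc_min Log2 fold-change cutoff.
#' @param alpha Adjusted-p cutoff.
#' @return A list with `up` and `down` gene vectors.
#' @export
select_degs <- function(results, lfc_min = 0.5, alpha = 0.05) {
  ok <- !is.na(results$p_adj) & !is.na(results$log2_fold)
  up <- results$gene[ok & results$p_adj < alpha & results$log2_fold > lfc_min]
  down <- results$gene[ok & results$p_adj < alpha & results$log2_fold < -lfc_min]
  list(up = up, down = down)
}

#' Hypergeometric over-representation analysis
#'
#' Per term: upper-tail hypergeometric probability of observing at
#' least the overlap between the DEG list and the term's gene set,
#' given the universe; Benjamini-Hochberg adjustment across terms;
#' terms with raw p below `alpha_term` are flagged as selected.
#'
#' @param deg_list Character vector of differentially expressed genes
#'   (genes outside the universe are dropped with a warning).
#' @param collection A list with `sets` (named list of gene vectors,
#'   possibly with a `names` attribute of term descriptions) and
#'   `universe` (character vector).
#' @param alpha_term Raw-p selection threshold for reported terms.
#' @return A `data.frame`: `term`, `overlap`, `term_size`, `list_size`,
#'   `universe_size`, `p`, `p_adj`, `selected`.
#' @export
ora_hypergeometric <- function(deg_list, collection, alpha_term = 0.1) {
  universe <- unique(collection$universe)
  outside <- setdiff(deg_list, universe)
  if (length(outside))
    warning(length(outside), " DEG(s) outside the universe dropped")
  deg <- unique(intersect(deg_list, universe))
  n <- length(deg); N <- length(universe)
  sets <- lapply(collection$sets, function(s) unique(intersect(s, universe)))
  sets <- sets[lengths(sets) > 0]
  if (!length(sets) || n == 0)
    return(data.frame(term = character(), overlap = integer(),
                      term_size = integer(), list_size = integer(),
                      universe_size = integer(), p = numeric(),
                      p_adj = numeric(), selected = logical()))
  res <- data.frame(
    term = names(sets),
    overlap = vapply(sets, function(s) length(intersect(s, deg)), 0L),
    term_size = lengths(sets), list_size = n, universe_size = N,
    stringsAsFactors = FALSE, row.names = NULL)
  res$p <- stats::phyper(res$overlap - 1, res$term_size, N - res$term_size,
                         n, lower.tail = FALSE)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res$selected <- res$p < alpha_term
  res[order(res$p), ]
}

#' Read gene sets in GMT format
#'
#' @param path Path to a GMT file (term, description, genes...).
#' @param universe Gene universe to intersect sets with.
#' @return A collection list usable by [ora_hypergeometric()].
#' @export
read_gmt <- function(path, universe) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  list(sets = sets, universe = universe)
}
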