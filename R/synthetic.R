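#' Describe one planted cell population
#'
#' A population is a cluster of cells sharing an expression program:
#' a baseline transcriptome (partly shared with other populations in the
#' same `block`, which is what makes merged main classes emerge), a set
#' of marker genes elevated by `marker_log_fold` (natural-log units), an
#' optional within-population latent gradient, and optional planted
#' region-specific differential expression.
#'
#' @param name Population name (unique across populations).
#' @param markers Character vector of marker gene names; names not part
#'   of the standard universe are added to it.
#' @param marker_log_fold Elevation of marker-gene log-means (natural log).
#' @param proportion_by_region Named numeric, e.g. `c(CN = .1, Pu = .1)`:
#'   expected fraction of this population among the cells of a sample
#'   from that region.  Per-region proportions must sum to 1 over
#'   populations.
#' @param block Integer correlation block; populations sharing a block
#'   share part of their baseline log-mean profile and therefore merge
#'   into one main class downstream.
#' @param n_private_markers Number of additional auto-named private
#'   marker genes (`MK-<name>-k`) elevated for this population.
#' @param gradient Optional `list(genes =, weights =, scale =)` planting
#'   a latent factor: each cell of the population draws a latent value z
#'   uniform on \[-1, 1\] and its log-mean on `genes` is shifted by
#'   `z * scale * weights` (weights normalised to unit norm).
#' @param planted_de Optional `data.frame(gene, region, log2_fold)`:
#'   cells of this population in `region` have the gene's mean
#'   multiplied by `2^log2_fold`.
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, markers = character(), marker_log_fold = 2,
                            proportion_by_region = c(CN = NA_real_, Pu = NA_real_),
                            block = 1L, n_private_markers = 0L,
                            gradient = NULL, planted_de = NULL) {
  if (!is.null(gradient)) {
    stopifnot(is.list(gradient), length(gradient$genes) == length(gradient$weights))
    nrm <- sqrt(sum(gradient$weights^2))
    if (nrm == 0) stop("gradient weights must not be all zero")
    gradient$weights <- gradient$weights / nrm
    if (is.null(gradient$scale)) gradient$scale <- 1
  }
  structure(list(name = name, markers = markers,
                 marker_log_fold = marker_log_fold,
                 proportion_by_region = proportion_by_region,
                 block = as.integer(block),
                 n_private_markers = as.integer(n_private_markers),
                 gradient = gradient, planted_de = planted_de),
            class = "population_spec")
}

#' Configure the synthetic snRNA-seq generator
#'
#' Defines the study conditions a generated dataset emulates:
#' multi-sample two-region (caudate nucleus / putamen) UMI count data
#' with class-structured marker blocks, log-normal baseline gene means,
#' negative-binomial overdispersion, gamma library-size variation,
#' mitochondrial content, and optionally injected doublets.
#'
#' The per-gene log-mean of population p decomposes as
#' `b_g + sqrt(s) u_{g,block(p)} + sqrt(1-s) v_{g,p}` with
#' `b_g ~ N(0, baseline_sdlog^2)` shared by all populations,
#' block and private deviations `u, v ~ N(0, pop_sdlog^2)` and
#' `s = block_share`.  In log-expression space the expected Pearson
#' correlation between two population mean profiles is then
#' `(1 + s c)/(1 + c)` within a block and `1/(1 + c)` across blocks,
#' with `c = (pop_sdlog/baseline_sdlog)^2` — the knob that makes the
#' r > 0.49 merge rule separate blocks.
#'
#' @param n_genes Total genes in the universe (first 1\% are `MT-` named).
#' @param populations List of [population_spec()].
#' @param samples `data.frame` with columns `sample_id`, `region`
#'   (in `c("CN","Pu")`) and `n_cells`.
#' @param mean_library_size Expected UMIs per cell.
#' @param library_size_dispersion Squared coefficient of variation of the
#'   gamma-distributed per-cell library size.
#' @param nb_dispersion Negative-binomial overdispersion phi
#'   (`variance = mu + phi mu^2`), global across genes.
#' @param doublet_rate Fraction of doublets injected on top (see
#'   [inject_doublets()]); 0 disables.
#' @param mito_fraction_mean Expected fraction of counts on `MT-` genes.
#' @param baseline_sdlog,pop_sdlog,block_share Parameters of the
#'   log-mean decomposition above.
#' @param silenced_genes Gene names forced to (near) zero expression in
#'   every population that does not mark them — used for lineage markers
#'   foreign to the simulated populations so that contamination filters
#'   have nothing to remove by construction.
#' @param seed Integer seed; every generator output is a pure function of
#'   `(config, seed)`.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_genes, populations, samples,
                             mean_library_size = 40000,
                             library_size_dispersion = 0.15,
                             nb_dispersion = 0.1,
                             doublet_rate = 0,
                             mito_fraction_mean = 0.03,
                             baseline_sdlog = 1.0,
                             pop_sdlog = 1.5,
                             block_share = 0.6,
                             silenced_genes = character(),
                             seed = 0L) {
  if (length(populations) == 0) stop("populations: must contain at least one population")
  if (n_genes <= 0) stop("n_genes: must be positive")
  nms <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("populations: names must be unique")
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "region", "n_cells") %in% names(samples)))
  if (!all(samples$region %in% c("CN", "Pu")))
    stop("samples$region: must be 'CN' or 'Pu'")
  if (!(doublet_rate >= 0 && doublet_rate < 0.5))
    stop("doublet_rate: must be in [0, 0.5)")
  for (reg in unique(samples$region)) {
    tot <- sum(vapply(populations,
                      function(p) p$proportion_by_region[[reg]], 0))
    if (abs(tot - 1) > 1e-6)
      stop(sprintf("proportion_by_region: proportions for region %s sum to %.4f, not 1",
                   reg, tot))
  }
  structure(list(n_genes = as.integer(n_genes), populations = populations,
                 samples = samples, mean_library_size = mean_library_size,
                 library_size_dispersion = library_size_dispersion,
                 nb_dispersion = nb_dispersion, doublet_rate = doublet_rate,
                 mito_fraction_mean = mito_fraction_mean,
                 baseline_sdlog = baseline_sdlog, pop_sdlog = pop_sdlog,
                 block_share = block_share,
                 silenced_genes = silenced_genes, seed = as.integer(seed)),
            class = "generator_config")
}

# Build the gene-name universe: MT- genes first (1% of universe), then every
# named marker / silenced / private-marker gene, then anonymous filler.
.build_gene_universe <- function(config) {
  n <- config$n_genes
  n_mito <- ceiling(0.01 * n)
  named <- unique(c(unlist(lapply(config$populations, `[[`, "markers")),
                    config$silenced_genes,
                    unlist(lapply(config$populations, function(p)
                      if (p$n_private_markers > 0)
                        sprintf("MK-%s-%02d", gsub("[^A-Za-z0-9]", "", p$name),
                                seq_len(p$n_private_markers)) else character())),
                    unlist(lapply(config$populations, function(p)
                      if (!is.null(p$planted_de)) p$planted_de$gene else character())),
                    unlist(lapply(config$populations, function(p)
                      if (!is.null(p$gradient)) p$gradient$genes else character()))))
  named <- setdiff(named, sprintf("MT-%03d", seq_len(n_mito)))
  if (n_mito + length(named) > n)
    stop("n_genes too small for the named genes in the configuration")
  c(sprintf("MT-%03d", seq_len(n_mito)), named,
    sprintf("G%05d", seq_len(n - n_mito - length(named))))
}

#' Generate a synthetic snRNA-seq dataset with ground truth
#'
#' Draws cells sample by sample: population assignment is multinomial on
#' the region's planted proportions, the library size is gamma, and
#' counts are negative binomial around the population's mean profile
#' (marker elevation, latent-gradient shift and planted regional DE
#' applied on the log-mean).  Mitochondrial genes are rescaled so their
#' expected share of counts equals `mito_fraction_mean`.  If
#' `doublet_rate > 0`, [inject_doublets()] is applied with the same seed.
#'
#' @param config A [generator_config()].
#' @return A list with `counts` (a [count_matrix()]) and `truth` (a
#'   `data.frame` with one row per cell: `cell_id`, `population`,
#'   `parent_populations`, `sample_id`, `region`, `latent_factor_value`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  genes <- .build_gene_universe(config)
  n_genes <- length(genes)
  n_mito <- ceiling(0.01 * n_genes)
  pops <- config$populations
  n_pop <- length(pops)
  pop_names <- vapply(pops, `[[`, "", "name")
  blocks <- vapply(pops, `[[`, 0L, "block")

  # log-mean construction: baseline + block-shared + private deviations
  b <- stats::rnorm(n_genes, 0, config$baseline_sdlog)
  silenced <- genes %in% config$silenced_genes
  b[silenced] <- -12
  u <- matrix(stats::rnorm(n_genes * length(unique(blocks)), 0, config$pop_sdlog),
              n_genes, length(unique(blocks)))
  colnames(u) <- as.character(sort(unique(blocks)))
  logmu <- matrix(0, n_genes, n_pop, dimnames = list(genes, pop_names))
  for (j in seq_len(n_pop)) {
    v <- stats::rnorm(n_genes, 0, config$pop_sdlog)
    dev <- sqrt(config$block_share) * u[, as.character(blocks[j])] +
      sqrt(1 - config$block_share) * v
    lm <- b + dev
    lm[silenced] <- -12          # deviations never resurrect silenced genes
    mk <- match(pops[[j]]$markers, genes)
    pm <- if (pops[[j]]$n_private_markers > 0)
      match(sprintf("MK-%s-%02d", gsub("[^A-Za-z0-9]", "", pops[[j]]$name),
                    seq_len(pops[[j]]$n_private_markers)), genes) else integer()
    mk <- c(mk, pm)
    # markers of silenced genes come up from zero to a typical level + fold
    lm[mk] <- pmax(lm[mk], 0) + pops[[j]]$marker_log_fold
    logmu[, j] <- lm
  }
  # rescale MT- genes so their expected count share is mito_fraction_mean
  for (j in seq_len(n_pop)) {
    w <- exp(logmu[, j])
    mt <- seq_len(n_mito)
    s_mt <- sum(w[mt]); s_rest <- sum(w[-mt])
    target <- config$mito_fraction_mean
    w[mt] <- w[mt] * (target / (1 - target)) * s_rest / s_mt
    logmu[, j] <- log(w)
  }

  lib_shape <- 1 / config$library_size_dispersion
  size_nb <- 1 / config$nb_dispersion

  counts_list <- list(); truth_list <- list()
  for (s in seq_len(nrow(config$samples))) {
    sid <- config$samples$sample_id[s]
    reg <- config$samples$region[s]
    n_cells <- config$samples$n_cells[s]
    props <- vapply(pops, function(p) p$proportion_by_region[[reg]], 0)
    n_by_pop <- as.vector(stats::rmultinom(1, n_cells, props))
    pop_of_cell <- rep(seq_len(n_pop), n_by_pop)
    libs <- stats::rgamma(n_cells, shape = lib_shape,
                          rate = lib_shape / config$mean_library_size)
    z <- rep(NA_real_, n_cells)
    cnt <- matrix(0L, n_cells, n_genes)
    for (j in seq_len(n_pop)) {
      idx <- which(pop_of_cell == j)
      if (!length(idx)) next
      lmj <- logmu[, j]
      if (!is.null(pops[[j]]$planted_de)) {
        de <- pops[[j]]$planted_de
        hit <- de$region == reg
        if (any(hit)) {
          gi <- match(de$gene[hit], genes)
          lmj[gi] <- lmj[gi] + de$log2_fold[hit] * log(2)
        }
      }
      base_pi <- exp(lmj)
      grad <- pops[[j]]$gradient
      gi <- if (!is.null(grad)) match(grad$genes, genes) else integer()
      if (is.null(grad)) {
        pii <- base_pi / sum(base_pi)
        mu <- libs[idx] %o% pii
        cnt[idx, ] <- stats::rnbinom(length(mu), mu = mu, size = size_nb)
      } else {
        z[idx] <- stats::runif(length(idx), -1, 1)
        for (i in idx) {
          pii <- base_pi
          pii[gi] <- pii[gi] * exp(z[i] * grad$scale * grad$weights)
          pii <- pii / sum(pii)
          cnt[i, ] <- stats::rnbinom(n_genes, mu = libs[i] * pii, size = size_nb)
        }
      }
    }
    ids <- sprintf("%s_C%04d", sid, seq_len(n_cells))
    counts_list[[s]] <- cnt
    truth_list[[s]] <- data.frame(
      cell_id = ids, population = pop_names[pop_of_cell],
      parent_populations = NA_character_, sample_id = sid, region = reg,
      latent_factor_value = z, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_list)
  cm <- count_matrix(do.call(rbind, counts_list), truth$cell_id, genes,
                     truth[, c("sample_id", "region")])
  out <- list(counts = cm, truth = truth)
  if (config$doublet_rate > 0)
    out <- inject_doublets(out$counts, out$truth, config$doublet_rate,
                           seed = config$seed + 1L)
  out
}

#' Inject artificial doublets by summing same-sample cell pairs
#'
#' Appends `floor(rate * n_cells)` new cells; each is the element-wise
#' sum of two distinct randomly chosen cells from the same sample
#' (allocated across samples by largest remainder).  Truth records flag
#' them with `population == "doublet"` and the two parent populations.
#'
#' @param counts A [count_matrix()].
#' @param truth Matching truth `data.frame` (see [generate_dataset()]).
#' @param rate Doublet fraction in `[0, 0.5)` relative to input cells.
#' @param seed Integer seed.
#' @return A list with augmented `counts` and `truth`.
#' @export
inject_doublets <- function(counts, truth, rate, seed = 0L) {
  stopifnot(inherits(counts, "count_matrix"), rate >= 0, rate < 0.5)
  if (rate == 0) return(list(counts = counts, truth = truth))
  set.seed(seed)
  n_total <- nrow(counts$counts)
  n_target <- floor(rate * n_total)
  samp <- counts$cell_meta$sample_id
  tab <- table(samp)
  eligible <- names(tab)[tab >= 2]
  if (length(eligible) < length(tab))
    warning("samples with fewer than 2 cells skipped for doublet injection: ",
            paste(setdiff(names(tab), eligible), collapse = ", "))
  quota <- n_target * tab[eligible] / sum(tab[eligible])
  n_s <- floor(quota)
  rem <- n_target - sum(n_s)
  if (rem > 0) {
    ord <- order(quota - n_s, decreasing = TRUE)
    n_s[ord[seq_len(rem)]] <- n_s[ord[seq_len(rem)]] + 1
  }
  new_rows <- list(); new_truth <- list(); k <- 0L
  for (sid in eligible) {
    idx <- which(samp == sid)
    if (n_s[[sid]] == 0) next
    pairs <- vapply(seq_len(n_s[[sid]]), function(i) sample(idx, 2), integer(2))
    m <- counts$counts[pairs[1, ], , drop = FALSE] +
      counts$counts[pairs[2, ], , drop = FALSE]
    rownames(m) <- sprintf("%s_DBL%04d", sid, k + seq_len(ncol(pairs)))
    new_rows[[sid]] <- m
    new_truth[[sid]] <- data.frame(
      cell_id = rownames(m), population = "doublet",
      parent_populations = paste(truth$population[pairs[1, ]],
                                 truth$population[pairs[2, ]], sep = "+"),
      sample_id = sid,
      region = counts$cell_meta$region[idx[1]],
      latent_factor_value = NA_real_, stringsAsFactors = FALSE)
    k <- k + ncol(pairs)
  }
  add <- do.call(rbind, new_rows)
  addt <- do.call(rbind, new_truth)
  all_counts <- rbind(counts$counts, add)
  all_truth <- rbind(truth, addt)
  cm <- count_matrix(all_counts, all_truth$cell_id, counts$gene_names,
                     all_truth[, c("sample_id", "region")])
  list(counts = cm, truth = all_truth)
}

#' Generate spatial coordinates with planted co-localization
#'
#' Places cells in a square field of side `field_size` (micrometres).
#' Cells of classes not named in `colocal_pairs` are uniform; for a pair
#' `(A, B, strength)`, each B cell is placed, with probability
#' `strength / (1 + strength)`, as a Gaussian displacement
#' (sd = `field_size / 50`) from a randomly chosen A cell, and uniformly
#' otherwise, so `strength = 0` recovers complete spatial randomness and
#' large strength gives tight attraction.
#'
#' @param labels Character vector of per-cell class labels.
#' @param colocal_pairs List of `list(a =, b =, strength =)` entries.
#' @param field_size Side of the square field.
#' @param seed Integer seed.
#' @return A `data.frame` with `cell_id`, `x`, `y`, `label`.
#' @export
generate_spatial <- function(labels, colocal_pairs = list(),
                             field_size = 1000, seed = 0L) {
  set.seed(seed)
  n <- length(labels)
  known <- unique(labels)
  for (p in colocal_pairs) {
    stopifnot(p$strength >= 0)
    if (!all(c(p$a, p$b) %in% known))
      stop("unknown class name in colocal_pairs: ",
           paste(setdiff(c(p$a, p$b), known), collapse = ", "))
  }
  x <- stats::runif(n, 0, field_size)
  y <- stats::runif(n, 0, field_size)
  for (p in colocal_pairs) {
    a_idx <- which(labels == p$a)
    b_idx <- which(labels == p$b)
    attract <- stats::runif(length(b_idx)) < p$strength / (1 + p$strength)
    anchors <- sample(a_idx, sum(attract), replace = TRUE)
    sdev <- field_size / 50
    x[b_idx[attract]] <- pmin(pmax(x[anchors] + stats::rnorm(sum(attract), 0, sdev), 0), field_size)
    y[b_idx[attract]] <- pmin(pmax(y[anchors] + stats::rnorm(sum(attract), 0, sdev), 0), field_size)
  }
  data.frame(cell_id = sprintf("SP%05d", seq_len(n)), x = x, y = y,
             label = labels, stringsAsFactors = FALSE)
}

#' Write a generated dataset (counts + truth) to a directory
#'
#' Writes `matrix.mtx`, `cells.tsv`, `genes.tsv` (via
#' [write_count_matrix()]) and `truth.tsv`.
#'
#' @param dataset A list with `counts` and `truth` as returned by
#'   [generate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  write_count_matrix(dataset$counts, dir)
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
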