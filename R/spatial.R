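#' Annotate spatial cells by hierarchical marker gating
#'
#' Counts-based gating on a targeted spatial panel: a cell is a neuron
#' iff `GAD1 >= pos_count` and both `OLIG1` and `MOBP` are below
#' `neg_count`; an interneuron iff additionally `LHX6` or `SST` reach
#' `pos_count` and `MEIS2` stays below `neg_count`; interneurons are
#' then assigned the first subclass row of `subclass_table` whose
#' required markers all reach their minimum copy numbers, and
#' `"unassigned"` if none matches (detection-limited cells).
#'
#' @param expr Cell x gene matrix of raw spatial transcript counts.
#' @param pos_count Minimum copies for a positive gate.
#' @param neg_count Copies at or above which a negative gate fails.
#' @param subclass_table `data.frame` with columns `subclass`,
#'   `markers` (comma-separated) and `min_count`; default read from the
#'   packaged best-effort table.
#' @return Character vector of per-cell labels: `"non-neuron"`,
#'   `"neuron"`, `"unassigned"` or a subclass name.
#' @export
annotate_spatial_cells <- function(expr, pos_count = 3, neg_count = 1,
                                   subclass_table = default_spatial_subclass_table()) {
  need <- c("GAD1", "OLIG1", "MOBP", "LHX6", "SST", "MEIS2")
  missing <- setdiff(need, colnames(expr))
  if (length(missing))
    stop("gating gene(s) missing from the spatial panel: ",
         paste(missing, collapse = ", "))
  expr <- as.matrix(expr)
  lab <- rep("non-neuron", nrow(expr))
  neuron <- expr[, "GAD1"] >= pos_count &
    expr[, "OLIG1"] < neg_count & expr[, "MOBP"] < neg_count
  lab[neuron] <- "neuron"
  inter <- neuron & (expr[, "LHX6"] >= pos_count | expr[, "SST"] >= pos_count) &
    expr[, "MEIS2"] < neg_count
  lab[inter] <- "unassigned"
  for (i in seq_len(nrow(subclass_table))) {
    mk <- strsplit(subclass_table$markers[i], ",")[[1]]
    mk <- intersect(mk, colnames(expr))
    if (!length(mk)) next
    ok <- inter & lab == "unassigned" &
      rowSums(expr[, mk, drop = FALSE] >= subclass_table$min_count[i]) == length(mk)
    lab[ok] <- subclass_table$subclass[i]
  }
  lab
}

#' Best-effort spatial subclass marker-positivity table
#'
#' One row per interneuron subclass with the required positive markers
#' and minimum copy number.  This table is a synthetic best-effort
#' rendering of the taxonomy's marker structure for targeted panels and
#' is meant to be edited per panel; it is shipped as
#' `extdata/default_subclass_markers.tsv`.
#'
#' @return A `data.frame` with `subclass`, `markers`, `min_count`.
#' @export
default_spatial_subclass_table <- function() {
  path <- system.file("extdata", "default_subclass_markers.tsv",
                      package = "striatax")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build an undirected spatial neighbour graph
#'
#' Symmetrized (union) k-nearest-neighbour graph on 2-D coordinates.
#' `method` is recorded on the result; only `"knn"` is currently
#' available (no Delaunay triangulation backend is bundled).
#'
#' @param coords Two-column matrix or data.frame of coordinates.
#' @param method Graph construction method.
#' @param k Neighbours per cell.
#' @return An `igraph` graph with a `method` attribute.
#' @export
build_neighbor_graph <- function(coords, method = "knn", k = 6) {
  coords <- as.matrix(coords[, 1:2])
  if (nrow(coords) < 3) stop("need at least 3 cells")
  method <- match.arg(method, "knn")
  g <- .knn_graph(coords, k = min(k, nrow(coords) - 1))
  igraph::graph_attr(g, "method") <- method
  g
}

#' Permutation-based spatial neighborhood enrichment
#'
#' Observed statistic: number of graph edges joining each pair of
#' labels (diagonal included).  Null: the label vector is permuted over
#' the fixed graph `n_perm` times; `z = (observed - mean) / sd` of the
#' permuted counts.  Pairs with zero permutation sd get `z = 0` and are
#' flagged.
#'
#' @param graph An undirected `igraph` graph over the cells.
#' @param labels Per-cell labels (graph vertex order).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list with `z`, `observed`, `perm_mean`, `perm_sd`
#'   (label x label matrices), `degenerate` (logical matrix),
#'   `n_perm`, `seed`.
#' @export
neighborhood_enrichment <- function(graph, labels, n_perm = 1000, seed = 0L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 distinct labels")
  el <- igraph::as_edgelist(graph, names = FALSE)
  lv <- sort(unique(labels))
  count_pairs <- function(lab) {
    a <- lab[el[, 1]]; b <- lab[el[, 2]]
    lo <- pmin(a, b); hi <- pmax(a, b)
    tab <- table(factor(lo, lv), factor(hi, lv))
    m <- matrix(tab, length(lv), length(lv), dimnames = dimnames(tab))
    m[lower.tri(m)] <- 0
    m + t(m * upper.tri(m))          # symmetric, diagonal kept once
  }
  obs <- count_pairs(labels)
  set.seed(seed)
  acc <- matrix(0, length(lv), length(lv))
  acc2 <- matrix(0, length(lv), length(lv))
  for (i in seq_len(n_perm)) {
    m <- count_pairs(sample(labels))
    acc <- acc + m
    acc2 <- acc2 + m^2
  }
  mu <- acc / n_perm
  sd_ <- sqrt(pmax(acc2 / n_perm - mu^2, 0) * n_perm / (n_perm - 1))
  z <- (obs - mu) / sd_
  degen <- sd_ == 0
  z[degen] <- 0
  dimnames(z) <- dimnames(mu) <- dimnames(sd_) <- dimnames(obs)
  list(z = z, observed = obs, perm_mean = mu, perm_sd = sd_,
       degenerate = degen, n_perm = n_perm, seed = seed)
}
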