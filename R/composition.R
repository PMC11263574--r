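#' Per-sample class composition
#'
#' Counts cells per (sample, class) and converts to fractions of the
#' sample's total.  Classes absent from a sample are recorded with
#' count 0 before any pseudocounting.
#'
#' @param labels Named character/integer vector: cell id -> class.
#' @param cell_meta `data.frame` with rownames = cell ids and columns
#'   `sample_id`, `region`.
#' @return A long-format `data.frame`: `sample_id`, `region`, `class`,
#'   `count`, `fraction`.
#' @export
class_fractions <- function(labels, cell_meta) {
  meta <- cell_meta[names(labels), , drop = FALSE]
  classes <- sort(unique(as.character(labels)))
  samples <- unique(meta[, c("sample_id", "region")])
  out <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    in_s <- meta$sample_id == sid
    n_s <- sum(in_s)
    if (n_s == 0) { warning("sample ", sid, " has no cells; dropped"); next }
    cnt <- vapply(classes, function(cl)
      sum(as.character(labels)[in_s] == cl), 0)
    out[[i]] <- data.frame(sample_id = sid, region = samples$region[i],
                           class = classes, count = cnt,
                           fraction = cnt / n_s,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Centered log-ratio transform of class compositions
#'
#' Per sample: counts are pseudocounted, fractions recomputed, and
#' `CLR_x = log(r_x / g)` with `r_x` the class fraction and `g` the
#' geometric mean of all class fractions in that sample (natural log).
#' CLR values of a sample sum to zero by construction.
#'
#' @param table Output of [class_fractions()].
#' @param pseudocount Added to every class count before recomputing
#'   fractions; must be positive if any class has count zero.
#' @return `table` with columns `fraction_pc` (pseudocounted fraction)
#'   and `clr` appended.
#' @export
compute_clr <- function(table, pseudocount = 0.5) {
  stopifnot(all(c("sample_id", "class", "count") %in% names(table)))
  if (any(table$count == 0) && pseudocount <= 0)
    stop("zero counts present: a positive pseudocount is required")
  out <- table
  out$fraction_pc <- NA_real_; out$clr <- NA_real_
  for (sid in unique(out$sample_id)) {
    i <- out$sample_id == sid
    cnt <- out$count[i] + pseudocount
    r <- cnt / sum(cnt)
    g <- exp(mean(log(r)))
    out$fraction_pc[i] <- r
    out$clr[i] <- log(r / g)
  }
  out
}

#' Compare class CLR values between regions by Wilcoxon rank-sum
#'
#' Per class, a two-sided unpaired Wilcoxon rank-sum test of the CLR
#' values of CN samples against Pu samples (exact distribution for
#' small, untied samples via [stats::wilcox.test()]; normal
#' approximation with tie correction otherwise).  A class with
#' identical CLR in every sample gets p = 1.
#'
#' @param table Output of [compute_clr()].
#' @return A `data.frame`: `class`, `statistic` (rank-sum W), `p`,
#'   `p_adj` (Benjamini-Hochberg across classes).
#' @export
region_composition_test <- function(table) {
  stopifnot("clr" %in% names(table))
  per_region <- table(unique(table[, c("sample_id", "region")])$region)
  if (any(!c("CN", "Pu") %in% names(per_region)) || any(per_region < 3))
    stop("need at least 3 samples per region")
  classes <- unique(table$class)
  res <- lapply(classes, function(cl) {
    sub <- table[table$class == cl, ]
    x <- sub$clr[sub$region == "CN"]
    y <- sub$clr[sub$region == "Pu"]
    if (stats::sd(c(x, y)) < 1e-12)
      return(data.frame(class = cl, statistic = NA_real_, p = 1))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = (length(x) + length(y) <= 25)))
    data.frame(class = cl, statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res
}
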