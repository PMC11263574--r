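#' Canonical marker panel for broad striatal cell types
#'
#' The panel used both for QC marker scores and for labeling broad
#' Louvain clusters: astrocytes (AQP4, ADGRV1), microglia (CSF1R, FYB1),
#' oligodendrocytes (MBP, MOG, MAG), oligodendrocyte precursors (PTPRZ1,
#' PDGFRA, VCAN), vascular cells (EBF1, ABCB1, ABCA9) and neurons (MEG3).
#'
#' @return Named list mapping cell-type name to marker gene names.
#' @export
default_marker_panel <- function() {
  list(astrocytes = c("AQP4", "ADGRV1"),
       microglia = c("CSF1R", "FYB1"),
       oligodendrocytes = c("MBP", "MOG", "MAG"),
       OPC = c("PTPRZ1", "PDGFRA", "VCAN"),
       vascular = c("EBF1", "ABCB1", "ABCA9"),
       neurons = "MEG3")
}

#' QC thresholds of the quality-control cascade
#'
#' Defaults: cells with fewer than 500 UMIs or 1200 genes, more than
#' 250,000 UMIs, more than 15,000 genes, or more than 10\% mitochondrial
#' content are discarded; neurons are re-filtered at 5000 UMIs and
#' 3000--12,000 genes; doublet consensus discards cells flagged on more
#' than 10\% of scorer runs; the gene--UMI relation is modelled as a
#' degree-2 polynomial with outliers beyond 2000 genes of deviation
#' removed.  All bounds use strict-exceedance semantics ("less than" /
#' "more than"), so a cell sitting exactly on a printed bound is kept.
#'
#' @param ... Named overrides of any default.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(...) {
  t <- list(min_umis = 500, min_genes = 1200, max_umis = 250000,
            max_genes = 15000, max_mito = 0.10,
            neuron_min_umis = 5000, neuron_min_genes = 3000,
            neuron_max_genes = 12000,
            doublet_vote_fraction = 0.10, n_doublet_runs = 100,
            doublet_expected_rate = 0.06,
            poly_degree = 2, poly_outlier_delta = 2000,
            poly_delta_unit = c("genes", "log"))
  over <- list(...)
  stopifnot(all(names(over) %in% names(t)))
  t[names(over)] <- over
  t$poly_delta_unit <- match.arg(t$poly_delta_unit[1], c("genes", "log"))
  stopifnot(t$min_umis < t$max_umis, t$min_genes < t$max_genes,
            t$max_mito > 0, t$max_mito < 1,
            t$doublet_vote_fraction > 0, t$doublet_vote_fraction < 1)
  structure(t, class = "qc_thresholds")
}

# The 14 interneuron subclasses and their 8 main classes (= correlation
# blocks), with the named markers that also drive the gating stages.
.subclass_table <- function() {
  data.frame(
    subclass = c("CCK/VIP", "CCK/VIP/CXCL14", "CCK", "CCK/CHST9",
                 "PVALB", "PVALB/GRIK3", "SST/GRIK3",
                 "SST/NPY", "SST/NPY/DACH1",
                 "PTHLH", "PTHLH/MOXD1", "CHAT", "TAC3", "TAC3/SEMA3A"),
    class = c("CCK/VIP", "CCK/VIP", "CCK", "CCK",
              "PVALB", "PVALB", "SST/GRIK3",
              "SST/NPY", "SST/NPY",
              "PTHLH", "PTHLH", "CHAT", "TAC3", "TAC3"),
    block = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 5L, 5L, 6L, 6L, 7L, 8L, 8L),
    markers = c("ADARB2,CCK,VIP,CALB2", "ADARB2,CCK,VIP,CXCL14",
                "ADARB2,CCK", "ADARB2,CCK,CHST9,CALB1",
                "PVALB", "PVALB,GRIK3", "SST,GRIK3",
                "SST,NPY,NOS1", "SST,NPY,NOS1,DACH1",
                "PTHLH,OPN3", "PTHLH,OPN3,MOXD1", "CHAT,SLC5A7",
                "TAC3,PTPRK", "TAC3,PTPRK,SEMA3A"),
    stringsAsFactors = FALSE)
}

# Lineage genes that striatal interneurons must not express; silenced in
# the default simulations so that the contamination gates are exercised
# but remove nothing by construction.
.foreign_lineage_genes <- function() {
  c("PPP1R1B", "DRD1", "DRD2", "MEIS2", "RORB",          # MSN / excitatory
    "NEUROD2", "TMEM155", "CARTPT", "SLC17A7",           # regional contamination
    "AQP4", "ADGRV1", "CSF1R", "FYB1", "MBP", "MOG", "MAG",
    "PTPRZ1", "PDGFRA", "VCAN", "EBF1", "ABCB1", "ABCA9",# glial/vascular panels
    "OLIG1", "MOBP", "LHX6")                             # spatial gating extras
}

#' Default taxonomy simulation: one population per interneuron subclass
#'
#' The bundled study conditions for the taxonomy stages: 14 well-separated
#' interneuron populations (one per subclass of the reference taxonomy,
#' each with its named markers plus 20 private markers), grouped into the
#' 8 main classes as correlation blocks; 10 samples (5 caudate nucleus,
#' 5 putamen) of 560 cells; 5000 genes; 5\% injected doublets; a mild
#' planted regional proportion shift (TAC3 higher in CN, CCK/VIP higher
#' in Pu); a planted latent gradient inside the PTHLH population; and
#' eight planted regional DE genes (log2 fold 1.5, CN up) in the PTHLH
#' population.
#'
#' @param seed Integer seed.
#' @param n_cells_per_sample Cells per sample before doublet injection.
#' @param doublet_rate Injected doublet fraction.
#' @return A [generator_config()].
#' @export
default_taxonomy_config <- function(seed = 0L, n_cells_per_sample = 560,
                                    doublet_rate = 0.05) {
  tab <- .subclass_table()
  base <- c(0.10, 0.06, 0.08, 0.06, 0.07, 0.06, 0.06,
            0.07, 0.06, 0.10, 0.055, 0.07, 0.10, 0.055)
  stopifnot(abs(sum(base) - 1) < 1e-9, length(base) == nrow(tab))
  cn <- base; pu <- base
  # planted compositional shift: TAC3 enriched in CN, CCK/VIP in Pu
  i_tac3 <- which(tab$subclass == "TAC3"); i_cckvip <- which(tab$subclass == "CCK/VIP")
  cn[i_tac3] <- cn[i_tac3] + 0.02; cn[i_cckvip] <- cn[i_cckvip] - 0.02
  pu[i_tac3] <- pu[i_tac3] - 0.02; pu[i_cckvip] <- pu[i_cckvip] + 0.02
  de_genes <- sprintf("RDE-%02d", 1:8)
  pops <- lapply(seq_len(nrow(tab)), function(i) {
    named <- strsplit(tab$markers[i], ",")[[1]]
    inhib <- if (tab$subclass[i] == "CHAT") character() else c("GAD1", "GAD2")
    pop <- population_spec(
      name = tab$subclass[i],
      markers = c("MEG3", inhib, named),
      marker_log_fold = 2.5,
      proportion_by_region = c(CN = cn[i], Pu = pu[i]),
      block = tab$block[i],
      n_private_markers = 20,
      gradient = if (tab$subclass[i] == "PTHLH")
        list(genes = sprintf("GRAD-%03d", 1:150),
             weights = rep(1, 150), scale = 8) else NULL,
      planted_de = if (tab$subclass[i] == "PTHLH")
        data.frame(gene = de_genes, region = "CN", log2_fold = 1.5,
                   stringsAsFactors = FALSE) else NULL)
    pop
  })
  samples <- data.frame(
    sample_id = sprintf("S%02d", 1:10),
    region = rep(c("CN", "Pu"), each = 5),
    n_cells = n_cells_per_sample, stringsAsFactors = FALSE)
  generator_config(
    n_genes = 5000, populations = pops, samples = samples,
    doublet_rate = doublet_rate,
    silenced_genes = .foreign_lineage_genes(), seed = seed)
}

#' Default QC simulation: broad, well-separated cell types
#'
#' A small mixed-tissue dataset for exercising the QC cascade end to
#' end: five well-separated populations (astrocytes, oligodendrocytes,
#' microglia, OPCs and inhibitory neurons) in roughly striatal
#' proportions, 4 samples (2 per region), with injected doublets.
#'
#' @param seed Integer seed.
#' @param n_cells_per_sample Cells per sample before doublet injection.
#' @param doublet_rate Injected doublet fraction.
#' @return A [generator_config()].
#' @export
default_qc_config <- function(seed = 0L, n_cells_per_sample = 400,
                              doublet_rate = 0.05) {
  panel <- default_marker_panel()
  mk <- function(type, extra = character())
    c(panel[[type]], extra)
  props <- c(astrocytes = 0.25, oligodendrocytes = 0.25, microglia = 0.15,
             OPC = 0.15, neurons = 0.20)
  pops <- lapply(names(props), function(ty)
    population_spec(name = ty,
                    markers = mk(ty, if (ty == "neurons") c("GAD1", "GAD2") else character()),
                    marker_log_fold = 3,
                    proportion_by_region = c(CN = props[[ty]], Pu = props[[ty]]),
                    block = match(ty, names(props)),
                    n_private_markers = 25))
  samples <- data.frame(sample_id = sprintf("Q%02d", 1:4),
                        region = rep(c("CN", "Pu"), each = 2),
                        n_cells = n_cells_per_sample, stringsAsFactors = FALSE)
  generator_config(n_genes = 3000, populations = pops, samples = samples,
                   doublet_rate = doublet_rate,
                   silenced_genes = unique(c(.foreign_lineage_genes(),
                                             unlist(panel))),
                   seed = seed)
}
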