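# Functional-gene and enzyme processing: QMEC HT-qPCR Ct filtering and
# relative copy numbers, qPCR biomass on the log10 scale, eco-enzymatic
# stoichiometry ratios, and protist trophic-group profiling.

#' QMEC relative copy numbers with detection and efficiency filters
#'
#' An entry is detected only when its Ct lies strictly below the detection
#' limit (Ct of exactly 31 counts as absent), its amplification efficiency
#' falls inside `eff_range`, and (when supplied) its melting curve is clean.
#' Detected entries get the chip's relative copy number
#' `10^((ct_limit - Ct) / divisor)` with `divisor = 10/3`; absent entries
#' are reported as 0 with a `FALSE` presence mask.
#'
#' @param ct Gene x sample Ct matrix (all values > 0).
#' @param efficiency Congruent matrix of amplification efficiencies.
#' @param ct_limit Detection limit on Ct (default 31).
#' @param eff_range Inclusive efficiency acceptance range (default 1.8-2.2).
#' @param melt_ok Optional congruent logical matrix from upstream melting
#'   curve review; `FALSE` entries are excluded.
#' @param divisor Denominator of the exponent (default `10/3`); exposed so
#'   an alternative delta-Ct convention can be configured.
#' @param normalize_16s Divide each gene's relative copies by the sample's
#'   16S row (row named `"16S"`) to express copies per 16S.
#' @param genes Optional gene panel data frame (`gene`, `cycle_group`)
#'   for per-cycle aggregation; defaults to [qmec_gene_panel()] when the
#'   row names match it.
#' @return A list of class `"qmec_result"`: `copies` (gene x sample),
#'   `present` (logical mask), `cycle_group` (per gene), and `cycle_sums`
#'   (cycle group x sample totals, 16S excluded).
#' @export
qmec_relative_copies <- function(ct, efficiency, ct_limit = 31,
                                 eff_range = c(1.8, 2.2), melt_ok = NULL,
                                 divisor = 10 / 3, normalize_16s = FALSE,
                                 genes = NULL) {
  if (!all(dim(ct) == dim(efficiency)))
    stop("ct and efficiency matrices differ in shape")
  if (ct_limit <= 0) stop("ct_limit must be positive")
  if (any(ct <= 0)) stop("Ct values must be positive")
  present <- ct < ct_limit &
    efficiency >= eff_range[1] & efficiency <= eff_range[2]
  if (!is.null(melt_ok)) {
    if (!all(dim(melt_ok) == dim(ct)))
      stop("melt_ok matrix differs in shape")
    present <- present & melt_ok
  }
  copies <- ifelse(present, 10^((ct_limit - ct) / divisor), 0)
  dimnames(copies) <- dimnames(ct)
  if (normalize_16s) {
    if (!"16S" %in% rownames(copies)) stop("no '16S' row to normalise by")
    ref <- copies["16S", ]
    if (any(ref <= 0)) stop("16S undetected in some sample; cannot normalise")
    copies <- sweep(copies, 2, ref, "/")
  }
  grp <- NULL
  if (is.null(genes)) {
    panel <- qmec_gene_panel()
    if (all(rownames(ct) %in% panel$gene)) genes <- panel
  }
  if (!is.null(genes))
    grp <- setNames(genes$cycle_group, genes$gene)[rownames(ct)]
  cycle_sums <- NULL
  if (!is.null(grp)) {
    cyc <- grp != "16S" & !is.na(grp)
    cycle_sums <- rowsum(copies[cyc, , drop = FALSE], grp[cyc])
  }
  structure(list(copies = copies, present = present, cycle_group = grp,
                 cycle_sums = cycle_sums), class = "qmec_result")
}

#' Microbial biomass as log10 gene copies per gram of soil
#'
#' @param copies_per_g Positive numeric vector (or matrix) of absolute qPCR
#'   copy numbers per gram of soil.
#' @return `log10(copies_per_g)`, same shape and names.
#' @export
biomass_log_copies <- function(copies_per_g) {
  if (any(copies_per_g <= 0))
    stop("copy numbers must be positive for the log10 scale")
  log10(copies_per_g)
}

ENZYMES <- c("BGC", "BXYS", "BCL", "LAP", "AGC", "NAG", "ALP", "ASF",
             "PPO", "POD")

#' Eco-enzymatic stoichiometry ratios
#'
#' `C:N = ln(BGC) / ln(NAG + LAP)`, `C:P = ln(BGC) / ln(ALP)`,
#' `N:P = ln(NAG + LAP) / ln(ALP)`, on activities in nmol h^-1 g^-1. A ratio
#' is undefined (`NA`) for a sample whenever the activity entering a
#' logarithm is at or below 1 (non-positive logarithm).
#'
#' @param panel Data frame or matrix of per-sample enzyme activities with
#'   (at least) columns `BGC`, `NAG`, `LAP`, `ALP`; rows are samples.
#' @return Data frame with columns `sample`, `cn`, `cp`, `np`.
#' @export
enzyme_stoichiometry <- function(panel) {
  p <- as.data.frame(panel)
  need <- c("BGC", "NAG", "LAP", "ALP")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing enzyme column(s): ", paste(miss, collapse = ", "))
  if (any(p[need] < 0, na.rm = TRUE)) stop("enzyme activities must be >= 0")
  bgc <- p$BGC; nl <- p$NAG + p$LAP; alp <- p$ALP
  safe_log <- function(x) ifelse(x > 1, log(x), NA_real_)
  l_bgc <- safe_log(bgc); l_nl <- safe_log(nl); l_alp <- safe_log(alp)
  data.frame(sample = if (!is.null(rownames(panel))) rownames(panel)
             else seq_len(nrow(p)),
             cn = l_bgc / l_nl, cp = l_bgc / l_alp, np = l_nl / l_alp,
             stringsAsFactors = FALSE)
}

TROPHIC_GROUPS <- c("consumer", "phototroph", "parasite",
                    "photophagotroph", "unclassified")

#' Template protist lineage-to-trophic-group map
#'
#' Seeded from the groups the framework names (Cercozoa/Lobosa consumers,
#' Chlorophyta phototrophs, Apicomplexa parasites, Hacrobia
#' photophagotrophs); editable via CSV with columns `lineage`, `group`.
#'
#' @param path Optional CSV path overriding the shipped template.
#' @return Named character vector lineage -> trophic group.
#' @export
default_trophic_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "trophic_map.csv", package = "soilassembly")
  df <- read.csv(path, stringsAsFactors = FALSE)
  setNames(df$group, df$lineage)
}

#' Per-sample protist trophic profile
#'
#' Relative abundance mass per trophic group. Taxa are matched to the
#' lineage map either directly by taxon id or through an explicit
#' `taxon_lineage` vector (taxon -> lineage, e.g. the sub-kingdom parsed
#' upstream); unmapped taxa fall into `unclassified`. Fractions sum to 1
#' per sample exactly.
#'
#' @param table Protist community table (taxa x samples).
#' @param lineage_map Named character vector lineage -> group; defaults to
#'   the shipped template.
#' @param taxon_lineage Optional named character vector taxon -> lineage.
#' @return Data frame, one row per sample, columns `sample` plus the five
#'   trophic groups.
#' @export
assign_trophic_groups <- function(table, lineage_map = default_trophic_map(),
                                  taxon_lineage = NULL) {
  rel <- relative_abundance(table)
  taxa <- rownames(rel)
  lin <- if (is.null(taxon_lineage)) taxa else unname(taxon_lineage[taxa])
  grp <- unname(lineage_map[lin])
  grp[is.na(grp)] <- "unclassified"
  bad <- setdiff(unique(grp), TROPHIC_GROUPS)
  if (length(bad)) stop("unknown trophic group(s): ", paste(bad, collapse = ", "))
  mass <- rowsum(rel, factor(grp, levels = TROPHIC_GROUPS))
  full <- matrix(0, length(TROPHIC_GROUPS), ncol(rel),
                 dimnames = list(TROPHIC_GROUPS, colnames(rel)))
  full[rownames(mass), ] <- mass
  out <- data.frame(sample = colnames(rel), t(full),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  out
}
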