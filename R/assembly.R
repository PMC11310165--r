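# Phylogenetic null-model inference of community assembly processes.
#
# The turnover between two communities is summarised by the beta mean
# nearest taxon distance (betaMNTD): for every taxon in one community, the
# patristic distance to its closest relative in the other, averaged with
# abundance weights over both directions. The beta nearest taxon index
# (betaNTI) is the z-score of the observed betaMNTD against a null built by
# shuffling taxon labels across the tips of the tree (richness and
# abundances untouched), one shuffle per null replicate shared across all
# sample pairs. |betaNTI| >= 2 signals deterministic selection (negative:
# homogeneous selection, positive: variable selection). Pairs inside the
# +/-2 band are split by the abundance-based Raup-Crick index (RCbray): null
# communities preserve each sample's observed richness and total abundance,
# draw occupancy with probability proportional to occurrence frequency
# across samples and fill abundances proportional to the pooled relative
# abundances; RC > +0.95 indicates dispersal limitation, RC < -0.95
# homogenizing dispersal, anything else is undominated.

#' All unordered within-group sample pairs
#'
#' @param frame A [sample_frame()].
#' @param grouping Metadata columns defining groups (default
#'   `c("plantation", "season")`); `NULL` pools all samples into one group.
#' @return Data frame with columns `sample_i`, `sample_j`, `group`.
#' @export
within_group_pairs <- function(frame, grouping = c("plantation", "season")) {
  if (is.null(grouping)) {
    grp <- rep("all", nrow(frame))
  } else {
    grp <- do.call(paste, c(as.data.frame(frame)[grouping], sep = "."))
  }
  out <- lapply(split(frame$sample, grp), function(s) {
    if (length(s) < 2) return(NULL)
    cmb <- utils::combn(s, 2)
    data.frame(sample_i = cmb[1, ], sample_j = cmb[2, ],
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(out, is.null, TRUE)
  res <- do.call(rbind, out[keep])
  res$group <- rep(names(out)[keep],
                   vapply(out[keep], nrow, 0L))
  rownames(res) <- NULL
  res
}

pair_index_matrix <- function(table, pairs) {
  cbind(match(pairs$sample_i, colnames(table)),
        match(pairs$sample_j, colnames(table)))
}

#' Beta mean nearest taxon distance for sample pairs
#'
#' @param table Community table aligned to `tree` (same taxon set).
#' @param tree Rooted phylogeny.
#' @param pairs Data frame with `sample_i`, `sample_j` columns; defaults to
#'   all unordered pairs.
#' @param abundance_weighted Weight each taxon's nearest-neighbour distance
#'   by its relative abundance (default) or uniformly over present taxa.
#' @return Numeric vector of betaMNTD values, one per pair.
#' @export
beta_mntd <- function(table, tree, pairs = NULL, abundance_weighted = TRUE) {
  al <- check_alignment(table, tree)
  if (is.null(pairs)) pairs <- all_pairs(colnames(table))
  D <- stats::cophenetic(al$tree)[rownames(al$table), rownames(al$table)]
  comm <- relative_abundance(al$table)
  idx <- pair_index_matrix(al$table, pairs)
  cpp_bmntd(D, comm, idx, abundance_weighted)
}

all_pairs <- function(samples) {
  cmb <- utils::combn(samples, 2)
  data.frame(sample_i = cmb[1, ], sample_j = cmb[2, ],
             stringsAsFactors = FALSE)
}

check_alignment <- function(table, tree) {
  if (!setequal(rownames(table), tree$tip.label))
    stop("table and tree taxa differ; run align_table_to_tree() first")
  list(table = table, tree = tree)
}

#' Beta nearest taxon index (tip-shuffling null)
#'
#' @inheritParams beta_mntd
#' @param n_null Number of null replicates (>= 99; default 999).
#' @param seed Integer seed for the tip shuffles.
#' @return Data frame with per-pair `sample_i`, `sample_j`, `bmntd_obs`,
#'   `bnti` and logical `undefined` (true where the null distribution has
#'   zero spread, e.g. on a star tree; `bnti` is `NA` there).
#' @export
beta_nti <- function(table, tree, pairs = NULL, n_null = 999,
                     abundance_weighted = TRUE, seed = 1L) {
  if (n_null < 99) stop("n_null must be at least 99")
  al <- check_alignment(table, tree)
  if (is.null(pairs)) pairs <- all_pairs(colnames(table))
  taxa <- rownames(al$table)
  D <- stats::cophenetic(al$tree)[taxa, taxa]
  comm <- relative_abundance(al$table)
  idx <- pair_index_matrix(al$table, pairs)
  obs <- cpp_bmntd(D, comm, idx, abundance_weighted)
  set.seed(seed)
  perms <- t(replicate(n_null, sample.int(length(taxa))))
  nulls <- cpp_bmntd_null(D, comm, idx, perms, abundance_weighted)
  mu <- rowMeans(nulls)
  sdev <- apply(nulls, 1, sd)
  undef <- sdev < 1e-12
  bnti <- ifelse(undef, NA_real_, (obs - mu) / sdev)
  data.frame(sample_i = pairs$sample_i, sample_j = pairs$sample_j,
             bmntd_obs = obs, bnti = bnti, undefined = undef,
             stringsAsFactors = FALSE)
}

# One null realisation of a sample: occupancy sampled without replacement
# with probability proportional to occurrence frequency, one individual per
# occupant to fix richness, remaining abundance filled by a multinomial on
# the pooled relative abundances of the occupants.
rc_null_sample <- function(richness, depth, occ_freq, pool_p) {
  S <- length(occ_freq)
  sel <- sample.int(S, richness, prob = occ_freq)
  x <- integer(S)
  x[sel] <- 1L
  if (depth > richness) {
    fill <- pool_p[sel]
    if (sum(fill) <= 0) fill <- rep(1, richness)
    x[sel] <- x[sel] + as.integer(rmultinom(1, depth - richness, fill))
  }
  x
}

bray_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

#' Abundance-based Raup-Crick index (RCbray)
#'
#' Null communities preserve each sample's observed richness and total
#' abundance; occupancy probability is proportional to occurrence frequency
#' across samples and abundances are filled proportional to pooled relative
#' abundance. One null realisation per sample per replicate is shared across
#' all pairs of that replicate.
#' `RC = 2 ((#null BC below observed + half ties) / n_null) - 1`.
#'
#' @param table Integer count community table.
#' @param pairs Data frame of sample pairs; defaults to all unordered pairs.
#' @param n_null Number of null replicates (>= 99; default 999).
#' @param seed Integer seed.
#' @return Data frame with `sample_i`, `sample_j`, `bc_obs`, `rc`.
#' @export
raup_crick_bray <- function(table, pairs = NULL, n_null = 999, seed = 1L) {
  counts <- unclass(table)
  if (any(counts != round(counts)))
    stop("Raup-Crick null requires integer counts")
  if (n_null < 99) stop("n_null must be at least 99")
  if (is.null(pairs)) pairs <- all_pairs(colnames(counts))
  idx <- pair_index_matrix(counts, pairs)
  occ_freq <- rowSums(counts > 0)
  pool_p <- rowSums(counts) / sum(counts)
  richness <- colSums(counts > 0)
  depth <- colSums(counts)
  rel <- relative_abundance(counts)
  m <- nrow(pairs)
  obs <- vapply(seq_len(m), function(k)
    bray_pair(rel[, idx[k, 1]], rel[, idx[k, 2]]), 0)
  below <- numeric(m); ties <- numeric(m)
  used <- sort(unique(as.vector(idx)))
  set.seed(seed)
  for (r in seq_len(n_null)) {
    nulls <- matrix(0, nrow(counts), ncol(counts))
    for (s in used) {
      ns <- rc_null_sample(richness[s], depth[s], occ_freq, pool_p)
      nulls[, s] <- ns / sum(ns)
    }
    for (k in seq_len(m)) {
      bc <- bray_pair(nulls[, idx[k, 1]], nulls[, idx[k, 2]])
      if (bc < obs[k] - 1e-12) below[k] <- below[k] + 1
      else if (abs(bc - obs[k]) <= 1e-12) ties[k] <- ties[k] + 1
    }
  }
  rc <- 2 * ((below + 0.5 * ties) / n_null) - 1
  data.frame(sample_i = pairs$sample_i, sample_j = pairs$sample_j,
             bc_obs = obs, rc = rc, stringsAsFactors = FALSE)
}

#' Partition pairwise turnover into the five assembly processes
#'
#' `betaNTI > +2` is variable selection and `betaNTI < -2` homogeneous
#' selection (the deterministic band takes precedence); within `|betaNTI|
#' <= 2`, `RC > +0.95` is dispersal limitation, `RC < -0.95` homogenizing
#' dispersal, and anything else undominated. Undefined betaNTI (degenerate
#' null) yields the label `"undefined"`.
#'
#' @param bnti Numeric vector of betaNTI values (`NA` where undefined).
#' @param rc Numeric vector of Raup-Crick values, same length.
#' @param bnti_threshold Significance threshold on betaNTI (default 2).
#' @param rc_threshold Significance threshold on RC (default 0.95).
#' @return Character vector of process labels.
#' @export
partition_processes <- function(bnti, rc, bnti_threshold = 2,
                                rc_threshold = 0.95) {
  stopifnot(length(bnti) == length(rc))
  out <- rep("undominated", length(bnti))
  out[!is.na(bnti) & bnti > bnti_threshold] <- "variable_selection"
  out[!is.na(bnti) & bnti < -bnti_threshold] <- "homogeneous_selection"
  inside <- !is.na(bnti) & abs(bnti) <= bnti_threshold
  out[inside & rc > rc_threshold] <- "dispersal_limitation"
  out[inside & rc < -rc_threshold] <- "homogenizing_dispersal"
  out[is.na(bnti)] <- "undefined"
  out
}

PROCESS_LEVELS <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated")

#' Per-group relative contribution of each assembly process
#'
#' Fractions are exact rationals on pair counts and sum to 1 per group over
#' the five defined processes; pairs with undefined betaNTI are excluded
#' from the denominator and reported in `n_undefined`.
#'
#' @param results Data frame with columns `group` and `process` (one row per
#'   pair), e.g. the output of [assembly_analysis()].
#' @return Data frame, one row per group: `group`, pair counts, one fraction
#'   column per process, `n_pairs`, `n_undefined`.
#' @export
process_fractions <- function(results) {
  stopifnot(all(c("group", "process") %in% names(results)))
  groups <- split(results, results$group)
  empty <- names(groups)[vapply(groups, function(g)
    sum(g$process != "undefined") == 0, TRUE)]
  if (length(empty)) {
    warning("group(s) with no defined pairs omitted: ",
            paste(empty, collapse = ", "))
    groups <- groups[setdiff(names(groups), empty)]
  }
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    defined <- g$process[g$process != "undefined"]
    tab <- table(factor(defined, levels = PROCESS_LEVELS))
    fr <- as.numeric(tab) / length(defined)
    out <- data.frame(group = nm, n_pairs = length(defined),
                      n_undefined = sum(g$process == "undefined"),
                      stringsAsFactors = FALSE)
    out[PROCESS_LEVELS] <- as.list(fr)
    out
  })
  do.call(rbind, rows)
}

#' Full assembly-process inference for a community table
#'
#' Runs betaNTI and RCbray over within-group pairs and applies the five-way
#' partition. The two null models draw from independent seeded streams.
#'
#' @param table Integer count community table.
#' @param tree Rooted phylogeny (aligned to the table, or alignable).
#' @param frame A [sample_frame()] covering the table's samples.
#' @param grouping Metadata columns defining pair groups (default
#'   plantation-by-season cells); `NULL` pools all samples.
#' @param n_null Null replicates for both null models (default 999).
#' @param abundance_weighted Passed to [beta_nti()].
#' @param bnti_threshold,rc_threshold Partition thresholds.
#' @param seed Integer seed.
#' @return A list with `pairs` (per-pair betaMNTD, betaNTI, RC, process) and
#'   `fractions` (per-group process fractions).
#' @export
assembly_analysis <- function(table, tree, frame,
                              grouping = c("plantation", "season"),
                              n_null = 999, abundance_weighted = TRUE,
                              bnti_threshold = 2, rc_threshold = 0.95,
                              seed = 1L) {
  al <- align_table_to_tree(table, tree, policy = "intersect")
  pairs <- within_group_pairs(frame[frame$sample %in% colnames(al$table), ],
                              grouping)
  nti <- beta_nti(al$table, al$tree, pairs, n_null = n_null,
                  abundance_weighted = abundance_weighted, seed = seed)
  rcb <- raup_crick_bray(al$table, pairs, n_null = n_null,
                         seed = seed + 1000L)
  pairs$bmntd_obs <- nti$bmntd_obs
  pairs$bnti <- nti$bnti
  pairs$rc <- rcb$rc
  pairs$process <- partition_processes(nti$bnti, rcb$rc,
                                       bnti_threshold, rc_threshold)
  list(pairs = pairs, fractions = process_fractions(pairs))
}
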