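# Alpha diversity, Bray-Curtis beta diversity, and distance-matrix PERMANOVA.
#
# Shannon/Simpson/ACE are delegated to vegan; Chao1 follows the classic
# estimator S_obs + F1^2 / (2 F2), switching to the bias-corrected form
# F1 (F1 - 1) / (2 (F2 + 1)) only when F2 = 0 (vegan's estimateR applies the
# bias-corrected form unconditionally, which disagrees with the convention
# used here). Faith's PD comes from picante and includes the root path.

#' Per-sample alpha diversity
#'
#' @param table Community table (taxa x samples). Counts must be integer for
#'   `chao1` and `ace`.
#' @param index One of `shannon`, `simpson`, `chao1`, `ace`, `sobs`,
#'   `faith_pd`. Shannon uses natural logarithms on relative abundances;
#'   Simpson is reported as `1 - sum(p^2)`; `sobs` is observed richness;
#'   `faith_pd` is the total branch length spanning the observed taxa
#'   including the path to the root.
#' @param tree Rooted phylogeny; required for `faith_pd`.
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table,
                            index = c("shannon", "simpson", "chao1", "ace",
                                      "sobs", "faith_pd"),
                            tree = NULL) {
  index <- match.arg(index)
  counts <- unclass(table)
  samples <- colnames(counts)
  if (index %in% c("chao1", "ace") && any(counts != round(counts)))
    stop(index, " requires integer counts")
  out <- switch(index,
    shannon = vegan::diversity(t(relative_abundance(counts)), index = "shannon"),
    simpson = vegan::diversity(t(counts), index = "simpson"),
    sobs = colSums(counts > 0),
    chao1 = apply(counts, 2, chao1_estimate),
    ace = vegan::estimateR(t(round(counts)))["S.ACE", ],
    faith_pd = {
      if (is.null(tree)) stop("faith_pd requires a tree")
      al <- align_table_to_tree(table, tree, policy = "intersect")
      picante::pd(t(unclass(al$table)), al$tree, include.root = TRUE)$PD
    })
  setNames(as.numeric(out), samples)
}

# Classic Chao1 with bias-corrected fallback when no doubletons exist.
chao1_estimate <- function(x) {
  x <- x[x > 0]
  s_obs <- length(x)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f1 == 0) return(s_obs)
  if (f2 == 0) s_obs + f1 * (f1 - 1) / 2 else s_obs + f1^2 / (2 * f2)
}

#' Bray-Curtis distance matrix on relative abundances
#'
#' Counts are normalised to relative abundances per sample before the
#' distance is taken, so the result is invariant to per-sample rescaling.
#'
#' @param table Community table with at least two samples.
#' @return Symmetric matrix of pairwise Bray-Curtis dissimilarities in
#'   `[0, 1]` with zero diagonal.
#' @export
bray_curtis <- function(table) {
  if (ncol(table) < 2) stop("need at least two samples")
  as.matrix(vegan::vegdist(t(relative_abundance(table)), method = "bray"))
}

#' Distance-matrix PERMANOVA with seed-controlled permutations
#'
#' A thin surface over [vegan::adonis2()] with sequential (Type-I) term
#' entry, whole-sample permutations from an explicit seeded permutation
#' matrix, and `p = (1 + #perm F >= F_obs) / (1 + n_perm)`. For designs with
#' few samples, `exhaustive = TRUE` enumerates every label permutation so
#' the p-value is exact.
#'
#' @param dm Symmetric distance matrix with sample ids as dimnames.
#' @param frame A [sample_frame()] (or data.frame with a `sample` column).
#' @param factors Character vector of metadata columns, entered in order.
#' @param n_perm Number of permutations (>= 99) when not exhaustive.
#' @param seed Integer seed for the permutation draws.
#' @param exhaustive Enumerate all `n!` sample permutations (n <= 8).
#' @param mode `"sequential"` fits one model with all factors; `"single"`
#'   fits one single-term model per factor.
#' @return Data frame with columns `term`, `df`, `sum_sq`, `pseudo_f`, `r2`,
#'   `p`; includes `Residual` and `Total` rows (sequential mode).
#' @export
permanova <- function(dm, frame, factors, n_perm = 999, seed = 1L,
                      exhaustive = FALSE, mode = c("sequential", "single")) {
  mode <- match.arg(mode)
  ids <- rownames(dm)
  stopifnot(!is.null(ids), all(ids %in% frame$sample))
  meta <- as.data.frame(frame)[match(ids, frame$sample), , drop = FALSE]
  miss <- setdiff(factors, names(meta))
  if (length(miss)) stop("unknown factor(s): ", paste(miss, collapse = ", "))
  for (f in factors) {
    lv <- table(meta[[f]])
    if (length(lv) < 2 || any(lv < 2))
      stop("factor '", f, "' needs >= 2 levels with >= 2 samples each")
  }
  # aliasing check: two factors whose levels are in bijection are confounded
  if (length(factors) > 1) {
    for (i in seq_len(length(factors) - 1)) for (j in (i + 1):length(factors)) {
      a <- meta[[factors[i]]]; b <- meta[[factors[j]]]
      if (all(tapply(b, a, function(x) length(unique(x))) == 1) &&
          all(tapply(a, b, function(x) length(unique(x))) == 1))
        stop("factors '", factors[i], "' and '", factors[j],
             "' are aliased (one-to-one confounded)")
    }
  }
  n <- length(ids)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8 samples")
    perms <- permutation_matrix_exhaustive(n)
  } else {
    if (n_perm < 99) stop("n_perm must be at least 99")
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(n)))
  }
  d <- as.dist(dm)
  run_one <- function(fs) {
    form <- as.formula(paste("d ~", paste(fs, collapse = " + ")))
    fit <- vegan::adonis2(form, data = meta, permutations = perms,
                          by = "terms")
    data.frame(term = rownames(fit), df = fit$Df, sum_sq = fit$SumOfSqs,
               pseudo_f = fit$F, r2 = fit$R2, p = fit$`Pr(>F)`,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (mode == "sequential") return(run_one(factors))
  do.call(rbind, lapply(factors, run_one))
}

# All n! permutations of 1..n as rows (identity excluded by adonis2's own
# handling of observed vs permuted statistics is not needed: vegan treats
# the supplied matrix as the permutation set).
permutation_matrix_exhaustive <- function(n) {
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    out <- vector("list", length(v))
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out[[i]] <- cbind(v[i], rest)
    }
    do.call(rbind, out)
  }
  unname(perms(seq_len(n)))
}
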