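# Seeded generators for phylogenies, factorial community tables under
# controllable assembly regimes, soil attribute panels and HT-qPCR Ct
# matrices. Every generator is a pure function of (arguments, seed), so the
# whole downstream pipeline is testable without any sequencing data.
#
# The community generator is built around the premise of the nearest-taxon
# framework: selection is only phylogenetically detectable when the selected
# trait is conserved on the tree. Traits evolve by Brownian motion and are
# blended with iid noise by weight lambda (a Pagel-like conservation knob);
# fitness under selection follows a Gaussian kernel around an environmental
# optimum.

ASSEMBLY_REGIMES <- c("homogeneous_selection", "variable_selection",
                      "dispersal_limitation", "homogenizing_dispersal",
                      "neutral")

#' Specify a synthetic assembly regime
#'
#' @param regime One of `homogeneous_selection`, `variable_selection`,
#'   `dispersal_limitation`, `homogenizing_dispersal`, `neutral`.
#' @param n_taxa Number of taxa in the regional pool (default 1024; soil
#'   marker-gene surveys resolve thousands of taxa, and nearest-taxon
#'   z-scores only gain resolution when per-sample richness reaches the
#'   low hundreds). The
#'   pool should be substantially richer than any one sample: nearest-taxon
#'   turnover is identically zero between samples sharing their full taxon
#'   support, so a pool no larger than per-sample richness degenerates the
#'   null model.
#' @param n_samples_per_group Samples per plantation-by-season group (default 3).
#' @param n_groups Number of groups (default 4).
#' @param trait_conservation Pagel-like lambda in `[0, 1]` weighting the
#'   Brownian (tree-structured) trait component against iid noise.
#' @param selection_strength Inverse squared bandwidth of the Gaussian
#'   fitness kernel `exp(-s (trait - optimum)^2)`; traits are standardised,
#'   so `s = 30` confines fitness to roughly a fifth of a trait standard
#'   deviation, a strong filter admitting a handful of trait-matched
#'   family clades. Membership probability under selection follows the
#'   kernel alone (fitness, not regional abundance, sets local dominance
#'   under strong selection), cut off below 1 percent of its maximum (a
#'   hard niche edge).
#' @param niche_keep Fraction of niche members retained per sample under
#'   the selection regimes (default 0.7): a within-niche lottery standing
#'   in for microsite and priority effects, so replicate communities
#'   filtered by the same optimum share clades without sharing every
#'   member.
#' @param migration_rate `m` in `[0, 1]`: weight of the shared pool in each
#'   resampling generation (`m` near 0 isolates samples; near 1 homogenises).
#' @param drift_size Effective local community size governing neutral
#'   demographic drift (default 800 individuals); every sample's realised
#'   composition is a Dirichlet draw at this concentration around its
#'   expected composition before reads are drawn. Smaller values mean
#'   stronger drift. Pure read-depth multinomial noise with no drift is not
#'   a neutral community process: local communities assemble through finite
#'   birth-death dynamics. Dispersal limitation applies drift an order of
#'   magnitude stronger (concentration `drift_size / 10`).
#' @param depth Reads per sample (default 2000).
#' @param seed Integer seed.
#' @return A list with class `"regime_spec"`.
#' @export
regime_spec <- function(regime, n_taxa = 1024L, n_samples_per_group = 3L,
                        n_groups = 4L, trait_conservation = 0.95,
                        selection_strength = 30, migration_rate = 0.5,
                        drift_size = 800L, niche_keep = 0.7,
                        depth = 2000L, seed = 1L) {
  regime <- match.arg(regime, ASSEMBLY_REGIMES)
  stopifnot(n_taxa >= 4, n_samples_per_group >= 2, n_groups >= 1, depth >= 1)
  if (trait_conservation < 0 || trait_conservation > 1)
    stop("trait_conservation must lie in [0, 1]")
  if (migration_rate < 0 || migration_rate > 1)
    stop("migration_rate must lie in [0, 1]")
  if (niche_keep <= 0 || niche_keep > 1)
    stop("niche_keep must lie in (0, 1]")
  structure(list(regime = regime, n_taxa = as.integer(n_taxa),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 n_groups = as.integer(n_groups),
                 trait_conservation = trait_conservation,
                 selection_strength = selection_strength,
                 migration_rate = migration_rate,
                 drift_size = as.integer(drift_size),
                 niche_keep = niche_keep,
                 depth = as.integer(depth), seed = as.integer(seed)),
            class = "regime_spec")
}

#' Specify the factorial sampling design and attribute panel
#'
#' Defaults follow a two-plantation by four-season design with three
#' composite replicates per cell and the 32-attribute panel split
#' 16 / 10 / 6 across nutrient stocks, organic matter decomposition and
#' microbial functional genes (plus a pH column excluded from all indices).
#'
#' @param replicates Replicates per plantation-by-season cell (>= 2).
#' @param categories Named character vector attribute -> category; defaults
#'   to the template panel shipped with the package.
#' @return A list with class `"design_spec"`.
#' @export
design_spec <- function(replicates = 3L, categories = default_attribute_categories()) {
  stopifnot(replicates >= 2)
  sizes <- table(factor(categories, levels = ATTR_CATEGORIES))
  if (sizes[["nutrient_stocks"]] != 16 ||
      sizes[["organic_matter_decomposition"]] != 10 ||
      sizes[["microbial_functional_genes"]] != 6)
    stop("attribute panel must be sized 16/10/6 across the three categories")
  structure(list(plantations = PLANTATIONS, seasons = SEASONS,
                 replicates = as.integer(replicates), categories = categories),
            class = "design_spec")
}

#' Template attribute-to-category map (32 attributes + excluded pH)
#'
#' A best-effort template roster: 15 physicochemical attributes named in the
#' field's standard panels plus a C:N ratio for nutrient stocks, the ten
#' hydrolytic/oxidative enzymes for organic matter decomposition, and six
#' per-cycle functional-gene aggregates. Editable via CSV; see
#' [read_attribute_matrix()].
#'
#' @return Named character vector attribute -> category.
#' @export
default_attribute_categories <- function() {
  path <- system.file("extdata", "attribute_categories.csv",
                      package = "soilassembly")
  df <- read.csv(path, stringsAsFactors = FALSE)
  setNames(df$category, df$attribute)
}

#' Build the sample metadata frame implied by a design
#'
#' @param design A [design_spec()].
#' @return A [sample_frame()] with ids `<plantation>_<season>_<replicate>`.
#' @export
design_frame <- function(design) {
  g <- expand.grid(replicate = seq_len(design$replicates),
                   season = design$seasons, plantation = design$plantations,
                   stringsAsFactors = FALSE)
  sample_frame(sprintf("%s_%s_%d", g$plantation, g$season, g$replicate),
               g$plantation, g$season, g$replicate)
}

#' Simulate a rooted random phylogeny
#'
#' The default `clustered` shape mimics a marker-gene OTU phylogeny: tight
#' family-level clades (shallow internal coalescents) hanging off long deep
#' stems. That geometry is what gives Brownian traits strong phylogenetic
#' conservation and makes nearest-taxon turnover informative — on trees
#' whose terminal branches are as long as their deep ones, random taxon
#' sets are already mutually close and the phylogenetic null loses power.
#' Plain coalescent and pure-birth alternatives are available.
#'
#' @param n_taxa Number of tips (>= 4).
#' @param birth_rate Speciation rate (used by the `birth_death` model).
#' @param seed Integer seed.
#' @param model `"clustered"` (default), `"coalescent"` or `"birth_death"`.
#' @param clade_size Approximate tips per clade for the clustered model
#'   (default 32; at least 4 clades are used).
#' @param within_depth Depth of each clade subtree relative to the
#'   backbone's depth of 2 (default 0.15).
#' @return A rooted `phylo` with positive branch lengths.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = 1L,
                          model = c("clustered", "coalescent", "birth_death"),
                          clade_size = 32L, within_depth = 0.15) {
  model <- match.arg(model)
  if (n_taxa < 4) stop("n_taxa must be at least 4")
  set.seed(seed)
  tree <- switch(model,
                 clustered = clustered_tree(n_taxa, clade_size, within_depth),
                 coalescent = ape::rcoal(n_taxa),
                 birth_death = ape::rphylo(n_taxa, birth = birth_rate,
                                           death = 0))
  validate_phylogeny(tree)
}

# Family-clade tree: a deep coalescent backbone (depth 2) whose tips are
# replaced by shallow coalescent subtrees (depth `within_depth`).
clustered_tree <- function(n_taxa, clade_size, within_depth) {
  k <- max(4L, as.integer(round(n_taxa / clade_size)))
  if (k >= n_taxa) return(ape::rcoal(n_taxa))
  sizes <- rep(n_taxa %/% k, k)
  extra <- n_taxa %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bb <- ape::rcoal(k)
  bb$edge.length <- bb$edge.length /
    max(ape::node.depth.edgelength(bb)) * 2
  out <- bb
  for (i in rev(seq_len(k))) {
    if (sizes[i] == 1) {
      out$tip.label[out$tip.label == bb$tip.label[i]] <-
        sprintf("c%dt1", i)
      next
    }
    sub <- ape::rcoal(sizes[i])
    sub$edge.length <- sub$edge.length /
      max(ape::node.depth.edgelength(sub)) * within_depth
    sub$tip.label <- sprintf("c%dt%d", i, seq_len(sizes[i]))
    out <- ape::bind.tree(out, sub,
                          where = which(out$tip.label == bb$tip.label[i]))
  }
  out
}

# Standardised trait with tunable phylogenetic conservation: Brownian motion
# on the tree blended with iid noise; weights are sqrt so the trait variance
# is independent of lambda.
simulate_traits <- function(tree, lambda) {
  z <- function(x) (x - mean(x)) / sd(x)
  bm <- z(as.numeric(ape::rTraitCont(tree, model = "BM", sigma = 1)))
  iid <- z(rnorm(length(tree$tip.label)))
  tr <- sqrt(lambda) * bm + sqrt(1 - lambda) * iid
  setNames(tr, tree$tip.label)
}

# One multinomial draw as a plain integer vector.
draw_community <- function(depth, prob) {
  as.integer(rmultinom(1, depth, prob))
}

# One generation of neutral demographic drift: a Dirichlet perturbation of
# the expected composition at concentration `size` (the effective local
# community size), drawn through independent gamma variates.
drift_probs <- function(p, size) {
  g <- stats::rgamma(length(p), shape = size * p, rate = 1)
  if (sum(g) <= 0) return(p)
  g / sum(g)
}

# Fitness kernel with a hard niche edge: Gaussian in trait distance from
# the optimum, zeroed below 1 percent of its maximum so communities under
# selection have no far-flung stragglers outside the niche.
niche_weights <- function(traits, opt, ss) {
  w <- exp(-ss * (traits - opt)^2)
  w[w < 0.01 * max(w)] <- 0
  w
}

#' Simulate factorial community tables under a named assembly regime
#'
#' Selection regimes draw taxa with probability proportional to the fitness
#' kernel `exp(-s (trait - optimum)^2)` (zeroed below 1 percent of its
#' maximum), thinned by a per-sample within-niche lottery. Homogeneous
#' selection applies one shared optimum to every sample; variable selection
#' alternates two strongly divergent optima across the samples of each
#' group, so most within-group pairs span different environments. Dispersal
#' limitation applies strong independent Dirichlet drift per sample from
#' mildly divergent group pools with migration near zero; homogenizing
#' dispersal draws each group's samples from one realised group pool with
#' migration near one; the neutral regime is iid multinomial sampling from
#' a single lognormal pool, softened by neutral demographic drift at
#' `drift_size`.
#'
#' @param tree Rooted phylogeny with at least `spec$n_taxa` tips.
#' @param spec A [regime_spec()].
#' @return A list: `table` (integer counts, column sums equal `depth`),
#'   `frame` (a [sample_frame()]), `env` (per-sample environmental optimum;
#'   zero for non-selective regimes).
#' @export
simulate_communities <- function(tree, spec) {
  stopifnot(inherits(spec, "regime_spec"))
  if (length(tree$tip.label) < spec$n_taxa)
    stop("tree has fewer tips than spec$n_taxa")
  if (length(tree$tip.label) > spec$n_taxa)
    tree <- ape::keep.tip(tree, tree$tip.label[seq_len(spec$n_taxa)])
  set.seed(spec$seed)
  S <- spec$n_taxa; depth <- spec$depth
  n_g <- spec$n_groups; n_per <- spec$n_samples_per_group
  n_samples <- n_g * n_per
  # heavy-tailed regional pool with dominance capped near 5 percent:
  # soil OTU tables are lognormal-like but their most abundant taxon
  # rarely exceeds a few percent relative abundance, and an uncapped
  # lognormal tail occasionally concentrates half the pool on one taxon
  pool_w <- rlnorm(S, meanlog = 0, sdlog = 2)
  pool_p <- pool_w / sum(pool_w)
  for (it in 1:3) pool_p <- pmin(pool_p, 0.05) / sum(pmin(pool_p, 0.05))
  traits <- simulate_traits(tree, spec$trait_conservation)
  ss <- spec$selection_strength; m <- spec$migration_rate

  env <- numeric(n_samples)
  counts <- matrix(0L, nrow = S, ncol = n_samples)
  group_of <- rep(seq_len(n_g), each = n_per)

  ds <- spec$drift_size
  sel_draw <- function(opt) {
    w <- niche_weights(traits, opt, ss)
    w <- w * (runif(S) < spec$niche_keep)  # within-niche lottery
    p <- w / sum(w)
    draw_community(depth, drift_probs(p, ds))
  }
  if (spec$regime == "neutral") {
    for (j in seq_len(n_samples))
      counts[, j] <- draw_community(depth, drift_probs(pool_p, ds))
  } else if (spec$regime == "homogeneous_selection") {
    opt <- as.numeric(quantile(traits, 0.9))
    env[] <- opt
    for (j in seq_len(n_samples)) counts[, j] <- sel_draw(opt)
  } else if (spec$regime == "variable_selection") {
    opts <- as.numeric(quantile(traits, c(0.1, 0.9)))
    # alternate optima within each group: within-group pairs mostly span
    # divergent environments
    which_opt <- ((seq_len(n_per) - 1L) %% 2L) + 1L
    for (g in seq_len(n_g)) {
      idx <- which(group_of == g)
      for (k in seq_along(idx)) {
        o <- opts[which_opt[k]]
        env[idx[k]] <- o
        counts[, idx[k]] <- sel_draw(o)
      }
    }
  } else if (spec$regime == "dispersal_limitation") {
    # strong independent drift (an order of magnitude below the neutral
    # effective size) from mildly divergent group pools; migration mixes
    # the pool back in
    for (g in seq_len(n_g)) {
      gw <- pool_p * rlnorm(S, 0, 0.1)
      gp <- gw / sum(gw)
      for (j in which(group_of == g)) {
        p <- (1 - m) * drift_probs(gp, max(1, ds / 10)) + m * gp
        counts[, j] <- draw_community(depth, p)
      }
    }
  } else if (spec$regime == "homogenizing_dispersal") {
    for (g in seq_len(n_g)) {
      bp <- drift_probs(pool_p, ds)  # the group's realised local pool
      for (j in which(group_of == g)) {
        own <- drift_probs(pool_p, ds)
        counts[, j] <- draw_community(depth, (1 - m) * own + m * bp)
      }
    }
  }

  cells <- expand.grid(season = SEASONS, plantation = PLANTATIONS,
                       stringsAsFactors = FALSE)
  cells <- cells[rep_len(seq_len(nrow(cells)), n_g), ]
  frame <- sample_frame(
    sample = sprintf("%s_%s_%d", cells$plantation[group_of],
                     cells$season[group_of],
                     sequence(rep(n_per, n_g))),
    plantation = cells$plantation[group_of],
    season = cells$season[group_of],
    replicate = sequence(rep(n_per, n_g)))
  rownames(counts) <- tree$tip.label
  colnames(counts) <- frame$sample
  keep <- rowSums(counts) >= 0  # keep all taxa; zero rows are legal
  list(table = community_table(counts[keep, , drop = FALSE]),
       frame = frame, env = setNames(env, frame$sample), tree = tree)
}

#' Simulate a soil attribute panel over a sampling frame
#'
#' Each attribute is `baseline + season effect + plantation effect + noise`,
#' with the factorial effects scaled by `effect_size`. The panel is the
#' 16/10/6 template plus a pH column mapped to `excluded`.
#'
#' @param frame A [sample_frame()].
#' @param design A [design_spec()].
#' @param effect_size Multiplier on the season and plantation effects
#'   (0 gives a null panel).
#' @param noise_sd Residual standard deviation (>= 0).
#' @param seed Integer seed.
#' @return An [attribute_matrix()].
#' @export
simulate_attribute_matrix <- function(frame, design = design_spec(),
                                      effect_size = 1, noise_sd = 1,
                                      seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  attrs <- names(design$categories)
  n <- nrow(frame); p <- length(attrs)
  baseline <- setNames(rnorm(p, mean = 10, sd = 2), attrs)
  season_eff <- matrix(rnorm(p * length(SEASONS)), nrow = p,
                       dimnames = list(attrs, SEASONS))
  plant_eff <- matrix(rnorm(p * length(PLANTATIONS)), nrow = p,
                      dimnames = list(attrs, PLANTATIONS))
  vals <- matrix(NA_real_, nrow = n, ncol = p,
                 dimnames = list(frame$sample, attrs))
  for (a in seq_len(p)) {
    vals[, a] <- baseline[a] +
      effect_size * season_eff[a, frame$season] +
      effect_size * plant_eff[a, frame$plantation] +
      rnorm(n, sd = noise_sd)
  }
  attribute_matrix(vals, design$categories)
}

#' Load the template QMEC gene panel (71 CNPS genes + 16S)
#'
#' @return Data frame with columns `gene` and `cycle_group`
#'   (`C_degradation`, `C_fixation`, `N`, `P`, `S`, `16S`).
#' @export
qmec_gene_panel <- function() {
  read.csv(system.file("extdata", "qmec_genes.csv", package = "soilassembly"),
           stringsAsFactors = FALSE, check.names = FALSE)
}

#' Simulate an HT-qPCR Ct matrix with per-entry efficiencies
#'
#' Ct values lie in `[10, 40]`; a `detection_fraction` of entries fall below
#' the Ct 31 detection limit. Efficiencies are drawn over `[1.5, 2.5]` so
#' the downstream QMEC efficiency filter `[1.8, 2.2]` is exercised.
#'
#' @param samples Character vector of sample ids (>= 1).
#' @param detection_fraction Fraction of entries with Ct below 31, in `[0,1]`.
#' @param seed Integer seed.
#' @param genes Gene panel data frame; defaults to [qmec_gene_panel()].
#' @return A list: `ct` and `efficiency` (gene x sample matrices) and
#'   `genes` (the panel with cycle groups).
#' @export
simulate_ct_matrix <- function(samples, detection_fraction = 0.7, seed = 1L,
                               genes = qmec_gene_panel()) {
  if (length(samples) < 1) stop("need at least one sample")
  if (detection_fraction < 0 || detection_fraction > 1)
    stop("detection_fraction must lie in [0, 1]")
  set.seed(seed)
  G <- nrow(genes); N <- length(samples)
  detected <- matrix(runif(G * N) < detection_fraction, G, N)
  ct <- matrix(runif(G * N, 31, 40), G, N,
               dimnames = list(genes$gene, samples))
  ct[detected] <- runif(sum(detected), 10, 31 - 1e-6)
  eff <- matrix(runif(G * N, 1.5, 2.5), G, N,
                dimnames = list(genes$gene, samples))
  list(ct = ct, efficiency = eff, genes = genes)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits community table (TSV), tree (Newick), metadata (CSV), attributes and
#' category map (CSV), Ct and efficiency matrices (CSV), and a manifest JSON
#' recording all parameters and seeds.
#'
#' @param dir Output directory (created if missing).
#' @param spec A [regime_spec()].
#' @param design A [design_spec()].
#' @param effect_size,noise_sd Passed to [simulate_attribute_matrix()].
#' @param detection_fraction Passed to [simulate_ct_matrix()].
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(dir, spec = regime_spec("neutral"),
                              design = design_spec(), effect_size = 1,
                              noise_sd = 1, detection_fraction = 0.7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(spec$n_taxa, seed = spec$seed)
  sim <- simulate_communities(tree, spec)
  attrs <- simulate_attribute_matrix(sim$frame, design, effect_size,
                                     noise_sd, seed = spec$seed + 1L)
  ctm <- simulate_ct_matrix(sim$frame$sample, detection_fraction,
                            seed = spec$seed + 2L)
  write_community_table(sim$table, file.path(dir, "community.tsv"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  write.csv(as.data.frame(sim$frame), file.path(dir, "metadata.csv"),
            row.names = FALSE)
  write.csv(data.frame(sample = rownames(attrs$values), attrs$values,
                       check.names = FALSE),
            file.path(dir, "attributes.csv"), row.names = FALSE)
  write.csv(data.frame(attribute = names(attrs$categories),
                       category = unname(attrs$categories)),
            file.path(dir, "attribute_categories.csv"), row.names = FALSE)
  write.csv(data.frame(gene = rownames(ctm$ct), ctm$ct, check.names = FALSE),
            file.path(dir, "ct.csv"), row.names = FALSE)
  write.csv(data.frame(gene = rownames(ctm$efficiency), ctm$efficiency,
                       check.names = FALSE),
            file.path(dir, "efficiency.csv"), row.names = FALSE)
  manifest <- list(generator = "soilassembly::write_fixture_set",
                   regime = spec[setdiff(names(spec), NULL)],
                   design = list(replicates = design$replicates),
                   effect_size = effect_size, noise_sd = noise_sd,
                   detection_fraction = detection_fraction)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
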