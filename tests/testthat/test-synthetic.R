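test_that("tree simulation honours its contract and seed", {
  tr <- simulate_tree(16, seed = 1)
  expect_equal(length(tr$tip.label), 16)
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length >= 0))
  expect_identical(ape::write.tree(simulate_tree(16, seed = 1)),
                   ape::write.tree(tr))
  expect_false(identical(ape::write.tree(simulate_tree(16, seed = 2)),
                         ape::write.tree(tr)))
  expect_error(simulate_tree(3), "at least 4")
  bd <- simulate_tree(16, birth_rate = 2, seed = 1, model = "birth_death")
  expect_equal(length(bd$tip.label), 16)
})

test_that("community simulation is seed-deterministic with fixed depth", {
  tree <- simulate_tree(64, seed = 3)
  spec <- regime_spec("neutral", n_taxa = 64, n_samples_per_group = 2,
                      n_groups = 2, depth = 500, seed = 9)
  a <- simulate_communities(tree, spec)
  b <- simulate_communities(tree, spec)
  expect_identical(unclass(a$table), unclass(b$table))
  expect_true(all(colSums(a$table) == 500))
  expect_equal(ncol(a$table), 4)
  expect_equal(nrow(as.data.frame(a$frame)), 4)

  spec2 <- regime_spec("neutral", n_taxa = 64, n_samples_per_group = 2,
                       n_groups = 2, depth = 500, seed = 10)
  expect_false(identical(unclass(simulate_communities(tree, spec2)$table),
                         unclass(a$table)))
  expect_error(simulate_communities(simulate_tree(8, seed = 1), spec),
               "fewer tips")
  expect_error(regime_spec("neutral", trait_conservation = 1.2), "\\[0, 1\\]")
  expect_error(regime_spec("neutral", migration_rate = -0.1), "\\[0, 1\\]")
})

test_that("zero selection strength degenerates the kernel to a uniform pool", {
  # membership probability is exp(-ss (trait - opt)^2); at ss = 0 every
  # taxon has equal fitness, so the mean profile approaches uniform
  tree <- simulate_tree(64, seed = 3)
  mean_profile <- function(ss) {
    spec <- regime_spec("homogeneous_selection", n_taxa = 64,
                        n_samples_per_group = 10, n_groups = 2,
                        selection_strength = ss, niche_keep = 1,
                        drift_size = 100000, depth = 5000, seed = 11)
    rowMeans(relative_abundance(simulate_communities(tree, spec)$table))
  }
  sel0 <- mean_profile(0)
  tv <- 0.5 * sum(abs(sel0 - rep(1 / 64, 64)))
  expect_lt(tv, 0.05)
  # and a strong kernel concentrates the distribution far from uniform
  expect_gt(0.5 * sum(abs(mean_profile(10) - rep(1 / 64, 64))), 0.3)
})

test_that("homogenizing dispersal yields tighter pairs than dispersal limitation", {
  tree <- simulate_tree(128, seed = 3)
  mean_bc <- function(regime, m, seed) {
    spec <- regime_spec(regime, n_taxa = 128, n_samples_per_group = 2,
                        n_groups = 1, migration_rate = m, depth = 1000,
                        seed = seed)
    tab <- simulate_communities(tree, spec)$table
    bray_curtis(tab)[1, 2]
  }
  bc_hd <- vapply(1:20, function(s) mean_bc("homogenizing_dispersal",
                                            0.999, s), 0)
  bc_dl <- vapply(1:20, function(s) mean_bc("dispersal_limitation",
                                            0.001, s), 0)
  expect_lt(mean(bc_hd), mean(bc_dl))
})

test_that("attribute simulation recovers planted effects and respects nulls", {
  frame <- design_frame(design_spec())
  # effect_size 0: one-way season ANOVA F should be near 1 on average
  f_null <- vapply(1:15, function(s) {
    am <- simulate_attribute_matrix(frame, effect_size = 0, noise_sd = 1,
                                    seed = s)
    y <- am$values[, "TN"]
    summary(stats::aov(y ~ frame$season))[[1]]$`F value`[1]
  }, 0)
  expect_lt(abs(mean(f_null) - 1), 0.6)

  # strong effects: season term significant in nearly all seeds (factorial
  # model, since the plantation effect is equally strong)
  p_strong <- vapply(1:15, function(s) {
    am <- simulate_attribute_matrix(frame, effect_size = 5, noise_sd = 1,
                                    seed = s)
    y <- am$values[, "TN"]
    summary(stats::aov(y ~ frame$season + frame$plantation))[[1]]$`Pr(>F)`[1]
  }, 0)
  expect_gte(mean(p_strong < 0.05), 0.9)

  a1 <- simulate_attribute_matrix(frame, seed = 4)
  a2 <- simulate_attribute_matrix(frame, seed = 4)
  expect_identical(a1$values, a2$values)
  expect_error(simulate_attribute_matrix(frame, noise_sd = -1),
               "non-negative")
  expect_equal(sum(a1$categories != "excluded"), 32)
})

test_that("design spec enforces the 16/10/6 panel and replicate floor", {
  expect_error(design_spec(replicates = 1))
  cats <- default_attribute_categories()
  expect_error(design_spec(categories = cats[-1]), "16/10/6")
  frame <- design_frame(design_spec())
  expect_equal(nrow(as.data.frame(frame)), 24)
})

test_that("Ct matrix simulation places detections as requested", {
  sim <- simulate_ct_matrix(paste0("s", 1:5), detection_fraction = 1,
                            seed = 2)
  expect_true(all(sim$ct < 31))
  sim0 <- simulate_ct_matrix(paste0("s", 1:5), detection_fraction = 0,
                             seed = 2)
  expect_true(all(sim0$ct >= 31))
  expect_true(all(sim0$ct <= 40))
  expect_true(all(sim0$efficiency >= 1.5 & sim0$efficiency <= 2.5))
  expect_equal(nrow(sim$ct), 72)
  expect_identical(simulate_ct_matrix(paste0("s", 1:5), 0.5, seed = 7)$ct,
                   simulate_ct_matrix(paste0("s", 1:5), 0.5, seed = 7)$ct)
  expect_error(simulate_ct_matrix(character(0)), "at least one")
  expect_error(simulate_ct_matrix("s1", detection_fraction = 1.4), "\\[0, 1\\]")
})

test_that("fixture sets are written complete with a parameter manifest", {
  dir <- tempfile("fixtures_")
  spec <- regime_spec("neutral", n_taxa = 32, n_samples_per_group = 2,
                      n_groups = 2, depth = 300, seed = 5)
  write_fixture_set(dir, spec)
  files <- c("community.tsv", "tree.nwk", "metadata.csv", "attributes.csv",
             "attribute_categories.csv", "ct.csv", "efficiency.csv",
             "manifest.json")
  expect_true(all(file.exists(file.path(dir, files))))
  tab <- read_community_table(file.path(dir, "community.tsv"))
  tree <- read_phylogeny(file.path(dir, "tree.nwk"))
  expect_true(all(rownames(tab) %in% tree$tip.label))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$regime$seed, 5)
})
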