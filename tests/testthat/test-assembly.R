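test_that("betaMNTD degenerate cases follow the definition", {
  tree <- toy_tree()
  # identical communities: every taxon's nearest neighbour is itself
  m <- matrix(c(3, 2, 1, 4, 3, 2, 1, 4), 4, 2,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  tab <- community_table(m)
  expect_equal(beta_mntd(tab, tree,
                         data.frame(sample_i = "s1", sample_j = "s2")), 0)

  # singleton communities {A} vs {B}: betaMNTD = d(A, B) = 3
  m2 <- matrix(c(5, 0, 0, 0, 0, 7, 0, 0), 4, 2,
               dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  tab2 <- community_table(m2)
  expect_equal(beta_mntd(tab2, tree,
                         data.frame(sample_i = "s1", sample_j = "s2")), 3)
})

test_that("betaMNTD equals the brute-force oracle on random instances", {
  set.seed(21)
  tree <- toy_tree()
  D <- stats::cophenetic(tree)
  for (rep in 1:20) {
    m <- matrix(rpois(8, 4), 4, 2,
                dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
    if (any(colSums(m) == 0)) next
    tab <- community_table(m)
    pr <- data.frame(sample_i = "s1", sample_j = "s2")
    for (w in c(TRUE, FALSE)) {
      got <- beta_mntd(tab, tree, pr, abundance_weighted = w)
      want <- bmntd_brute(unclass(tab), D[rownames(tab), rownames(tab)],
                          1, 2, weighted = w)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("betaMNTD agrees with picante::comdistnt", {
  set.seed(3)
  tree <- simulate_tree(16, seed = 9, model = "coalescent")
  m <- matrix(rpois(16 * 4, 2), 16, 4,
              dimnames = list(tree$tip.label, paste0("s", 1:4)))
  m[1, colSums(m) == 0] <- 1
  tab <- community_table(m)
  pairs <- all_pairs(colnames(m))
  mine <- beta_mntd(tab, tree, pairs, abundance_weighted = TRUE)
  ref <- as.matrix(picante::comdistnt(t(unclass(tab)),
                                      stats::cophenetic(tree),
                                      abundance.weighted = TRUE))
  want <- mapply(function(i, j) ref[i, j], pairs$sample_i, pairs$sample_j)
  expect_equal(mine, unname(want), tolerance = 1e-10)
})

test_that("betaNTI is reproducible, order-invariant and relabel-invariant", {
  set.seed(4)
  tree <- simulate_tree(24, seed = 2, model = "coalescent")
  m <- matrix(rpois(24 * 4, 3), 24, 4,
              dimnames = list(tree$tip.label, paste0("s", 1:4)))
  m[, colSums(m) == 0] <- 1
  tab <- community_table(m)
  a <- beta_nti(tab, tree, n_null = 99, seed = 7)
  b <- beta_nti(tab, tree, n_null = 99, seed = 7)
  expect_identical(a, b)

  # permuting sample columns leaves each pair's value unchanged
  tab2 <- community_table(unclass(tab)[, c(3, 1, 4, 2)])
  c2 <- beta_nti(tab2, tree, n_null = 99, seed = 7)
  key <- function(d) {
    k <- apply(cbind(pmin(d$sample_i, d$sample_j),
                     pmax(d$sample_i, d$sample_j)), 1, paste,
               collapse = "|")
    setNames(d$bnti, k)[order(k)]
  }
  expect_equal(key(a), key(c2), tolerance = 1e-10)

  # consistent relabeling of taxa in table and tree
  relab <- setNames(sprintf("taxon_%02d", seq_len(24)), tree$tip.label)
  tree3 <- tree; tree3$tip.label <- unname(relab[tree$tip.label])
  m3 <- unclass(tab); rownames(m3) <- unname(relab[rownames(m3)])
  c3 <- beta_nti(community_table(m3), tree3, n_null = 99, seed = 7)
  expect_equal(a$bnti, c3$bnti, tolerance = 1e-10)
})

test_that("a star tree flags betaNTI undefined instead of erroring", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1):0;")
  m <- matrix(c(1, 1, 0, 0, 0,
                0, 0, 1, 1, 0), 5, 2,
              dimnames = list(c("A", "B", "C", "D", "E"), c("s1", "s2")))
  tab <- community_table(m)
  res <- beta_nti(tab, star, n_null = 99, seed = 1)
  expect_true(all(res$undefined))
  expect_true(all(is.na(res$bnti)))
})

test_that("Raup-Crick hits its forced extremes", {
  # identical communities: observed BC = 0, no null can be smaller
  m <- matrix(c(4, 3, 3, 4, 3, 3), 3, 2,
              dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  rc <- raup_crick_bray(community_table(m), n_null = 199, seed = 1)
  expect_lt(rc$rc, -0.9)

  # disjoint supports over a larger shared pool: obs BC = 1, while null
  # draws of the same richness from the 12-taxon pool usually overlap
  m2 <- matrix(0L, 18, 3, dimnames = list(paste0("t", 1:18),
                                          paste0("s", 1:3)))
  m2[1:6, 1] <- c(5L, 4L, 3L, 3L, 2L, 2L)
  m2[7:12, 2] <- c(5L, 4L, 3L, 3L, 2L, 2L)
  m2[, 3] <- 2L                       # broad sample keeps every taxon in the pool
  rc2 <- raup_crick_bray(community_table(m2),
                         data.frame(sample_i = "s1", sample_j = "s2"),
                         n_null = 199, seed = 2)
  expect_gt(rc2$rc, 0.9)

  expect_error(raup_crick_bray(community_table(
    matrix(c(1.5, 1, 1, 1), 2, 2,
           dimnames = list(c("a", "b"), c("x", "y"))))), "integer")
})

test_that("Raup-Crick matches exact enumeration of the null space", {
  # 3 taxa, two samples of depth 4 and richness 2: the null space is small
  # enough to enumerate exactly (weighted selection without replacement,
  # then a multinomial fill), giving the exact expectation of the RC score.
  counts <- matrix(c(3, 1, 0,
                     0, 1, 3), 3, 2,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  tab <- community_table(counts)
  occ <- rowSums(counts > 0)          # a:1 b:2 c:1
  pool <- rowSums(counts) / sum(counts)
  rich <- colSums(counts > 0); dep <- colSums(counts)
  rel <- sweep(counts, 2, colSums(counts), "/")
  obs_bc <- sum(abs(rel[, 1] - rel[, 2])) / sum(rel[, 1] + rel[, 2])

  # enumerate one sample's null distribution: P(selection set) over ordered
  # draws, then P(fill) over compositions of (depth - richness)
  null_dist <- function(R, depth) {
    S <- 3
    sets <- utils::combn(S, R, simplify = FALSE)
    out <- list()
    for (set in sets) {
      p_set <- 0
      for (ord in asplit(all_permutations(R), 1)) {
        seq_taxa <- set[ord]
        p <- 1; remaining <- occ
        for (tx in seq_taxa) {
          p <- p * remaining[tx] / sum(remaining)
          remaining[tx] <- 0
        }
        p_set <- p_set + p
      }
      fill <- depth - R
      comps <- expand.grid(rep(list(0:fill), R))
      comps <- comps[rowSums(comps) == fill, , drop = FALSE]
      fp <- pool[set] / sum(pool[set])
      for (r in seq_len(nrow(comps))) {
        x <- integer(S); x[set] <- 1 + as.integer(comps[r, ])
        pr <- stats::dmultinom(as.integer(comps[r, ]), prob = fp)
        out[[length(out) + 1]] <- list(x = x / sum(x), p = p_set * pr)
      }
    }
    out
  }
  d1 <- null_dist(rich[1], dep[1]); d2 <- null_dist(rich[2], dep[2])
  below <- 0; ties <- 0
  for (u in d1) for (v in d2) {
    bc <- sum(abs(u$x - v$x)) / sum(u$x + v$x)
    w <- u$p * v$p
    if (bc < obs_bc - 1e-12) below <- below + w
    else if (abs(bc - obs_bc) <= 1e-12) ties <- ties + w
  }
  rc_exact <- 2 * (below + 0.5 * ties) - 1

  rc_hat <- raup_crick_bray(tab, n_null = 20000, seed = 5)$rc
  # Monte-Carlo band: 4 binomial standard errors at n_null = 20000
  se <- 2 * sqrt(0.25 / 20000) * 4
  expect_lt(abs(rc_hat - rc_exact), se + 1e-9)
})

test_that("the five-way partition reproduces the published thresholds", {
  expect_equal(partition_processes(2.5, 0.1), "variable_selection")
  expect_equal(partition_processes(-3.0, 0.99), "homogeneous_selection")
  expect_equal(partition_processes(0, 0.99), "dispersal_limitation")
  expect_equal(partition_processes(0, -0.99), "homogenizing_dispersal")
  expect_equal(partition_processes(0, 0), "undominated")
  # boundary: |betaNTI| = 2 is stochastic, RC = 0.95 is undominated
  expect_equal(partition_processes(2, 0.9), "undominated")
  expect_equal(partition_processes(-2, -0.9), "undominated")
  expect_equal(partition_processes(NA, 0.5), "undefined")
})

test_that("process fractions count exactly and sum to one per group", {
  res <- data.frame(
    group = c("g1", "g1", "g1", "g2"),
    process = c("variable_selection", "dispersal_limitation",
                "dispersal_limitation", "undominated"))
  fr <- process_fractions(res)
  g1 <- fr[fr$group == "g1", ]
  expect_equal(g1$variable_selection, 1 / 3)
  expect_equal(g1$dispersal_limitation, 2 / 3)
  expect_equal(g1$homogeneous_selection, 0)
  expect_equal(rowSums(fr[, c("variable_selection", "homogeneous_selection",
                              "dispersal_limitation",
                              "homogenizing_dispersal", "undominated")]),
               c(1, 1), ignore_attr = TRUE)

  # undefined pairs excluded from the denominator but reported
  res2 <- rbind(res, data.frame(group = "g1", process = "undefined"))
  fr2 <- process_fractions(res2)
  expect_equal(fr2$n_undefined[fr2$group == "g1"], 1)
  expect_equal(fr2$variable_selection[fr2$group == "g1"], 1 / 3)

  res3 <- data.frame(group = "g3", process = "undefined")
  expect_warning(process_fractions(rbind(res, res3)), "g3")
})

test_that("within-group pairs enumerate plantation-by-season cells", {
  frame <- toy_frame(3)
  pr <- within_group_pairs(frame)
  expect_equal(nrow(pr), 4 * 3)   # 4 cells x choose(3, 2)
  expect_true(all(table(pr$group) == 3))
  pooled <- within_group_pairs(frame, grouping = NULL)
  expect_equal(nrow(pooled), choose(12, 2))
})
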