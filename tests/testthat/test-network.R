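# Builds a network object directly for metric tests, bypassing correlation.
manual_network <- function(edges, kingdoms) {
  structure(list(
    nodes = data.frame(id = names(kingdoms), kingdom = unname(kingdoms),
                       stringsAsFactors = FALSE),
    edges = data.frame(from = edges[, 1], to = edges[, 2],
                       rho = rep(0.9, nrow(edges)),
                       sign = "positive", p_adj = 0.001,
                       stringsAsFactors = FALSE),
    params = list()), class = "cooccurrence_network")
}

test_that("perfectly rank-correlated taxa are linked; no self-loops ever", {
  set.seed(1)
  n <- 10
  base <- sort(runif(n)) + 0.5
  # t3 constant so compositional closure keeps t1, t2 monotone in base
  m <- rbind(t1 = base, t2 = base * 2, t3 = rep(5, n))
  colnames(m) <- paste0("s", 1:n)
  tab <- community_table(m)
  net <- build_network(list(bacteria = tab), rho_min = 0.6,
                       alpha_fdr = 0.05, min_prevalence = 0)
  key <- paste(net$edges$from, net$edges$to)
  expect_true("bacteria:t1 bacteria:t2" %in% key)
  expect_equal(net$edges$sign[key == "bacteria:t1 bacteria:t2"], "positive")
  expect_false(any(net$edges$from == net$edges$to))
})

test_that("triangle and path metrics match closed forms", {
  tri <- manual_network(cbind(c("a", "b", "c"), c("b", "c", "a")),
                        c(a = "bacteria", b = "bacteria", c = "bacteria"))
  s <- summarize_network(tri)
  expect_equal(s$average_degree, 2)
  expect_equal(s$average_clustering_coefficient, 1)
  expect_equal(s$average_path_length, 1)

  path <- manual_network(cbind(c("a", "b"), c("b", "c")),
                         c(a = "bacteria", b = "fungi", c = "bacteria"))
  s2 <- summarize_network(path)
  expect_equal(s2$average_degree, 4 / 3)
  expect_equal(s2$average_clustering_coefficient, 0)
  expect_equal(s2$average_path_length, 4 / 3)
  expect_equal(s2$key_nodes$id[1], "b")   # centre has highest betweenness
})

test_that("metrics agree with a brute-force oracle on random graphs", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 12
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.5)
    A <- A + t(A)
    ids <- sprintf("n%02d", 1:n)
    dimnames(A) <- list(ids, ids)
    idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    net <- manual_network(cbind(ids[idx[, 1]], ids[idx[, 2]]),
                          setNames(rep("bacteria", n), ids))
    s <- summarize_network(net)
    o <- graph_oracle(A)
    expect_equal(s$average_degree, o$average_degree, tolerance = 1e-12)
    expect_equal(s$average_clustering_coefficient, o$acc, tolerance = 1e-12)
    # oracle APL over the largest component
    comp_nodes <- which(is.finite(o$distances[which.max(
      rowSums(is.finite(o$distances))), ]))
    dsub <- o$distances[comp_nodes, comp_nodes]
    expect_equal(s$average_path_length, mean(dsub[upper.tri(dsub)]),
                 tolerance = 1e-12)
    btw <- setNames(o$betweenness, ids)
    expect_equal(s$key_nodes$betweenness,
                 unname(sort(btw, decreasing = TRUE))[seq_len(
                   nrow(s$key_nodes))],
                 tolerance = 1e-9)
  }
})

test_that("summary metrics are invariant under node relabeling", {
  set.seed(5)
  n <- 10
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.4)
  A <- A + t(A)
  ids1 <- paste0("x", 1:n); ids2 <- paste0("zz", sample(n))
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  n1 <- manual_network(cbind(ids1[idx[, 1]], ids1[idx[, 2]]),
                       setNames(rep("fungi", n), ids1))
  n2 <- manual_network(cbind(ids2[idx[, 1]], ids2[idx[, 2]]),
                       setNames(rep("fungi", n), ids2))
  s1 <- summarize_network(n1); s2 <- summarize_network(n2)
  expect_equal(s1$average_degree, s2$average_degree)
  expect_equal(s1$average_clustering_coefficient,
               s2$average_clustering_coefficient)
  expect_equal(s1$average_path_length, s2$average_path_length)
  expect_equal(sort(s1$key_nodes$betweenness),
               sort(s2$key_nodes$betweenness), tolerance = 1e-9)
})

test_that("cross-kingdom links are counted by unordered kingdom pair", {
  net <- manual_network(cbind(c("b1", "b1"), c("p1", "b2")),
                        c(b1 = "bacteria", b2 = "bacteria", p1 = "protists"))
  ck <- cross_kingdom_links(net)
  expect_equal(ck$n_links[ck$kingdom_a == "bacteria" &
                            ck$kingdom_b == "protists"], 1)
  expect_equal(ck$n_links[ck$kingdom_a == "bacteria" &
                            ck$kingdom_b == "bacteria"], 1)

  # planted cross-kingdom edges recovered exactly
  kf <- c(setNames(rep("bacteria", 5), paste0("b", 1:5)),
          setNames(rep("fungi", 5), paste0("f", 1:5)))
  planted <- cbind(paste0("b", 1:5), paste0("f", 1:5))
  net2 <- manual_network(planted, kf)
  ck2 <- cross_kingdom_links(net2)
  expect_equal(ck2$n_links[ck2$kingdom_a == "bacteria" &
                             ck2$kingdom_b == "fungi"], 5)
})

test_that("prevalence filter, family collapse and environment nodes apply", {
  set.seed(8)
  m <- matrix(rpois(60, 5) + 1, 6, 10,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  m[1, 1:8] <- 0   # t1 prevalence 0.2
  m[2, ] <- pmax(m[2, ], 1)
  tab <- community_table(m)
  fam <- setNames(c("famA", "famA", "famB", "famB", "famC", "famC"),
                  rownames(m))
  cats <- c(TN = "nutrient_stocks", pH = "excluded")
  av <- matrix(rnorm(20), 10, 2, dimnames = list(colnames(m), names(cats)))
  net <- build_network(list(bacteria = tab), attrs = attribute_matrix(av, cats),
                       level_collapse = fam, rho_min = 0.01, alpha_fdr = 1,
                       min_prevalence = 0.5)
  expect_true(all(grepl("^(bacteria:fam|env:TN)", net$nodes$id)))
  expect_false("env:pH" %in% net$nodes$id)

  expect_error(build_network(list(b = tab), rho_min = 0), "rho_min")
  small <- community_table(m[, 1:4])
  expect_error(build_network(list(b = small)), "shared samples")
})
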