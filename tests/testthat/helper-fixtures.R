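# Small in-code fixtures shared across tests.

toy_table <- function() {
  community_table(matrix(c(5, 0, 1,
                           2, 3, 0,
                           0, 4, 2) * 1.0, nrow = 3, byrow = TRUE,
                         dimnames = list(c("OTU1", "OTU2", "OTU3"),
                                         c("S1", "S2", "S3"))))
}

# Four-tip rooted tree with known patristic distances:
# ((A:1,B:2):3,(C:4,D:5):6);
# d(A,B)=3, d(A,C)=14, d(A,D)=15, d(B,C)=15, d(B,D)=16, d(C,D)=9
toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
}

toy_frame <- function(n_per = 3) {
  g <- expand.grid(replicate = seq_len(n_per), season = c("SP", "SU"),
                   plantation = c("CP", "CS"), stringsAsFactors = FALSE)
  sample_frame(sprintf("%s_%s_%d", g$plantation, g$season, g$replicate),
               g$plantation, g$season, g$replicate)
}

# Brute-force betaMNTD: direct translation of the definition, independent
# of the compiled kernel.
bmntd_brute <- function(counts, D, i, j, weighted = TRUE) {
  a <- which(counts[, i] > 0); b <- which(counts[, j] > 0)
  fa <- counts[a, i] / sum(counts[a, i])
  fb <- counts[b, j] / sum(counts[b, j])
  if (!weighted) { fa <- rep(1 / length(a), length(a)); fb <- rep(1 / length(b), length(b)) }
  da <- D[a, b, drop = FALSE]
  0.5 * (sum(fa * apply(da, 1, min)) + sum(fb * apply(da, 2, min)))
}

# Exact pseudo-F for a one-factor PERMANOVA from raw pairwise distances:
# SS_total = sum_{i<j} d_ij^2 / n ; SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2.
permanova_f_brute <- function(dm, grp) {
  n <- nrow(dm)
  ss_t <- sum(dm[upper.tri(dm)]^2) / n
  ss_w <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- dm[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ss_a <- ss_t - ss_w
  a <- length(unique(grp))
  (ss_a / (a - 1)) / (ss_w / (n - a))
}

all_permutations <- function(n) {
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  perms(seq_len(n))
}

# Graph metric oracle on a small adjacency matrix: Floyd-Warshall distances,
# shortest-path counts via powers of A (a walk whose length equals the graph
# distance cannot revisit a vertex), triangle-based local clustering.
graph_oracle <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); D[A == 1] <- 1; diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  pows <- list(diag(n), A)
  maxd <- max(D[is.finite(D)])
  for (k in seq_len(max(0, maxd - 1)) + 1) pows[[k + 1]] <- pows[[k]] %*% A
  sigma <- function(i, j) {
    if (!is.finite(D[i, j])) return(0)
    pows[[D[i, j] + 1]][i, j]
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) if (is.finite(D[s, t])) {
    tot <- sigma(s, t)
    for (v in seq_len(n)) if (v != s && v != t &&
                              is.finite(D[s, v]) && is.finite(D[v, t]) &&
                              D[s, v] + D[v, t] == D[s, t])
      btw[v] <- btw[v] + sigma(s, v) * sigma(v, t) / tot
  }
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  local_cc <- ifelse(deg < 2, 0, tri / (deg * (deg - 1) / 2))
  comp_sizes <- {
    seen <- rep(FALSE, n); sizes <- integer(0)
    for (s in 1:n) if (!seen[s]) {
      members <- which(is.finite(D[s, ]))
      seen[members] <- TRUE
      sizes <- c(sizes, length(members))
    }
    sizes
  }
  list(distances = D, betweenness = btw, local_cc = local_cc,
       average_degree = mean(deg), acc = mean(local_cc),
       largest_comp = max(comp_sizes))
}
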