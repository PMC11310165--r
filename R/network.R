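# Correlation-based co-occurrence networks across kingdoms, with the three
# standard topology summaries (average degree, average clustering
# coefficient, average path length on the largest connected component),
# betweenness-ranked key nodes and cross-kingdom link counts.

#' Build a Spearman co-occurrence network
#'
#' Taxa from each kingdom's table (optionally collapsed to families) are
#' filtered by prevalence, correlated pairwise by Spearman's rho across the
#' shared samples, and connected when `|rho| >= rho_min` and the
#' Benjamini-Hochberg adjusted p-value (t approximation) falls below
#' `alpha_fdr`. Environmental attribute columns join as nodes of kingdom
#' `"environment"` when `attrs` is given.
#'
#' @param tables Named list of community tables, names are kingdom tags
#'   (e.g. `bacteria`, `fungi`, `protists`).
#' @param attrs Optional [attribute_matrix()] whose non-excluded columns
#'   become environmental nodes.
#' @param level_collapse Optional named character vector taxon -> family;
#'   taxa sharing a family are summed before correlation.
#' @param rho_min Minimum absolute Spearman correlation in `(0, 1]`.
#' @param alpha_fdr BH-adjusted significance level for edges.
#' @param min_prevalence Minimum fraction of samples in which a taxon must
#'   be present.
#' @return A list of class `"cooccurrence_network"`: `nodes` (data frame
#'   `id`, `kingdom`), `edges` (`from`, `to`, `rho`, `sign`, `p_adj`),
#'   `params`.
#' @export
build_network <- function(tables, attrs = NULL, level_collapse = NULL,
                          rho_min = 0.6, alpha_fdr = 0.05,
                          min_prevalence = 0.5) {
  if (rho_min <= 0 || rho_min > 1) stop("rho_min must lie in (0, 1]")
  stopifnot(is.list(tables), !is.null(names(tables)))
  shared <- Reduce(intersect, lapply(tables, colnames))
  if (!is.null(attrs)) shared <- intersect(shared, rownames(attrs$values))
  if (length(shared) < 5) stop("need at least 5 shared samples; found ",
                               length(shared))
  profiles <- list(); kingdom <- character(0)
  for (kg in names(tables)) {
    rel <- relative_abundance(unclass(tables[[kg]])[, shared, drop = FALSE])
    if (!is.null(level_collapse)) {
      fam <- level_collapse[rownames(rel)]
      fam[is.na(fam)] <- rownames(rel)[is.na(fam)]
      rel <- rowsum(rel, fam)
    }
    prev <- rowMeans(rel > 0)
    rel <- rel[prev >= min_prevalence, , drop = FALSE]
    if (!nrow(rel)) next
    rownames(rel) <- paste0(kg, ":", rownames(rel))
    profiles[[kg]] <- rel
    kingdom <- c(kingdom, rep(kg, nrow(rel)))
  }
  mat <- do.call(rbind, profiles)
  if (!is.null(attrs)) {
    keep <- names(attrs$categories)[attrs$categories != "excluded"]
    env <- t(attrs$values[shared, keep, drop = FALSE])
    rownames(env) <- paste0("env:", rownames(env))
    mat <- rbind(mat, env)
    kingdom <- c(kingdom, rep("environment", nrow(env)))
  }
  nodes <- data.frame(id = rownames(mat), kingdom = kingdom,
                      stringsAsFactors = FALSE)
  n <- length(shared)
  rho <- suppressWarnings(cor(t(mat), method = "spearman"))
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[ut]
  r[is.na(r)] <- 0
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p_adj <- p.adjust(p, method = "BH")
  keep <- abs(r) >= rho_min & p_adj < alpha_fdr
  edges <- data.frame(from = rownames(mat)[ut[keep, 1]],
                      to = rownames(mat)[ut[keep, 2]],
                      rho = r[keep],
                      sign = ifelse(r[keep] >= 0, "positive", "negative"),
                      p_adj = p_adj[keep], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 params = list(rho_min = rho_min, alpha_fdr = alpha_fdr,
                               min_prevalence = min_prevalence,
                               n_samples = n,
                               n_candidate_pairs = length(r))),
            class = "cooccurrence_network")
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = FALSE,
                                vertices = net$nodes)
}

#' Topological summary of a co-occurrence network
#'
#' Average degree `AD = 2 |E| / |V|`; average clustering coefficient `ACC`
#' as the mean local transitivity with degree-below-2 nodes contributing 0;
#' average path length `APL` and betweenness on the largest connected
#' component. Key nodes are the top ten by betweenness, ties broken
#' lexicographically by node id.
#'
#' @param net A `"cooccurrence_network"`.
#' @return A list of class `"network_summary"`: `average_degree`,
#'   `average_clustering_coefficient`, `average_path_length`, `n_nodes`,
#'   `n_edges`, `key_nodes` (data frame `id`, `betweenness`),
#'   `cross_kingdom` (see [cross_kingdom_links()]).
#' @export
summarize_network <- function(net) {
  g <- as_igraph(net)
  nv <- igraph::vcount(g); ne <- igraph::ecount(g)
  if (nv == 0 || ne == 0) {
    warning("empty network; metrics reported as 0")
    return(structure(list(average_degree = 0,
                          average_clustering_coefficient = 0,
                          average_path_length = 0, n_nodes = nv,
                          n_edges = ne,
                          key_nodes = data.frame(id = character(0),
                                                 betweenness = numeric(0)),
                          cross_kingdom = cross_kingdom_links(net)),
                     class = "network_summary"))
  }
  ad <- 2 * ne / nv
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  local_cc[is.nan(local_cc)] <- 0
  acc <- mean(local_cc)
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  apl <- if (igraph::vcount(big) > 1)
    igraph::mean_distance(big, directed = FALSE) else 0
  btw <- igraph::betweenness(big, directed = FALSE)
  ord <- order(-btw, names(btw))
  top <- head(ord, 10)
  structure(list(average_degree = ad, average_clustering_coefficient = acc,
                 average_path_length = apl, n_nodes = nv, n_edges = ne,
                 key_nodes = data.frame(id = names(btw)[top],
                                        betweenness = unname(btw[top]),
                                        stringsAsFactors = FALSE),
                 cross_kingdom = cross_kingdom_links(net)),
            class = "network_summary")
}

#' Count edges by kingdom pair
#'
#' Edges are tallied by the unordered pair of their endpoint kingdoms;
#' environmental nodes count as their own class.
#'
#' @param net A `"cooccurrence_network"`.
#' @return Data frame with columns `kingdom_a`, `kingdom_b`, `n_links`.
#' @export
cross_kingdom_links <- function(net) {
  kg <- setNames(net$nodes$kingdom, net$nodes$id)
  if (!nrow(net$edges))
    return(data.frame(kingdom_a = character(0), kingdom_b = character(0),
                      n_links = integer(0)))
  a <- kg[net$edges$from]; b <- kg[net$edges$to]
  lo <- pmin(a, b); hi <- pmax(a, b)
  tab <- table(paste(lo, hi, sep = "|"))
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  data.frame(kingdom_a = vapply(parts, `[`, "", 1),
             kingdom_b = vapply(parts, `[`, "", 2),
             n_links = as.integer(tab), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param net A `"cooccurrence_network"`.
#' @param edge_path Path for the edge-list TSV (`from`, `to`, `sign`, `rho`).
#' @param graphml_path Optional path for a GraphML export.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  write.table(net$edges[, c("from", "to", "sign", "rho")], edge_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- as_igraph(net)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
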