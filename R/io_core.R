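# Shared domain types and file I/O.
#
# A community table is a plain numeric matrix, taxa in rows and samples in
# columns (the orientation of most OTU/ASV pipelines), validated by
# community_table(). Trees are ape "phylo" objects. Sample metadata is a
# data.frame with columns sample/plantation/season/replicate. Soil attributes
# travel as an "attribute_matrix": a samples x attributes numeric matrix plus
# a category map assigning every attribute to one of the multifunctionality
# categories (or "excluded").

PLANTATIONS <- c("CP", "CS")
SEASONS     <- c("SP", "SU", "AU", "WI")
ATTR_CATEGORIES <- c("nutrient_stocks", "organic_matter_decomposition",
                     "microbial_functional_genes", "excluded")

#' Construct and validate a community table
#'
#' A community table is a non-negative numeric matrix of abundances (counts
#' or relative abundances) with unique taxon row names and unique sample
#' column names. Every sample must contain at least one non-zero value.
#'
#' @param counts Numeric matrix, taxa in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @return The validated matrix with class `"community_table"` prepended.
#' @examples
#' m <- matrix(c(5, 0, 1, 2, 3, 0), nrow = 3,
#'             dimnames = list(c("OTU1", "OTU2", "OTU3"), c("S1", "S2")))
#' community_table(m)
#' @export
community_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("community table must be numeric")
  taxa <- rownames(counts); samples <- colnames(counts)
  if (is.null(taxa) || is.null(samples))
    stop("community table needs taxon row names and sample column names")
  dup_t <- unique(taxa[duplicated(taxa)])
  if (length(dup_t))
    stop("duplicate taxon ids: ", paste(dup_t, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (anyNA(counts)) stop("community table contains missing values")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 taxa[neg[1, 1]], samples[neg[1, 2]]))
  empty <- samples[colSums(counts) <= 0]
  if (length(empty))
    stop("sample(s) with all-zero abundance: ", paste(empty, collapse = ", "))
  class(counts) <- c("community_table", class(counts))
  counts
}

#' Convert a community table to relative abundances
#'
#' Columns are rescaled to sum to one. Tables already in relative-abundance
#' form (columns summing to 1 within 1e-9) are returned unchanged up to
#' floating point.
#'
#' @param table Community table matrix (taxa x samples).
#' @return Matrix of the same shape with unit column sums.
#' @export
relative_abundance <- function(table) {
  sweep(unclass(table), 2, colSums(table), "/")
}

#' Read a community table from TSV or dense BIOM-style JSON
#'
#' The TSV layout is the field's standard flat OTU table: a header row of
#' sample ids, first column taxon ids. The JSON layout is a dense BIOM-style
#' object with `rows`, `columns` and a row-major `data` matrix.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom_dense"`.
#' @return A validated [community_table()].
#' @export
read_community_table <- function(path, format = c("tsv", "biom_dense")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    taxa <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    if (any(duplicated(taxa)))
      stop("duplicate taxon ids: ",
           paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
    rownames(m) <- taxa
  } else {
    b <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    pick_ids <- function(x) {
      if (is.data.frame(x)) x$id
      else if (is.list(x) && !is.null(x$id)) x$id
      else unlist(x, use.names = FALSE)
    }
    ids_r <- pick_ids(b$rows); ids_c <- pick_ids(b$columns)
    m <- b$data
    if (is.null(dim(m)))
      m <- matrix(as.numeric(m), nrow = length(ids_r), byrow = TRUE)
    dimnames(m) <- list(ids_r, ids_c)
  }
  community_table(m)
}

#' Write a community table
#'
#' @param table Community table.
#' @param path Output path.
#' @param format `"tsv"` or `"biom_dense"`.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path, format = c("tsv", "biom_dense")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(taxon = rownames(table), unclass(table),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    obj <- list(
      format = "dense-biom-json",
      rows = data.frame(id = rownames(table)),
      columns = data.frame(id = colnames(table)),
      data = unname(unclass(table))
    )
    jsonlite::write_json(obj, path, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' Read a rooted phylogeny from Newick
#'
#' @param path Newick file. The tree must be rooted and carry branch lengths;
#'   unrooted input is rejected.
#' @return An [ape::phylo] object.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  validate_phylogeny(tree)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree")
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; the nearest-taxon framework requires a rooted tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (any(duplicated(tree$tip.label)))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}

#' Restrict a community table and a tree to matching taxa
#'
#' Taxon id matching is exact, case-sensitive string equality.
#'
#' @param table Community table.
#' @param tree Rooted phylogeny.
#' @param policy `"intersect"` prunes both objects to the shared taxa,
#'   preserving each object's original relative order; `"strict"` requires the
#'   two taxon sets to be identical and returns the inputs unchanged.
#' @return A list with elements `table` and `tree`.
#' @export
align_table_to_tree <- function(table, tree, policy = c("intersect", "strict")) {
  policy <- match.arg(policy)
  taxa <- rownames(table); tips <- tree$tip.label
  shared <- intersect(taxa, tips)
  if (policy == "strict") {
    only_t <- setdiff(taxa, tips); only_p <- setdiff(tips, taxa)
    if (length(only_t) || length(only_p))
      stop("taxon sets differ; only in table: [",
           paste(only_t, collapse = ", "), "]; only in tree: [",
           paste(only_p, collapse = ", "), "]")
    return(list(table = table, tree = tree))
  }
  if (length(shared) < 2)
    stop("fewer than 2 taxa shared between table and tree")
  tab2 <- unclass(table)[taxa %in% shared, , drop = FALSE]
  tree2 <- if (length(shared) == length(tips)) tree else
    ape::drop.tip(tree, setdiff(tips, shared))
  list(table = community_table(tab2), tree = validate_phylogeny(tree2))
}

#' Construct and validate a sample metadata frame
#'
#' @param sample Character vector of sample ids.
#' @param plantation Factor-like vector with levels in `c("CP", "CS")`.
#' @param season Factor-like vector with levels in `c("SP","SU","AU","WI")`.
#' @param replicate Positive integer replicate index within plantation/season.
#' @return A `data.frame` with class `"sample_frame"`.
#' @export
sample_frame <- function(sample, plantation, season, replicate) {
  df <- data.frame(sample = as.character(sample),
                   plantation = as.character(plantation),
                   season = as.character(season),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  if (any(duplicated(df$sample)))
    stop("duplicate sample ids in metadata")
  bad_p <- setdiff(unique(df$plantation), PLANTATIONS)
  if (length(bad_p)) stop("unknown plantation level(s): ", paste(bad_p, collapse = ", "))
  bad_s <- setdiff(unique(df$season), SEASONS)
  if (length(bad_s)) stop("unknown season level(s): ", paste(bad_s, collapse = ", "))
  if (any(df$replicate < 1)) stop("replicate must be a positive integer")
  key <- paste(df$plantation, df$season, df$replicate)
  if (any(duplicated(key)))
    stop("duplicate (plantation, season, replicate) combination")
  class(df) <- c("sample_frame", class(df))
  df
}

#' Read sample metadata from CSV
#'
#' Expected columns: `sample`, `plantation`, `season`, `replicate`.
#'
#' @param path CSV path.
#' @return A [sample_frame()].
#' @export
read_sample_frame <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "plantation", "season", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  sample_frame(df$sample, df$plantation, df$season, df$replicate)
}

#' Construct a soil attribute matrix with category map
#'
#' @param values Numeric matrix, samples in rows, attributes in columns.
#'   Missing values are allowed and are excluded pairwise downstream.
#' @param categories Named character vector mapping every attribute to one of
#'   `nutrient_stocks`, `organic_matter_decomposition`,
#'   `microbial_functional_genes`, `excluded`. A `pH` column, if present,
#'   must map to `excluded` (pH is a logarithmic quantity and never enters
#'   the multifunctionality indices).
#' @return An object of class `"attribute_matrix"` with fields `values` and
#'   `categories`.
#' @export
attribute_matrix <- function(values, categories) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("attribute matrix needs sample row names and attribute column names")
  categories <- categories[colnames(values)]
  if (anyNA(names(categories)) || anyNA(categories))
    stop("category map must cover every attribute; missing: ",
         paste(setdiff(colnames(values), names(categories)), collapse = ", "))
  bad <- setdiff(unique(categories), ATTR_CATEGORIES)
  if (length(bad)) stop("unknown attribute categories: ", paste(bad, collapse = ", "))
  if ("pH" %in% colnames(values) && categories[["pH"]] != "excluded")
    stop("pH must be mapped to the 'excluded' category")
  structure(list(values = values, categories = categories),
            class = "attribute_matrix")
}

#' Read a soil attribute matrix and its category map from CSV
#'
#' @param path CSV with a `sample` column followed by one column per attribute.
#' @param categories_path Two-column CSV (`attribute`, `category`).
#' @return An [attribute_matrix()].
#' @export
read_attribute_matrix <- function(path, categories_path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample" %in% names(df)) stop("attribute CSV needs a 'sample' column")
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  rownames(m) <- df$sample
  cat_df <- read.csv(categories_path, stringsAsFactors = FALSE)
  attribute_matrix(m, setNames(cat_df$category, cat_df$attribute))
}

#' Rarefy a count table to even depth
#'
#' Optional subsampling without replacement to a common library size, for
#' users who rarefy before diversity or assembly analysis. No claim is made
#' that the original study rarefied.
#'
#' @param table Integer count community table.
#' @param depth Target depth; defaults to the minimum column sum.
#' @param seed Integer seed.
#' @return Rarefied [community_table()].
#' @export
rarefy_table <- function(table, depth = min(colSums(table)), seed = 1L) {
  counts <- unclass(table)
  if (any(counts != round(counts))) stop("rarefaction requires integer counts")
  if (any(colSums(counts) < depth))
    stop("depth exceeds the shallowest sample")
  set.seed(seed)
  out <- apply(counts, 2, function(x) {
    picks <- sample(rep.int(seq_along(x), x), depth)
    tabulate(picks, nbins = length(x))
  })
  rownames(out) <- rownames(counts)
  keep <- colSums(out) > 0
  community_table(out[, keep, drop = FALSE])
}
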