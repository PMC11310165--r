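# Soil multifunctionality: z-score standardisation of the attribute panel
# and unweighted averaging within the three functional categories
# (nutrient stocks n=16, organic matter decomposition n=10, microbial
# functional genes n=6) plus the net index over all 32 standardised
# attributes. pH never enters any index.

#' Z-score standardise a soil attribute panel
#'
#' Each retained attribute is centred and scaled to unit sample (n-1)
#' standard deviation across all samples jointly. Attributes in the
#' `excluded` category (pH) are never standardised; attributes with zero
#' spread or fewer than two non-missing observations are dropped with a
#' warning. Missing values are excluded pairwise.
#'
#' @param attrs An [attribute_matrix()].
#' @return Numeric matrix of z-scores (samples x retained attributes) with
#'   a `"categories"` attribute carrying the retained category map.
#' @export
zscore_attributes <- function(attrs) {
  stopifnot(inherits(attrs, "attribute_matrix"))
  keep <- names(attrs$categories)[attrs$categories != "excluded"]
  v <- attrs$values[, keep, drop = FALSE]
  n_obs <- colSums(!is.na(v))
  sds <- apply(v, 2, sd, na.rm = TRUE)
  drop <- n_obs < 2 | is.na(sds) | sds == 0
  if (any(drop))
    warning("dropped attribute(s) with zero spread or < 2 observations: ",
            paste(keep[drop], collapse = ", "))
  v <- v[, !drop, drop = FALSE]
  z <- scale(v, center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "categories") <- attrs$categories[colnames(v)]
  z
}

#' Multifunctionality indices from a z-score matrix
#'
#' Each narrow index is the unweighted mean of its category's z-scores per
#' sample; the net index is the unweighted mean over all standardised
#' attributes, so with the full 16/10/6 panel and no missing values
#' `net = (16 NS + 10 OMD + 6 MFG) / 32` exactly.
#'
#' @param z Z-score matrix from [zscore_attributes()] (with its
#'   `"categories"` attribute), or any samples x attributes matrix plus an
#'   explicit `categories` map.
#' @param categories Named character vector attribute -> category;
#'   defaults to the matrix's `"categories"` attribute.
#' @return Data frame with columns `sample`, `nutrient_stocks`,
#'   `organic_matter_decomposition`, `microbial_functional_genes`, `net`;
#'   the z-matrix is attached as attribute `"z"` for audit.
#' @export
multifunctionality_indices <- function(z, categories = attr(z, "categories")) {
  if (is.null(categories)) stop("no category map supplied")
  miss <- setdiff(colnames(z), names(categories))
  if (length(miss))
    stop("category map does not cover: ", paste(miss, collapse = ", "))
  cats <- setdiff(ATTR_CATEGORIES, "excluded")
  out <- data.frame(sample = rownames(z), stringsAsFactors = FALSE)
  for (cc in cats) {
    cols <- names(categories)[categories == cc]
    cols <- intersect(cols, colnames(z))
    if (!length(cols)) {
      warning("empty category '", cc, "'; index reported as missing")
      out[[cc]] <- NA_real_
    } else {
      out[[cc]] <- rowMeans(z[, cols, drop = FALSE], na.rm = TRUE)
    }
  }
  out$net <- rowMeans(z, na.rm = TRUE)
  attr(out, "z") <- z
  out
}

#' Per-sample multifunctionality from a raw attribute panel
#'
#' Convenience wrapper: [zscore_attributes()] then
#' [multifunctionality_indices()].
#'
#' @param attrs An [attribute_matrix()].
#' @return See [multifunctionality_indices()].
#' @export
multifunctionality <- function(attrs) {
  multifunctionality_indices(zscore_attributes(attrs))
}
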