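# Pairwise phi (Pearson) correlation between binary presence columns, the
# full correlation matrix, and heatmap export.

#' Phi coefficient between two binary vectors
#'
#' The Pearson correlation coefficient specialized to binary data, computed
#' from the 2x2 contingency counts:
#' \deqn{\phi = (n_{11} n_{00} - n_{10} n_{01}) /
#'   \sqrt{n_{1\cdot} n_{0\cdot} n_{\cdot 1} n_{\cdot 0}}}
#' A constant input makes the coefficient undefined; `NA` is returned (never
#' a silent 0) and the caller decides policy.
#'
#' @param x,y binary vectors (entries in \{0, 1\}) of equal length >= 2.
#' @return a number in \[-1, 1\], or `NA_real_` when undefined.
#' @examples
#' pearsonBinary(c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0))  # 1
#' pearsonBinary(c(1, 0, 1, 0), c(0, 1, 0, 1))        # -1
#' @export
pearsonBinary <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("inputs must be binary (0/1)")
  }
  n <- length(x)
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- n - n11 - n10 - n01
  r1 <- n11 + n10   # x margin
  c1 <- n11 + n01   # y margin
  denom2 <- as.numeric(r1) * (n - r1) * c1 * (n - c1)
  if (denom2 == 0) return(NA_real_)   # constant column: undefined
  (as.numeric(n11) * n00 - as.numeric(n10) * n01) / sqrt(denom2)
}

#' Pairwise phi correlation matrix of a modification matrix
#'
#' Computes all p(p-1)/2 pairwise phi coefficients once (via cross-products
#' of the binary matrix) and mirrors them. Entries involving constant
#' columns are undefined (`NA`) and the constant marks are recorded; the
#' diagonal is 1 for non-constant marks.
#'
#' @param x a [ModificationMatrix-class] (p >= 2 marks).
#' @return a [CorrelationMatrix-class].
#' @seealso [pearsonBinary()] for the per-pair definition,
#'   [heatmapExport()] for plotting.
#' @export
correlationMatrix <- function(x) {
  stopifnot(is(x, "ModificationMatrix"))
  X <- as.matrix(x)
  if (ncol(X) < 2L) stop("parameter error: at least two marks are required")
  n <- nrow(X)
  s <- colSums(X)                      # per-mark counts of 1s
  co <- crossprod(X)                   # n11 for every pair
  num <- n * co - outer(s, s)
  var_counts <- s * (n - s)            # n * variance * n
  den <- sqrt(outer(var_counts, var_counts))
  vals <- ifelse(den > 0, num / den, NA_real_)
  const <- colnames(X)[var_counts == 0]
  diag(vals) <- ifelse(var_counts > 0, 1, NA_real_)
  dimnames(vals) <- list(colnames(X), colnames(X))
  new("CorrelationMatrix", values = vals, nUsed = as.integer(n),
      constantMarks = const)
}

#' Export a correlation heatmap
#'
#' Draws the coefficient matrix with a diverging palette centered at 0.
#' Marks can be ordered by average-linkage hierarchical clustering on the
#' (1 - r) distance (default; shows the block structure) or left in catalog
#' order (reproducible side-by-side comparison). Undefined marks (constant
#' columns) cannot be placed on the (1 - r) distance scale and are dropped
#' with a warning.
#'
#' @param cm a [CorrelationMatrix-class] with >= 2 defined marks.
#' @param path output image path; `.png` and `.svg` are supported.
#' @param order `"hierarchical"` or `"catalog"` (input order).
#' @return `invisible(path)`.
#' @export
heatmapExport <- function(cm, path, order = c("hierarchical", "catalog")) {
  stopifnot(is(cm, "CorrelationMatrix"))
  order <- match.arg(order)
  v <- as.matrix(cm)
  keep <- setdiff(rownames(v), cm@constantMarks)
  if (length(keep) < 2L) {
    stop("heatmap needs at least two marks with defined correlations")
  }
  if (length(keep) < nrow(v)) {
    warning("dropping undefined (constant) marks from heatmap: ",
            paste(cm@constantMarks, collapse = ", "), call. = FALSE)
  }
  v <- v[keep, keep]
  if (order == "hierarchical") {
    hc <- stats::hclust(stats::as.dist(1 - v), method = "average")
    v <- v[hc$order, hc$order]
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = 9, height = 8)
  } else {
    grDevices::png(path, width = 1800, height = 1600, res = 180)
  }
  on.exit(grDevices::dev.off())
  ph <- pheatmap::pheatmap(
    v,
    cluster_rows = FALSE, cluster_cols = FALSE,
    breaks = seq(-1, 1, length.out = 101),
    color = grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(100),
    border_color = NA,
    fontsize = 7,
    silent = TRUE
  )
  grid::grid.newpage()
  grid::grid.draw(ph$gtable)
  invisible(path)
}
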