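#' Correlate the columns of two patient-aligned tables
#'
#' Computes the product-moment correlation
#' `r(i,j) = sum_p (X[p,i] - mean_i)(Y[p,j] - mean_j) / (sd_i * sd_j * (n-1))`
#' between every column of `X` and every column of `Y` (Spearman uses the
#' same formula on ranks). Two-sided p-values come from the t-transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom;
#' optionally from a seeded permutation null. All pairs tested in one call
#' form a single Benjamini-Hochberg family, flattened row-major over the
#' (column of X, column of Y) grid.
#'
#' Missing values (clinical tables) are handled by pairwise-complete
#' deletion with the per-pair sample size reported in `n`. Pairs with fewer
#' than 3 complete observations or a constant column are flagged missing
#' (`NA` r/p/q) with a warning, never reported as zero.
#'
#' @param X,Y Abundance tibbles sharing identical patient ids in identical
#'   order (see [harmonize()]); `Y = NULL` correlates `X` with itself.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm Permutations when `p_method = "permutation"`.
#' @param seed Seed for the permutation null.
#' @return A tibble of class `ldalink_cor`, long format
#'   `(entity_x, entity_y, r, p, q, n)`, row-major over the pair grid, with
#'   attributes `method` and `cor_dim`.
#' @export
correlate_tables <- function(X, Y = NULL, method = c("pearson", "spearman"),
                             p_method = c("t", "permutation"),
                             n_perm = 1000L, seed = 1L) {
  method <- match.arg(method)
  p_method <- match.arg(p_method)
  self <- is.null(Y)
  if (self) Y <- X
  xi <- as.character(X[[1]]); yi <- as.character(Y[[1]])
  if (!identical(xi, yi)) {
    abort("X and Y are not harmonized: patient ids differ; run harmonize() first")
  }
  mx <- abund_matrix(X); my <- abund_matrix(Y)
  if (method == "spearman") {
    mx <- apply(mx, 2, rank, na.last = "keep")
    my <- apply(my, 2, rank, na.last = "keep")
  }
  r <- suppressWarnings(cor(mx, my, use = "pairwise.complete.obs", method = "pearson"))
  n <- crossprod(!is.na(mx), !is.na(my))
  const_x <- apply(mx, 2, function(v) sd(v, na.rm = TRUE) == 0 | all(is.na(v)))
  const_y <- apply(my, 2, function(v) sd(v, na.rm = TRUE) == 0 | all(is.na(v)))
  bad <- outer(const_x, const_y, `|`) | n < 3
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf("%d pair(s) flagged missing (constant column or n < 3)", sum(bad)))
    r[bad] <- NA_real_
  }
  if (p_method == "t") {
    tt <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = pmax(n - 2, 1))
    p[is.na(r)] <- NA_real_
  } else {
    p <- withr::with_seed(seed, perm_pvals(mx, my, r, n_perm))
    p[is.na(r)] <- NA_real_
  }
  q <- bh_adjust(p)
  out <- tibble::tibble(
    entity_x = rep(colnames(mx), each = ncol(my)),
    entity_y = rep(colnames(my), times = ncol(mx)),
    r = as.vector(t(r)), p = as.vector(t(p)), q = as.vector(t(q)),
    n = as.integer(t(n))
  )
  structure(out, class = c("ldalink_cor", class(tibble::tibble())),
            method = method, cor_dim = dim(r), self = self)
}

# permutation p-values: permute rows of X jointly, recompute all pairwise r
perm_pvals <- function(mx, my, r_obs, n_perm = 1000L) {
  np <- nrow(mx)
  exceed <- matrix(0, ncol(mx), ncol(my))
  for (b in seq_len(n_perm)) {
    rp <- suppressWarnings(cor(mx[sample.int(np), , drop = FALSE], my,
                               use = "pairwise.complete.obs"))
    exceed <- exceed + (abs(rp) >= abs(r_obs))
  }
  (exceed + 1) / (n_perm + 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector or matrix of p-values by the BH step-up procedure over
#' the flattened vector (row-major for matrices), treating all supplied
#' values as one family. `NA` entries are passed through and excluded from
#' the family size.
#'
#' @param p Numeric vector or matrix of p-values in `[0, 1]`.
#' @return Adjusted values, same shape as `p`.
#' @export
bh_adjust <- function(p) {
  v <- as.vector(p)
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 1)) abort("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(v))
  q[ok] <- p.adjust(v[ok], method = "BH")
  if (is.matrix(p)) q <- matrix(q, nrow(p), ncol(p), dimnames = dimnames(p))
  q
}

#' Reshape a long correlation result into a matrix
#'
#' @param cor_tbl Result of [correlate_tables()].
#' @param value Which statistic to spread: `"r"`, `"p"`, `"q"` or `"n"`.
#' @return Matrix, rows = `entity_x`, columns = `entity_y`.
#' @export
cor_matrix <- function(cor_tbl, value = c("r", "p", "q", "n")) {
  value <- match.arg(value)
  rn <- unique(cor_tbl$entity_x)
  cn <- unique(cor_tbl$entity_y)
  matrix(cor_tbl[[value]], nrow = length(rn), ncol = length(cn),
         byrow = TRUE, dimnames = list(rn, cn))
}

#' Heatmap of a correlation result
#'
#' @param object Result of [correlate_tables()].
#' @param ... Unused.
#' @return A ggplot tile heatmap of r.
#' @export
autoplot.ldalink_cor <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$entity_y, .data$entity_x,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
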