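#' @importFrom rlang abort warn inform %||%
#' @importFrom stats cor pt sd rnorm rgamma runif rmultinom quantile hclust cutree dist setNames predict p.adjust
#' @importFrom utils head
NULL

#' Extract the numeric value matrix of an abundance table
#'
#' Abundance tables are tibbles whose first column holds patient identifiers
#' and whose remaining columns are numeric entity values. This returns the
#' value block as a numeric matrix with patient ids as row names.
#'
#' @param tbl A data frame in abundance-table layout (id column first).
#' @return A numeric matrix, rows = patients, columns = entities.
#' @export
abund_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), ncol(tbl) >= 2)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tbl[[1]])
  m
}

#' Build an abundance table from a matrix
#'
#' @param m Numeric matrix with row names (patients) and column names
#'   (entities).
#' @param kind One of `"gene"`, `"microbe"`, `"clinical"`, `"cellfraction"`.
#' @param id_col Name for the identifier column.
#' @return A validated abundance tibble (see [abundance_table()]).
#' @export
as_abundance_table <- function(m, kind, id_col = "patient_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  tbl <- tibble::as_tibble(m, .name_repair = "minimal")
  tbl <- tibble::add_column(tbl, !!id_col := rownames(m), .before = 1)
  abundance_table(tbl, kind = kind)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic 31-bit seed for a named pipeline stage, derived from the
#' master seed by a stable string hash, so one integer reproduces the whole
#' run while every stage gets an independent stream.
#'
#' @param master Master seed (single number).
#' @param stage Stage name (string).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Dirichlet draws (n x length(alpha)); standard gamma construction.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# Rank-based AUC (equivalent to Mann-Whitney U / (n1*n0)); labels logical.
rank_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC curve points (FPR, TPR) swept over score thresholds, descending.
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  tibble::tibble(
    threshold = c(Inf, scores[o]),
    tpr = c(0, cumsum(lab) / max(1L, sum(lab))),
    fpr = c(0, cumsum(!lab) / max(1L, sum(!lab)))
  )
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
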