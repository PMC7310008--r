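#' Validate a cell-type signature matrix
#'
#' A signature matrix has one row per reference cell type and one column per
#' signature gene (reference panels typically carry ~22 immune cell types
#' over a few hundred genes). Layout mirrors abundance tables: first column
#' `cell_type`, remaining columns numeric gene values.
#'
#' @param tbl Data frame, first column cell-type ids, rest numeric genes.
#' @return Tibble of class `ldalink_signature`.
#' @export
signature_matrix <- function(tbl) {
  if (!is.data.frame(tbl) || ncol(tbl) < 2) abort("signature needs cell ids + genes")
  ids <- as.character(tbl[[1]])
  if (anyDuplicated(ids)) abort("duplicate cell-type ids")
  if (anyDuplicated(names(tbl)[-1])) abort("duplicate signature genes")
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(m < 0)) {
    abort("signature values must be dense and non-negative")
  }
  dead <- colSums(m) == 0
  if (any(dead)) {
    abort(paste0("signature gene(s) zero in every cell type: ",
                 paste(head(names(tbl)[-1][dead], 5), collapse = ", ")))
  }
  out <- tibble::as_tibble(tbl)
  names(out)[1] <- "cell_type"
  out$cell_type <- ids
  structure(out, class = c("ldalink_signature", class(tibble::tibble())))
}

sig_matrix <- function(sig) {
  m <- as.matrix(sig[, -1, drop = FALSE])
  rownames(m) <- as.character(sig[[1]])
  m
}

# One nu-SVR deconvolution of a standardized mixture profile y (length
# n_genes) on standardized signature X (n_genes x n_celltypes). Returns the
# raw (unclipped) coefficient vector, fitted values, rmse, and fit r.
svr_fit_one <- function(X, y, nu) {
  fit <- e1071::svm(x = X, y = y, type = "nu-regression", kernel = "linear",
                    nu = nu, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  pred <- drop(predict(fit, X))
  list(w = w, rmse = sqrt(mean((pred - y)^2)),
       fit_r = suppressWarnings(cor(pred, y)))
}

#' Estimate cell-type fractions by nu-support-vector regression
#'
#' Solves `G = F S'` one patient at a time: the patient's signature-gene
#' profile is regressed on the reference cell-type profiles with a linear
#' nu-SVR over a small nu grid, the best nu chosen by lowest reconstruction
#' RMSE. Negative coefficients are clipped to zero and the remainder
#' renormalized to sum 1. Both the mixture profile and the signature are
#' standardized to a comparable magnitude first (the mixture z-scored across
#' genes, the signature centred/scaled by its global mean and SD so relative
#' cell-type magnitudes survive).
#'
#' Goodness of fit per patient is the correlation `fit_r` between the
#' reconstructed and observed profile; its significance `fit_p` is a
#' permutation p-value from `n_perm` random relabelings of the profile's
#' genes (null distribution of `fit_r` at the chosen nu).
#'
#' @param G Gene abundance tibble (patients x genes).
#' @param Sref Signature tibble from [signature_matrix()].
#' @param nu_grid Candidate nu values.
#' @param n_perm Permutations for the fit p-value (0 skips it).
#' @param seed RNG seed for the permutation null.
#' @return List of class `deconv_result`: `fractions` (cellfraction
#'   abundance tibble), `fit` tibble `(patient_id, nu, fit_r, rmse, fit_p,
#'   flagged)`, and `signature_genes` used.
#' @export
fit_fractions <- function(G, Sref, nu_grid = c(0.25, 0.5, 0.75),
                          n_perm = 100L, seed = 1L) {
  S <- sig_matrix(Sref)
  genes <- intersect(colnames(S), names(G)[-1])
  if (length(genes) < 0.25 * ncol(S)) {
    abort(sprintf("only %d of %d signature genes present in G (< 25%%)",
                  length(genes), ncol(S)))
  }
  gm <- abund_matrix(G)[, genes, drop = FALSE]
  Ssub <- S[, genes, drop = FALSE]
  # standardize: signature by global mean/sd, each mixture profile z-scored
  X <- t((Ssub - mean(Ssub)) / sd(Ssub))        # genes x cell types
  np <- nrow(gm); nf <- nrow(S)
  Fmat <- matrix(NA_real_, np, nf, dimnames = list(rownames(gm), rownames(S)))
  fit_tbl <- vector("list", np)
  withr::with_seed(seed, {
    perms <- if (n_perm > 0) {
      replicate(n_perm, sample.int(length(genes)), simplify = FALSE)
    } else list()
    for (i in seq_len(np)) {
      y0 <- gm[i, ]
      if (sd(y0) == 0) {
        fit_tbl[[i]] <- tibble::tibble(patient_id = rownames(gm)[i],
                                       nu = NA_real_, fit_r = NA_real_,
                                       rmse = NA_real_, fit_p = NA_real_,
                                       flagged = TRUE)
        next
      }
      y <- (y0 - mean(y0)) / sd(y0)
      fits <- lapply(nu_grid, function(nu) svr_fit_one(X, y, nu))
      best <- which.min(vapply(fits, `[[`, numeric(1), "rmse"))
      w <- pmax(fits[[best]]$w, 0)
      if (sum(w) == 0) w <- rep(1 / nf, nf)
      Fmat[i, ] <- w / sum(w)
      fit_p <- NA_real_
      if (n_perm > 0) {
        null_r <- vapply(perms, function(pm) {
          svr_fit_one(X, y[pm], nu_grid[best])$fit_r
        }, numeric(1))
        fit_p <- (1 + sum(null_r >= fits[[best]]$fit_r)) / (1 + n_perm)
      }
      fit_tbl[[i]] <- tibble::tibble(patient_id = rownames(gm)[i],
                                     nu = nu_grid[best],
                                     fit_r = fits[[best]]$fit_r,
                                     rmse = fits[[best]]$rmse,
                                     fit_p = fit_p, flagged = FALSE)
    }
  })
  fr <- as_abundance_table(Fmat, kind = "cellfraction")
  structure(list(fractions = fr, fit = dplyr::bind_rows(fit_tbl),
                 signature_genes = genes),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("Deconvolution: %d patients x %d cell types over %d signature genes\n",
              nrow(x$fractions), ncol(x$fractions) - 1L, length(x$signature_genes)))
  invisible(x)
}

#' Tidy cell fractions into long format
#'
#' @param x A `deconv_result`.
#' @param ... Unused.
#' @return Long tibble `(patient_id, cell_type, fraction)`.
#' @export
tidy.deconv_result <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x$fractions), -1,
                      names_to = "cell_type", values_to = "fraction") |>
    dplyr::rename(patient_id = 1)
}

#' One-row deconvolution summary
#'
#' @param x A `deconv_result`.
#' @param ... Unused.
#' @return Tibble with patient count, mean fit r, and the count of fits
#'   significant at 0.05.
#' @export
glance.deconv_result <- function(x, ...) {
  tibble::tibble(n_patients = nrow(x$fit),
                 n_cell_types = ncol(x$fractions) - 1L,
                 mean_fit_r = mean(x$fit$fit_r, na.rm = TRUE),
                 n_significant = sum(x$fit$fit_p <= 0.05, na.rm = TRUE))
}

#' Stacked-bar plot of estimated cell fractions
#'
#' @param object A `deconv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deconv_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$patient_id, .data$fraction,
                               fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "patient", y = "cell fraction", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Expand cell-type signatures to all genes
#'
#' Given estimated fractions `F` and the full gene table `G`, solves the
#' same linear model `G = F S` for `S` gene-by-gene as an overdetermined
#' least-squares problem (via the QR pseudoinverse of `F`), inferring the
#' per-cell-type expression of every gene, including non-signature genes.
#' Negative inferred expression is clipped to zero with a message.
#'
#' @param fractions Cell-fraction abundance tibble (patients x cell types),
#'   e.g. `fit_fractions(...)$fractions`.
#' @param G Gene abundance tibble on the same patients.
#' @return Signature tibble (cell types x all genes).
#' @export
expand_signatures <- function(fractions, G) {
  Fm <- abund_matrix(fractions)
  gm <- abund_matrix(G)
  if (!identical(rownames(Fm), rownames(gm))) {
    abort("fractions and G are not harmonized on patients")
  }
  if (nrow(Fm) < ncol(Fm)) abort("need at least as many patients as cell types")
  qrF <- qr(Fm)
  if (qrF$rank < ncol(Fm)) {
    bad <- colnames(Fm)[qrF$pivot[seq(qrF$rank + 1, ncol(Fm))]]
    abort(paste0("rank-deficient fraction matrix; collinear cell type(s): ",
                 paste(bad, collapse = ", ")))
  }
  S <- qr.coef(qrF, gm)
  neg <- sum(S < 0)
  if (neg > 0) {
    inform(sprintf("clipped %d negative inferred expression value(s) to 0", neg))
    S[S < 0] <- 0
  }
  rownames(S) <- colnames(Fm)
  out <- tibble::as_tibble(S, rownames = "cell_type")
  signature_matrix(out)
}

#' Aggregate cell-type fractions into coarser groups
#'
#' Sums disjoint groups of fraction columns (e.g. M0 + M1 + M2 ->
#' macrophage); ungrouped columns pass through unchanged.
#'
#' @param fractions Cell-fraction abundance tibble.
#' @param groups Named list: group name -> character vector of member
#'   cell-type columns.
#' @return Cell-fraction abundance tibble with grouped columns.
#' @export
aggregate_cell_types <- function(fractions, groups) {
  Fm <- abund_matrix(fractions)
  members <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(members, colnames(Fm))
  if (length(unknown)) {
    abort(paste0("unknown cell type(s): ", paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(members)) abort("groups must be disjoint")
  rest <- setdiff(colnames(Fm), members)
  agg <- vapply(groups, function(g) rowSums(Fm[, g, drop = FALSE]),
                numeric(nrow(Fm)))
  if (nrow(Fm) == 1L) agg <- matrix(agg, nrow = 1, dimnames = list(rownames(Fm), names(groups)))
  out <- cbind(agg, Fm[, rest, drop = FALSE])
  as_abundance_table(out, kind = "cellfraction")
}
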