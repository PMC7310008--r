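#' Validate and classify an abundance tibble
#'
#' The pipeline's data model is a tidy rectangle: one row per patient, the
#' first column a character `patient_id`, every other column a numeric entity
#' (gene, microbe taxon, clinical variable, or cell-type fraction). This
#' constructor validates the invariants and records the table kind and
#' declared unit as attributes.
#'
#' Gene and microbe tables must be dense (no missing cells) and non-negative;
#' clinical tables may contain missing values, which downstream correlation
#' handles by pairwise-complete deletion. Units (TPM, FPKM, RPM, relative
#' abundance, ...) are treated as opaque non-negative abundances and only
#' recorded as metadata.
#'
#' @param tbl Data frame; first column identifiers, the rest numeric.
#' @param kind One of `"gene"`, `"microbe"`, `"clinical"`, `"cellfraction"`.
#' @param unit Free-text unit label stored as metadata.
#' @return A tibble of class `ldalink_abund` with attributes `kind`, `unit`.
#' @export
abundance_table <- function(tbl, kind = c("gene", "microbe", "clinical", "cellfraction"),
                            unit = "abundance") {
  kind <- match.arg(kind)
  if (!is.data.frame(tbl) || ncol(tbl) < 2) {
    abort("an abundance table needs an id column plus at least one entity column")
  }
  ids <- as.character(tbl[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate patient id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  cn <- names(tbl)[-1]
  if (anyDuplicated(cn)) {
    abort(paste0("duplicate entity column(s): ",
                 paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  }
  vals <- tbl[, -1, drop = FALSE]
  bad_num <- !vapply(vals, is.numeric, logical(1))
  if (any(bad_num)) {
    abort(paste0("non-numeric column(s): ", paste(cn[bad_num], collapse = ", ")))
  }
  m <- as.matrix(vals)
  if (any(is.infinite(m))) abort("abundance values must be finite")
  if (kind %in% c("gene", "microbe")) {
    if (anyNA(m)) abort(sprintf("missing values are not allowed in a %s table", kind))
    if (any(m < 0)) {
      j <- which(colSums(m < 0) > 0)[1]
      i <- which(m[, j] < 0)[1]
      abort(sprintf("negative value in %s table at row '%s', column '%s'",
                    kind, ids[i], cn[j]))
    }
  }
  out <- tibble::as_tibble(tbl)
  names(out)[1] <- names(tbl)[1]
  out[[1]] <- ids
  structure(out,
            class = c("ldalink_abund", class(tibble::tibble())),
            kind = kind, unit = unit)
}

#' @export
print.ldalink_abund <- function(x, ...) {
  cat(sprintf("# Abundance table (%s, unit: %s): %d patients x %d entities\n",
              attr(x, "kind"), attr(x, "unit"), nrow(x), ncol(x) - 1L))
  NextMethod()
}

table_kind <- function(tbl) attr(tbl, "kind") %||% "gene"

#' Read a patient-by-entity TSV matrix
#'
#' Expects a UTF-8 tab-delimited file whose header row carries entity ids and
#' whose first column carries patient ids. Every cell is parsed as a number;
#' a malformed cell raises an error naming its row and column. Missing cells
#' are preserved for clinical tables and rejected for gene/microbe tables.
#'
#' @param path Path to the TSV file.
#' @inheritParams abundance_table
#' @return An abundance tibble (see [abundance_table()]).
#' @export
load_table <- function(path, kind = c("gene", "microbe", "clinical", "cellfraction"),
                       unit = "abundance") {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = c("", "NA"))
  if (ncol(raw) < 2) abort("expected at least two tab-separated columns")
  ids <- raw[[1]]
  for (j in seq(2, ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad)) {
      abort(sprintf("malformed numeric cell at row '%s', column '%s': '%s'",
                    ids[bad[1]], names(raw)[j], raw[[j]][bad[1]]))
    }
    raw[[j]] <- v
  }
  abundance_table(raw, kind = kind, unit = unit)
}

#' Write an abundance table (or any tibble) as TSV
#'
#' Values are printed at full precision so that write -> load round-trips
#' reproduce the table bit-exactly.
#'
#' @param tbl Data frame to write.
#' @param path Output path.
#' @return `tbl`, invisibly.
#' @export
write_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(tbl)
}

#' Restrict a set of tables to their shared patients
#'
#' All cross-table statistics sum over the patient index, so every table must
#' list the same patients in the same order. Returns the input tables
#' restricted to the sorted intersection of their patient ids.
#'
#' @param tables List of abundance tibbles (>= 2).
#' @return List of tables with identical row order; column sets untouched.
#' @export
harmonize <- function(tables) {
  if (!is.list(tables) || length(tables) < 2) abort("harmonize() needs >= 2 tables")
  ids <- lapply(tables, function(t) as.character(t[[1]]))
  shared <- sort(Reduce(intersect, ids))
  if (length(shared) == 0) abort("no patients shared across the tables")
  lapply(tables, function(t) {
    out <- tibble::as_tibble(t[match(shared, as.character(t[[1]])), , drop = FALSE])
    kind <- attr(t, "kind")
    if (is.null(kind)) out else {
      abundance_table(out, kind = kind, unit = attr(t, "unit") %||% "abundance")
    }
  })
}

#' Read a taxon lineage map
#'
#' A 2+ column TSV: first column the leaf taxon name as it appears in the
#' microbe table, remaining columns named taxonomic ranks (e.g. `phylum`).
#'
#' @param path TSV path.
#' @return Tibble with column `taxon` plus one column per rank.
#' @export
load_lineage <- function(path) {
  ln <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(ln) < 2) abort("lineage map needs a leaf column plus >= 1 rank column")
  names(ln)[1] <- "taxon"
  if (anyDuplicated(ln$taxon)) abort("duplicate leaf taxa in lineage map")
  ln
}

#' Roll a microbe table up to a higher taxonomic rank
#'
#' Sums leaf-taxon columns into one column per taxon at the requested rank
#' (e.g. phylum), conserving each patient's total abundance exactly. Leaves
#' absent from the lineage map (or unassigned at that rank) are pooled into
#' an `"unclassified"` column rather than dropped.
#'
#' @param M Microbe abundance tibble.
#' @param lineage Lineage map tibble from [load_lineage()].
#' @param rank Rank column name in `lineage` (e.g. `"phylum"`).
#' @return A microbe abundance tibble with one column per rank-level taxon.
#' @export
rollup_taxa <- function(M, lineage, rank = "phylum") {
  if (!identical(table_kind(M), "microbe")) abort("rollup_taxa() expects a microbe table")
  if (!rank %in% names(lineage)[-1]) {
    abort(sprintf("unknown rank '%s'; lineage map has: %s",
                  rank, paste(names(lineage)[-1], collapse = ", ")))
  }
  leaves <- names(M)[-1]
  grp <- lineage[[rank]][match(leaves, lineage$taxon)]
  grp[is.na(grp)] <- "unclassified"
  m <- abund_matrix(M)
  out <- t(rowsum(t(m), group = grp))
  out <- out[, order(colnames(out)), drop = FALSE]
  as_abundance_table(out, kind = "microbe", id_col = names(M)[1])
}

#' Scale an abundance table to bounded integer counts
#'
#' Converts abundances into the small integer counts the Gibbs sampler
#' tokenizes: each value is rounded to an integer, divided by `divisor`,
#' floored, and capped at `cap`. Defaults implement divide-by-10 with a
#' ceiling of 1000. The integer-conversion step uses round-half-to-even
#' (`rounding = "half_even"`, R's `round()`); `rounding = "floor"` truncates
#' instead.
#'
#' @param X Abundance tibble with non-negative values.
#' @param divisor Positive divisor applied after integer conversion.
#' @param cap Integer ceiling per cell.
#' @param rounding `"half_even"` (default) or `"floor"`.
#' @return A tibble of class `ldalink_counts` (integer cells in `[0, cap]`)
#'   with attributes `cap`, `divisor`.
#' @export
scale_counts <- function(X, divisor = 10, cap = 1000L, rounding = c("half_even", "floor")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(divisor) || length(divisor) != 1 || divisor <= 0) {
    abort("divisor must be a single positive number")
  }
  m <- abund_matrix(X)
  if (any(m < 0)) abort("scale_counts() requires non-negative values")
  ints <- if (rounding == "half_even") round(m) else floor(m)
  scaled <- pmin(as.numeric(cap), floor(ints / divisor))
  storage.mode(scaled) <- "integer"
  out <- as_abundance_table(matrix(as.double(scaled), nrow = nrow(m),
                                   dimnames = dimnames(m)),
                            kind = table_kind(X), id_col = names(X)[1])
  structure(out,
            class = c("ldalink_counts", class(out)),
            cap = as.integer(cap), divisor = divisor)
}

#' Cluster patients by their taxon profiles
#'
#' Renormalizes each patient's row to relative abundances (sum 1), computes
#' Euclidean distances, and cuts a Ward-linkage (`ward.D2`) dendrogram at
#' `n_clusters`. Deterministic given the table.
#'
#' @param Mrank Abundance tibble (typically a rank roll-up).
#' @param n_clusters Number of clusters (1..N patients).
#' @return Tibble `(patient_id, cluster)`.
#' @export
cluster_patients_by_taxa <- function(Mrank, n_clusters) {
  if (!is.numeric(n_clusters) || n_clusters < 1) abort("n_clusters must be >= 1")
  m <- abund_matrix(Mrank)
  if (nrow(m) < n_clusters) abort("more clusters requested than patients")
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  rel <- m / rs
  hc <- hclust(dist(rel), method = "ward.D2")
  tibble::tibble(patient_id = rownames(m),
                 cluster = as.integer(cutree(hc, k = n_clusters)))
}
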