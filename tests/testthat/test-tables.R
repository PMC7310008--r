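test_that("TSV round trip reproduces a table bit-exactly and flags bad input", {
  tbl <- toy_table(kind = "microbe", n = 3, m = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(tbl, path)
  back <- load_table(path, kind = "microbe")
  expect_identical(abund_matrix(back), abund_matrix(tbl))
  expect_identical(as.character(back[[1]]), as.character(tbl[[1]]))

  # malformed numeric cell names row and column
  writeLines(c("patient_id\tg1\tg2", "pA\t1.5\toops", "pB\t2\t3"), path)
  expect_error(load_table(path, "gene"), "row 'pA', column 'g2'")

  # negative value rejected for microbe kind, allowed nowhere dense
  writeLines(c("patient_id\tm1", "pA\t-1"), path)
  expect_error(load_table(path, "microbe"), "negative")

  # duplicate entity column named
  df <- tibble::tibble(patient_id = c("a", "b"), x = c(1, 2), x2 = c(3, 4))
  names(df)[3] <- "x"
  expect_error(abundance_table(df, "gene"), "duplicate entity column")
  expect_error(
    abundance_table(tibble::tibble(patient_id = c("a", "a"), x = c(1, 2)), "gene"),
    "duplicate patient"
  )
})

test_that("clinical tables keep missing cells, count tables must be dense", {
  df <- tibble::tibble(patient_id = c("a", "b"), age = c(40, NA))
  clin <- abundance_table(df, "clinical")
  expect_true(is.na(abund_matrix(clin)["b", "age"]))
  expect_error(abundance_table(df, "gene"), "missing")
})

test_that("harmonize restricts to the sorted shared patients and is idempotent", {
  t1 <- toy_table(n = 4, seed = 1)
  t2 <- toy_table(n = 4, seed = 2)
  t2[[1]] <- c("p02", "p03", "p04", "p05")
  h <- harmonize(list(t1, t2))
  expect_identical(as.character(h[[1]][[1]]), c("p02", "p03", "p04"))
  expect_identical(as.character(h[[2]][[1]]), c("p02", "p03", "p04"))
  expect_identical(names(h[[1]]), names(t1))
  h2 <- harmonize(h)
  expect_identical(abund_matrix(h2[[1]]), abund_matrix(h[[1]]))

  t3 <- toy_table(n = 2, seed = 3)
  t3[[1]] <- c("zz1", "zz2")
  expect_error(harmonize(list(t1, t3)), "no patients shared")
})

test_that("rollup_taxa sums leaves by rank, conserves totals, pools unmapped", {
  m <- matrix(c(1, 3, 2, 4, 5, 6), nrow = 2,
              dimnames = list(c("pA", "pB"), c("genA", "genB", "genC")))
  M <- as_abundance_table(m, "microbe")
  lineage <- tibble::tibble(taxon = c("genA", "genB"),
                            phylum = c("Proteobacteria", "Proteobacteria"))
  out <- rollup_taxa(M, lineage, "phylum")
  om <- abund_matrix(out)
  expect_identical(om[, "Proteobacteria"], c(pA = 3, pB = 7))
  expect_identical(om[, "unclassified"], c(pA = 5, pB = 6))
  expect_equal(rowSums(om), rowSums(m))
  expect_error(rollup_taxa(M, lineage, "order"), "unknown rank")

  # random table matches a brute-force group-by-sum oracle and conserves rows
  withr::with_seed(9, {
    big <- matrix(sample(0:20, 40, replace = TRUE), nrow = 5,
                  dimnames = list(paste0("p", 1:5), paste0("leaf", 1:8)))
    groups <- sample(paste0("phy", 1:3), 8, replace = TRUE)
  })
  Mb <- as_abundance_table(big + 0.0, "microbe")
  lg <- tibble::tibble(taxon = colnames(big), phylum = groups)
  rolled <- abund_matrix(rollup_taxa(Mb, lg, "phylum"))
  for (g in unique(groups)) {
    expect_equal(rolled[, g], rowSums(big[, groups == g, drop = FALSE]))
  }
  expect_equal(rowSums(rolled), rowSums(big))
})

test_that("scale_counts applies round, divide, floor, cap and is monotone", {
  vals <- matrix(c(0, 9.4, 10.5, 25.7, 99999, 1000), nrow = 1)
  dimnames(vals) <- list("p1", paste0("g", 1:6))
  X <- as_abundance_table(vals, "gene")
  out <- abund_matrix(scale_counts(X))
  # hand-computed: round-half-even then /10 then floor, capped at 1000
  expect_equal(unname(out[1, ]), c(0, 0, 1, 2, 1000, 100))
  expect_error(scale_counts(X, divisor = 0), "positive")

  withr::with_seed(4, {
    a <- sort(runif(50, 0, 20000))
  })
  A <- as_abundance_table(matrix(a, 1, dimnames = list("p", paste0("g", 1:50))),
                          "gene")
  sc <- as.vector(abund_matrix(scale_counts(A)))
  expect_true(all(diff(sc) >= 0))          # monotone in the input
  expect_true(all(sc >= 0 & sc <= 1000))   # bounded by the cap
  expect_true(all(sc == floor(sc)))
})

test_that("patient clustering recovers two distinct abundance regimes", {
  withr::with_seed(21, {
    g1 <- rdir <- matrix(rgamma(20 * 6, shape = rep(c(8, 8, 1, 1, 1, 1), each = 20)), 20)
    g2 <- matrix(rgamma(20 * 6, shape = rep(c(1, 1, 1, 1, 8, 8), each = 20)), 20)
  })
  m <- rbind(g1, g2)
  dimnames(m) <- list(sprintf("p%02d", 1:40), paste0("phy", 1:6))
  M <- as_abundance_table(m, "microbe")
  cl <- cluster_patients_by_taxa(M, 2)
  truth <- rep(1:2, each = 20)
  ari <- ldalink:::adjusted_rand_index(cl$cluster, truth)
  expect_gte(ari, 0.8)

  # degenerate cuts
  expect_identical(unique(cluster_patients_by_taxa(M, 1)$cluster), 1L)
  expect_identical(sort(cluster_patients_by_taxa(M, 40)$cluster), 1:40)
  expect_error(cluster_patients_by_taxa(M, 0), "n_clusters")
})
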