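test_that("size factors obey symmetry and scale invariance", {
  m <- toy_counts(genes = 10, cells = 2, lambda = 20)
  m[, 2] <- m[, 1]
  res <- size_factor_normalize(m)
  expect_equal(unname(res$size_factors), c(1, 1))

  m2 <- cbind(A = m[, 1] + 1, B = 2 * (m[, 1] + 1))
  res2 <- size_factor_normalize(m2)
  expect_equal(res2$size_factors[["B"]] / res2$size_factors[["A"]], 2)
  expect_equal(res2$normalized[, "A"], res2$normalized[, "B"])
})

test_that("size factors match the median-of-ratios arithmetic by hand", {
  m <- matrix(c(2, 4, 8,
                4, 16, 8), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  res <- size_factor_normalize(m)
  geo <- exp(rowMeans(log(m)))
  sf <- apply(m / geo, 2, median)
  expect_equal(res$size_factors, sf)
  expect_equal(res$normalized, sweep(m, 2, sf, "/"))
  expect_equal(res$n_reference_genes, 3)
  expect_false(res$fallback)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  m <- toy_counts(genes = 50, cells = 6, lambda = 15, seed = 99)
  got <- size_factor_normalize(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(got), unname(ref), tolerance = 1e-12)
})

test_that("dropout-heavy matrices trigger the >=50% fallback", {
  set.seed(13)
  m <- toy_counts(genes = 40, cells = 6, lambda = 6, seed = 13)
  # put one zero in every gene so no gene is nonzero in all cells
  m[cbind(1:40, rep_len(1:6, 40))] <- 0
  expect_message(res <- size_factor_normalize(m), "falling back")
  expect_true(res$fallback)
  expect_true(all(res$size_factors > 0))
  # every gene nonzero in only a quarter of cells: no usable reference set
  m_bad <- diag(4)
  expect_error(suppressMessages(size_factor_normalize(m_bad)),
               "cannot normalize")
})

test_that("marker-gene exclusion removes panel rows and logs counts", {
  panels <- default_marker_panels()
  expect_length(panels$RBC, 138)
  expect_length(panels$PLT, 173)
  m <- toy_counts(genes = 5, cells = 3)
  rownames(m) <- c("HBB", "PF4", "ACTB", "GAPDH", "EEF1A1")
  res <- exclude_marker_genes(m, panels)
  expect_false("HBB" %in% rownames(res$matrix))
  expect_false("PF4" %in% rownames(res$matrix))
  expect_equal(res$log$n_removed[res$log$panel == "RBC"], 1)
  expect_equal(res$log$n_removed[res$log$panel == "PLT"], 1)
  m2 <- toy_counts(genes = 4, cells = 3)
  res2 <- exclude_marker_genes(m2, panels)
  expect_equal(res2$matrix, m2)
})

test_that("DEG calls gate on both significance and fold change", {
  set.seed(23)
  n <- 8
  a <- matrix(2^rnorm(3 * n, mean = c(2, 6, 6), sd = 0.3), nrow = 3,
              byrow = FALSE, dimnames = list(c("down_g", "up_g", "flat_g"),
                                             paste0("a", 1:n)))
  b <- matrix(2^rnorm(3 * n, mean = c(6, 2, 6), sd = 0.3), nrow = 3,
              dimnames = list(rownames(a), paste0("b", 1:n)))
  res <- deg_call(cbind(a, b), colnames(a), colnames(b))
  expect_equal(as.character(res$call[res$gene == "down_g"]), "down")
  expect_equal(as.character(res$call[res$gene == "up_g"]), "up")
  expect_equal(as.character(res$call[res$gene == "flat_g"]), "unchanged")
  # a large fold change without significance stays unchanged
  a2 <- matrix(c(0.1, 0.1, 80, 90), nrow = 1,
               dimnames = list("noisy", paste0("a", 1:4)))
  b2 <- matrix(c(60, 0.2, 0.1, 70), nrow = 1,
               dimnames = list("noisy", paste0("b", 1:4)))
  res2 <- deg_call(cbind(a2, b2), colnames(a2), colnames(b2))
  expect_true(res2$p_value > 0.05)
  expect_equal(as.character(res2$call), "unchanged")
})

test_that("zero-variance genes are flagged, not called", {
  m <- matrix(5, nrow = 2, ncol = 8,
              dimnames = list(c("const", "var"), paste0("c", 1:8)))
  set.seed(3)
  m["var", ] <- rpois(8, 10)
  res <- deg_call(m, paste0("c", 1:4), paste0("c", 5:8))
  expect_true(res$flagged[res$gene == "const"])
  expect_true(is.na(res$p_value[res$gene == "const"]))
  expect_equal(as.character(res$call[res$gene == "const"]), "unchanged")
})

test_that("calls partition genes and survive global rescaling", {
  set.seed(41)
  raw <- matrix(rpois(100 * 12, 30) + 1, nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("c%02d", 1:12)))
  raw[1:10, 1:6] <- raw[1:10, 1:6] * 8
  a <- sprintf("c%02d", 1:6)
  b <- sprintf("c%02d", 7:12)
  calls1 <- deg_call(size_factor_normalize(raw)$normalized, a, b)
  expect_true(all(as.character(calls1$call) %in% c("down", "up", "unchanged")))
  # rescaling the raw matrix is absorbed by normalization
  calls2 <- deg_call(size_factor_normalize(raw * 3)$normalized, a, b)
  expect_equal(as.character(calls1$call), as.character(calls2$call))
})

test_that("BH correction gates calls in validation mode", {
  set.seed(57)
  n_genes <- 300
  base <- matrix(2^rnorm(n_genes * 16, 5, 0.5), nrow = n_genes,
                 dimnames = list(sprintf("g%03d", 1:n_genes),
                                 sprintf("c%02d", 1:16)))
  base[1:5, 1:8] <- base[1:5, 1:8] * 16
  a <- sprintf("c%02d", 1:8)
  b <- sprintf("c%02d", 9:16)
  res <- deg_call(base, a, b, deg_config(fdr_correct = TRUE))
  expect_false(anyNA(res$adjusted_p))
  expect_equal(res$adjusted_p, p.adjust(res$p_value, "BH"))
  expect_true(all(res$gene[res$call == "up"] %in% sprintf("g%03d", 1:5)))
})
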