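test_that("percent normalization matches hand arithmetic and sums to 100", {
  m <- manual_counts(
    matrix(c(0, 10, 90,
             5,  5,  5,
             1,  2,  3,
             0,  0,  0,
             2,  2,  2), nrow = 3,
           dimnames = list(c("G1", "G2", "G3"),
                           c("a", "b", "c", "d", "m"))),
    c(a = "case", b = "case", c = "control", d = "control", m = "mock_ip"))
  pct <- normalize_pct(m)
  expect_equal(unname(pct[, "a"]),
               100 * c(0.5, 10.5, 90.5) / 101.5, tolerance = 1e-12)
  # all-zero sample: every gene gets 100/G
  expect_equal(unname(pct[, "d"]), rep(100 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(colSums(pct)), rep(100, 5), tolerance = 1e-9)
})

test_that("fold change divides by the mock-IP mean, per gene", {
  pct <- matrix(c(5, 1, 0.04, 0.06, 0.05, 0.05), nrow = 1,
                dimnames = list("G1", c("s1", "s2", "m1", "m2", "m3", "m4")))
  roles <- c(s1 = "case", s2 = "control", m1 = "mock_ip", m2 = "mock_ip",
             m3 = "mock_ip", m4 = "mock_ip")
  fc <- fold_change(pct, roles)
  expect_equal(unname(fc["G1", "s1"]), 5 / 0.05, tolerance = 1e-12)  # 100
  expect_equal(sort(colnames(fc)), c("s1", "s2"))
  expect_equal(unname(attr(fc, "mock_mean_pct")), 0.05)
})

test_that("a sample identical to the mock mean has fold change 1 everywhere", {
  tc <- tiny_cohort(seed = 21)
  pct <- normalize_pct(tc$gene_counts)
  mock <- names(tc$gene_counts$roles)[tc$gene_counts$roles == "mock_ip"]
  pct2 <- cbind(pct, probe = rowMeans(pct[, mock, drop = FALSE]))
  roles2 <- c(tc$gene_counts$roles, probe = "case")
  fc <- fold_change(pct2, roles2)
  expect_equal(unname(fc[, "probe"]), rep(1, nrow(fc)), tolerance = 1e-12)
})

test_that("fold change is invariant to sequencing depth (compositional)", {
  tc <- tiny_cohort(seed = 22, dispersion = Inf, private_reactivity_rate = 0,
                    poisson_depth = FALSE)
  doubled <- tc$gene_counts
  doubled$counts[, "case001"] <- doubled$counts[, "case001"] * 2
  fc1 <- fold_change(normalize_pct(tc$gene_counts), tc$gene_counts$roles)
  fc2 <- fold_change(normalize_pct(doubled), doubled$roles)
  # pseudocount breaks exact identity; at these depths the effect is ~1e-4
  expect_equal(fc1[, "case001"], fc2[, "case001"], tolerance = 1e-2)
  # with the pseudocount removed the invariance is exact
  pct_a <- sweep(tc$gene_counts$counts, 2, colSums(tc$gene_counts$counts), "/") * 100
  pct_b <- sweep(doubled$counts, 2, colSums(doubled$counts), "/") * 100
  expect_equal(pct_a[, "case001"], pct_b[, "case001"], tolerance = 1e-12)
})

test_that("z-scores match hand arithmetic for cases", {
  # one gene: case fc 10 against controls with mean 1 and sd 0.5
  fc <- matrix(c(10, 0.5, 1.0, 1.5, 1.0), nrow = 1,
               dimnames = list("G1", c("s1", "c1", "c2", "c3", "c4")))
  roles <- c(s1 = "case", c1 = "control", c2 = "control",
             c3 = "control", c4 = "control")
  z <- z_scores(fc, roles)
  sd_ctrl <- sd(c(0.5, 1.0, 1.5, 1.0))
  expect_equal(unname(z["G1", "s1"]), (10 - 1) / sd_ctrl, tolerance = 1e-12)
  # a control equal to the mean of the others scores 0
  expect_equal(unname(z["G1", "c2"]), 0, tolerance = 1e-12)
})

test_that("control z-scores match a brute-force leave-one-out loop", {
  tc <- tiny_cohort(seed = 23, n_controls = 10)
  enr <- compute_enrichment(tc$gene_counts)
  fc <- enr$fc
  ctrls <- names(tc$gene_counts$roles)[tc$gene_counts$roles == "control"]
  for (s in ctrls) {
    others <- setdiff(ctrls, s)
    mu <- rowMeans(fc[, others])
    sdev <- apply(fc[, others], 1, sd)
    expect_equal(enr$z[, s], (fc[, s] - mu) / sdev, tolerance = 1e-9)
  }
  cases <- names(tc$gene_counts$roles)[tc$gene_counts$roles == "case"]
  for (s in cases) {
    expect_equal(enr$z[, s],
                 (fc[, s] - rowMeans(fc[, ctrls])) / apply(fc[, ctrls], 1, sd),
                 tolerance = 1e-9)
  }
})

test_that("zero-variance reference genes are flagged and scored by convention", {
  fc <- matrix(c(2, 1, 1, 1, 1,
                 1, 1, 1, 1, 1), nrow = 2, byrow = TRUE,
               dimnames = list(c("G1", "G2"), c("s1", "c1", "c2", "c3", "c4")))
  roles <- c(s1 = "case", c1 = "control", c2 = "control",
             c3 = "control", c4 = "control")
  z <- z_scores(fc, roles)
  expect_true(all(attr(z, "degenerate")))
  expect_equal(unname(z["G1", "s1"]), Inf)   # above the degenerate reference
  expect_equal(unname(z["G2", "s1"]), 0)     # equal to it
})

test_that("null-model control z-scores are standardized per gene", {
  tc <- tiny_cohort(seed = 24, n_genes = 100, n_cases = 2, n_controls = 60,
                    private_reactivity_rate = 0)
  enr <- compute_enrichment(tc$gene_counts)
  ctrls <- names(tc$gene_counts$roles)[tc$gene_counts$roles == "control"]
  zc <- enr$z[, ctrls]
  expect_lt(max(abs(rowMeans(zc))), 0.2)
  sds <- apply(zc, 1, sd)
  expect_lt(max(abs(sds - 1)), 0.35)
  expect_lt(abs(mean(sds) - 1), 0.1)
})

test_that("enrichment requires mocks, controls, and non-empty genes", {
  tc <- tiny_cohort(seed = 25, n_controls = 2)
  expect_error(compute_enrichment(tc$gene_counts), "3 control")
  m <- manual_counts(matrix(1, 1, 2, dimnames = list("G1", c("a", "b"))),
                     c(a = "case", b = "control"))
  expect_error(fold_change(normalize_pct(m), m$roles), "mock_ip")
})
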