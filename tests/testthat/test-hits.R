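# build a phip_enrichment object directly from fc/z matrices
fake_enr <- function(fc, z, roles) {
  structure(list(pct = fc, fc = fc, z = z,
                 mock_mean_pct = rep(1, nrow(fc)),
                 degenerate = stats::setNames(rep(FALSE, nrow(fc)), rownames(fc)),
                 roles = roles),
            class = "phip_enrichment")
}

test_that("the four hit criteria behave per their definitions", {
  samples <- c(sprintf("p%02d", 1:10), sprintf("c%02d", 1:10))
  roles <- stats::setNames(rep(c("case", "control"), each = 10), samples)
  # gene A: 2/10 cases positive, strong case fc 60, quiet controls -> hit
  # gene B: like A but one POSITIVE control exceeds every case fc -> rejected
  # gene C: positive cases max fc 20 (< 50) -> rejected
  # gene D: 1/10 cases positive (10% needs >= 1; set threshold to see freq)
  fc <- rbind(
    A = c(60, 55, rep(2, 8), rep(1, 10)),
    B = c(60, 55, rep(2, 8), 80, rep(1, 9)),
    C = c(20, 15, rep(2, 8), rep(1, 10)),
    D = c(60, rep(2, 9), rep(1, 10)))
  z <- rbind(
    A = c(30, 25, rep(0, 8), rep(0, 10)),
    B = c(30, 25, rep(0, 8), 40, rep(0, 9)),
    C = c(30, 25, rep(0, 8), rep(0, 10)),
    D = c(30, rep(0, 9), rep(0, 10)))
  colnames(fc) <- colnames(z) <- samples
  enr <- fake_enr(fc, z, roles)
  hits <- call_hits(enr, hit_call_config())
  expect_equal(hits$is_hit[hits$gene == "A"], TRUE)
  expect_equal(hits$is_hit[hits$gene == "B"], FALSE)
  expect_false(hits$dominance_ok[hits$gene == "B"])
  expect_equal(hits$is_hit[hits$gene == "C"], FALSE)
  expect_false(hits$strong_ok[hits$gene == "C"])
  expect_equal(hits$is_hit[hits$gene == "D"], TRUE)  # exactly 10% counts
  # fractional control cap: 1/10 positive controls (10%) > 2% -> B still out
  hits_frac <- call_hits(enr, hit_call_config(mode = "fraction"))
  expect_false(hits_frac$control_ok[hits_frac$gene == "B"])
})

test_that("call_hits equals a brute-force loop over random cohorts", {
  for (s in 1:20) {
    sp <- if (s %% 2 == 0) {
      data.frame(gene = c("GENE0001", "GENE0002"), case_frequency = 0.3,
                 multiplier = 150)
    } else NULL
    tc <- tiny_cohort(seed = 500 + s, n_genes = 200, peptides_per_gene = 4,
                      n_cases = 10, n_controls = 20, n_mock = 3,
                      spike_genes = sp)
    enr <- compute_enrichment(tc$gene_counts)
    for (cfg in list(hit_call_config(),
                     hit_call_config(z_threshold = 5, case_frequency_min = 0.2,
                                     strong_fc_min = 10),
                     hit_call_config(mode = "fraction"))) {
      got <- call_hits(enr, cfg)
      expect_equal(stats::setNames(got$is_hit, got$gene),
                   brute_force_hits(enr, cfg))
    }
  }
})

test_that("tightening any single threshold never adds hits", {
  sp <- data.frame(gene = c("GENE0001", "GENE0002"), case_frequency = 0.4,
                   multiplier = 150)
  tc <- tiny_cohort(seed = 31, n_genes = 100, peptides_per_gene = 2,
                    n_cases = 10, n_controls = 15, n_mock = 3,
                    spike_genes = sp)
  enr <- compute_enrichment(tc$gene_counts)
  base <- call_hits(enr, hit_call_config())$is_hit
  tighter <- list(
    hit_call_config(z_threshold = 20),
    hit_call_config(case_frequency_min = 0.3),
    hit_call_config(control_positive_max = 1),
    hit_call_config(strong_fc_min = 100))
  for (cfg in tighter) {
    expect_true(all(base | !call_hits(enr, cfg)$is_hit))
  }
})

test_that("degenerate-variance genes are evaluated but flagged", {
  # equal totals per sample and a constant gene give that gene constant pct,
  # hence constant fold change and a zero-variance control reference
  counts <- rbind(G1 = rep(10, 7),
                  G2 = c(40, 50, 30, 45, 35, 50, 40),
                  G3 = c(50, 40, 60, 45, 55, 40, 50))
  colnames(counts) <- c("p1", sprintf("c%d", 1:5), "m1")
  roles <- stats::setNames(c("case", rep("control", 5), "mock_ip"),
                           colnames(counts))
  enr <- compute_enrichment(manual_counts(counts, roles))
  hits <- call_hits(enr, hit_call_config())
  expect_true(enr$degenerate["G1"])
  expect_false(enr$degenerate["G2"])
  expect_true(hits$degenerate_sd[hits$gene == "G1"])
  expect_equal(unname(enr$z["G1", "p1"]), 0)  # fc equal to the reference
})

test_that("downsampling at the full control set reproduces call_hits", {
  tc <- tiny_cohort(seed = 33, n_genes = 80, n_cases = 8, n_controls = 12,
                    spike_genes = data.frame(gene = "GENE0001",
                                             case_frequency = 0.5,
                                             multiplier = 200))
  full_hits <- sum(call_hits(compute_enrichment(tc$gene_counts))$is_hit)
  ds <- downsample_controls(tc$gene_counts, bins = 12, reps = 1, seed = 5)
  expect_equal(ds$per_rep$n_hits, full_hits)
})

test_that("downsampling results are deterministic and well-formed", {
  tc <- tiny_cohort(seed = 34, n_cases = 5, n_controls = 10)
  a <- downsample_controls(tc$gene_counts, bins = c(4, 8), reps = 3, seed = 9)
  b <- downsample_controls(tc$gene_counts, bins = c(4, 8), reps = 3, seed = 9)
  expect_identical(a$per_rep, b$per_rep)
  expect_equal(nrow(a$per_rep), 6)
  expect_equal(a$summary$mean_hits,
               as.numeric(tapply(a$per_rep$n_hits, a$per_rep$bin, mean)))
  expect_error(downsample_controls(tc$gene_counts, bins = 50, reps = 2),
               "exceeds")
})

test_that("small control cohorts inflate the apparent-hit count", {
  # private reactivity only, no spikes: bins of 5 controls must admit more
  # apparent hits than bins of 20, on average across seeds
  gap <- numeric(5)
  for (s in 1:5) {
    tc <- tiny_cohort(seed = 600 + s, n_genes = 200, peptides_per_gene = 4,
                      n_cases = 15, n_controls = 30, n_mock = 3,
                      private_reactivity_rate = 3)
    ds <- downsample_controls(tc$gene_counts, bins = c(5, 20), reps = 5,
                              seed = s)
    gap[s] <- ds$summary$mean_hits[ds$summary$bin == 5] -
      ds$summary$mean_hits[ds$summary$bin == 20]
  }
  expect_gt(mean(gap), 0)
})
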