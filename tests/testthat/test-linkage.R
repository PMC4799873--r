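# Two-point LOD scores: closed form, analytic maximiser, cluster scores.

test_that("lod matches direct evaluation of the closed form", {
  expect_equal(lod(18, 6, 0.25), 1.3635, tolerance = 5e-4)
  expect_equal(lod(23, 1, 1 / 24), 5.419, tolerance = 5e-4)
  # theta = 0.5 gives exactly zero for any counts
  set.seed(1)
  for (i in 1:20) {
    nr <- sample(0:40, 1); r <- sample(0:40, 1)
    expect_identical(lod(nr, r, 0.5), 0)
  }
  # theta = 0: perfect linkage value with no recombinants, -Inf with any
  expect_equal(lod(24, 0, 0), 24 * log10(2))
  expect_identical(lod(23, 1, 0), -Inf)
})

test_that("recombinant counts classify chromosomes by the ancestral allele", {
  expect_identical(count_recombinants(FIX_TAB, FIX_ANC, "DXS1108"),
                   c(NR = 23L, R = 1L))
  expect_identical(count_recombinants(FIX_TAB, FIX_ANC, "DXS7423"),
                   c(NR = 18L, R = 6L))
  expect_identical(count_recombinants(FIX_TAB, FIX_ANC, "STR24"),
                   c(NR = 22L, R = 2L))
  # all ancestral -> no recombinants
  map <- tiny_map()
  tab <- tiny_table(map, matrix(c(10L, 20L), 5, 2, byrow = TRUE))
  anc <- infer_ancestral(tab)
  expect_identical(count_recombinants(tab, anc, "A"), c(NR = 5L, R = 0L))
})

test_that("maximize_lod uses the analytic MLE theta = R/(NR+R)", {
  r <- maximize_lod(21, 3)
  expect_equal(r$theta_max, 0.125)
  expect_equal(r$lod_max, 3.2976, tolerance = 5e-4)
  r0 <- maximize_lod(24, 0)
  expect_equal(r0$theta_max, 0)
  expect_equal(r0$lod_max, 24 * log10(2))
})

test_that("analytic maximiser agrees with fine-grid search for all counts up to 50", {
  grid <- seq(1e-4, 0.5, by = 1e-4)
  l2g <- log10(2 * grid); l2g1 <- log10(2 * (1 - grid))
  for (n in 1:50) {
    for (R in 0:n) {
      NR <- n - R
      curve <- NR * l2g1 + R * l2g
      best <- grid[which.max(curve)]
      analytic <- min(max(R / n, 0), 0.5)
      got <- maximize_lod(NR, R)$theta_max
      expect_equal(got, analytic)
      # grid argmax within one grid step of the analytic maximiser
      expect_lt(abs(best - max(analytic, 1e-4)), 1.5e-4)
      expect_gte(maximize_lod(NR, R)$lod_max, max(curve) - 1e-9)
    }
  }
})

test_that("lod is concave in theta and matches numeric optimisation", {
  set.seed(2)
  for (i in 1:10) {
    NR <- sample(1:40, 1); R <- sample(1:20, 1)
    th <- seq(0.01, 0.49, by = 0.01)
    v <- lod(NR, R, th)
    expect_true(all(diff(v, differences = 2) < 1e-8))  # concavity
    opt <- optimize(function(t) lod(NR, R, t), c(1e-9, 0.5), maximum = TRUE,
                    tol = 1e-10)
    expect_equal(opt$maximum, min(R / (NR + R), 0.5), tolerance = 1e-6)
  }
})

test_that("lod is symmetric under (NR,R) swap with theta -> 1 - theta", {
  # restricted to the valid domain: compare the raw likelihood-ratio form
  raw <- function(NR, R, th) NR * log10(2 * (1 - th)) + R * log10(2 * th)
  set.seed(3)
  for (i in 1:10) {
    NR <- sample(1:30, 1); R <- sample(1:30, 1); th <- runif(1, 0.05, 0.45)
    expect_equal(raw(NR, R, th), raw(R, NR, 1 - th), tolerance = 1e-12)
  }
})

test_that("cluster LOD sums member curves at a shared theta", {
  members <- lapply(1:3, function(i) maximize_lod(22, 2, locus = paste0("S", i)))
  cl <- cluster_lod(members)
  expect_equal(cl$theta_max, 1 / 12, tolerance = 1e-12)
  expect_equal(cl$lod_max, 3 * maximize_lod(22, 2)$lod_max, tolerance = 1e-12)
  expect_equal(cl$lod_max, 12.705, tolerance = 5e-3)

  # single member passes through unchanged
  expect_identical(cluster_lod(members[1]), members[[1]])

  # brute-force maximisation of the summed curve on a fine grid
  grid <- seq(1e-4, 0.5, by = 1e-4)
  summed <- Reduce(`+`, lapply(members, function(m) lod(m$NR, m$R, grid)))
  expect_lt(abs(grid[which.max(summed)] - cl$theta_max), 1.5e-4)
})

test_that("classification thresholds are exposed", {
  expect_equal(LOD_LINKAGE_THRESHOLD, 3)
  expect_equal(LOD_EXCLUSION_THRESHOLD, -2)
})

test_that("linkage_table covers every marker plus the requested cluster", {
  lt <- linkage_table(FIX_TAB, FIX_ANC, cluster = c("STR24", "STR22", "STR13"))
  expect_equal(length(lt), 7L)
  expect_equal(lt[["STR24/STR22/STR13"]]$lod_max, 12.705, tolerance = 5e-3)
  expect_equal(lt[["DXS1108"]]$NR + lt[["DXS1108"]]$R, 24L)
  expect_error(linkage_table(FIX_TAB, FIX_ANC, cluster = "nope"),
               "not in map")
})
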