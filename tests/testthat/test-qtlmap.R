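test_that("expected genotype scores honour observed markers and flanking symmetry", {
  map <- simulate_genetic_map(2, 20, 10)  # markers at 0, 10, 20
  geno <- simulate_ril_genotypes(map, 80, seed = 51)
  grid <- build_scan_grid(geno, map, step_cM = 1)

  # at observed markers E[x] equals the observed code
  for (mk in map$marker) {
    j <- which(grid$positions$chrom == map$chrom[map$marker == mk] &
                 grid$positions$pos == map$pos[map$marker == mk])
    expect_equal(unname(grid$Ex[, j]), unname(geno[, mk]))
  }
  expect_true(all(grid$Ex >= -1 & grid$Ex <= 1))

  # midpoint between agreeing tightly linked flanks tends to the shared code
  map2 <- validate_map(data.frame(marker = c("l", "r"), chrom = "1",
                                  pos = c(0, 0.2)))
  g2 <- matrix(c(1, -1, 1, -1), 2, 2, dimnames = list(c("a", "b"), c("l", "r")))
  gr2 <- build_scan_grid(g2, map2, step_cM = 0.1)
  mid <- which(abs(gr2$positions$pos - 0.1) < 1e-9)
  expect_equal(gr2$Ex[, mid], c(a = 1, b = -1), tolerance = 1e-3)

  # midpoint between disagreeing flanks at equal distance is exactly 0
  g3 <- matrix(c(1, -1), 1, 2, dimnames = list("a", c("l", "r")))
  map3 <- validate_map(data.frame(marker = c("l", "r"), chrom = "1",
                                  pos = c(0, 10)))
  gr3 <- build_scan_grid(g3, map3, step_cM = 5)
  expect_equal(unname(gr3$Ex[1, gr3$positions$pos == 5]), 0)

  # missing flank: conditioning falls back to the nearest observed markers
  gm <- mask_genotypes(geno, 0.15, seed = 52)
  grm <- build_scan_grid(gm, map, step_cM = 1)
  obs <- !is.na(gm[, "M1_02"])
  j <- which(grm$positions$chrom == "1" & grm$positions$pos == 10)
  expect_equal(unname(grm$Ex[obs, j]), unname(gm[obs, "M1_02"]))
  expect_true(all(abs(grm$Ex[!obs, j]) < 1))
})

test_that("with no cofactors the scan equals single-marker regression in closed form", {
  map <- std_map()
  geno <- std_geno()
  grid_mk <- build_scan_grid(geno, map, step_cM = 5)  # positions = markers
  set.seed(53)
  y <- rnorm(200) + 0.5 * geno[, "M3_05"]
  sc <- cim_scan(y, grid_mk, cofactors = NULL)
  n <- length(y)
  for (k in sample(nrow(sc), 10)) {
    mk <- map$marker[map$chrom == sc$chrom[k] & map$pos == sc$pos[k]]
    r2 <- cor(y, geno[, mk])^2
    expect_equal(sc$lod[k], (n / 2) * log10(1 / (1 - r2)), tolerance = 1e-8)
    expect_equal(sc$effect[k], unname(coef(lm(y ~ geno[, mk]))[2]),
                 tolerance = 1e-8)
  }
  # LOD/LRT conversion is exact everywhere
  expect_equal(sc$lrt, sc$lod * 2 * log(10), tolerance = 1e-12)
})

test_that("scan is invariant to phenotype shifts and scales effects linearly", {
  geno <- std_geno()
  grid <- std_grid()
  set.seed(54)
  y <- rnorm(200) + 0.4 * geno[, "M2_09"]
  cof <- select_cofactors(y, grid)
  s1 <- cim_scan(y, grid, cof)
  s2 <- cim_scan(y + 100, grid, cof)
  s3 <- cim_scan(3 * y, grid, cof)
  expect_equal(s1$lrt, s2$lrt, tolerance = 1e-8)
  expect_equal(s1$lrt, s3$lrt, tolerance = 1e-8)
  expect_equal(3 * s1$effect, s3$effect, tolerance = 1e-8)
})

test_that("cofactor selection is deterministic, bounded and finds planted markers", {
  geno <- std_geno()
  grid <- std_grid()
  set.seed(55)
  y <- rnorm(200) + 1.2 * geno[, "M4_07"]
  sel <- select_cofactors(y, grid)
  expect_equal(sel[1], "M4_07")
  expect_lte(length(sel), 5)
  expect_identical(sel, select_cofactors(y, grid))
  expect_identical(select_cofactors(y, grid, max_cofactors = 0), character(0))

  # under the null, forward-BIC admits a small spurious set: genome-wide
  # multiplicity over ~95 markers means a clean stop at zero happens in only
  # about a third of null traits, and the count stays well below the cap
  set.seed(56)
  n_cof <- replicate(100, length(select_cofactors(rnorm(200), grid)))
  expect_gte(mean(n_cof == 0), 0.2)
  expect_gte(mean(n_cof <= 2), 0.7)
  expect_lt(mean(n_cof), 2)
})

test_that("cofactors inside the exclusion window do not absorb the tested position", {
  geno <- std_geno()
  grid <- std_grid()
  set.seed(57)
  y <- rnorm(200, sd = 0.5) + 0.8 * geno[, "M2_09"]  # QTL at chr2, 40 cM
  # force the planted marker itself in as a cofactor: within the 10 cM
  # window it must be excluded, so the peak survives at its position
  sc <- cim_scan(y, grid, cofactors = "M2_09", window_cM = 10)
  k <- which(sc$chrom == "2" & sc$pos == 40)
  expect_gt(sc$lod[k], 10)
  # far from the cofactor the background effect is regressed out: LRT there
  # is smaller than in a scan without the cofactor
  sc0 <- cim_scan(y, grid, cofactors = NULL)
  far <- sc$chrom != "2"
  expect_lt(mean(sc$lrt[far]), mean(sc0$lrt[far]) + 1)
})

test_that("permutation thresholds are reproducible and sized sensibly", {
  geno <- std_geno()
  grid <- std_grid()
  tr <- simulate_replicated_traits(geno, std_map(), null_specs(5), seed = 58)
  cvm <- cv_phenotypes(tr)$cv_mean

  expect_warning(
    thr <- permutation_threshold(cvm, grid, n_traits = 10, n_perm = 60,
                                 alpha = 0.05, seed = 59),
    "traits available")
  thr2 <- suppressWarnings(
    permutation_threshold(cvm, grid, n_traits = 10, n_perm = 60,
                          alpha = 0.05, seed = 59))
  expect_identical(thr$threshold, thr2$threshold)
  expect_equal(dim(thr$max_lrt), c(60, 5))
  # genome-wide max-LRT threshold must exceed the pointwise chi-square cutoff
  expect_gt(thr$threshold, qchisq(0.95, 1))

  # n_perm = 1, n_traits = 1 -> the threshold is that single max LRT
  thr1 <- suppressWarnings(
    permutation_threshold(cvm[, 1, drop = FALSE], grid, n_traits = 1,
                          n_perm = 1, alpha = 0.5, seed = 60))
  expect_equal(thr1$threshold, thr1$max_lrt[1, 1])

  # relabeling lines leaves the permutation null unchanged (the null depends
  # only on the multiset of phenotype values and the genotypes): thresholds
  # from the original and a relabeled phenotype agree to Monte-Carlo error
  set.seed(61)
  perm <- sample(nrow(cvm))
  thr3 <- permutation_threshold(cvm[, 1, drop = FALSE], grid, n_traits = 1,
                                n_perm = 250, seed = 62, alpha = 0.05)
  thr4 <- permutation_threshold(cvm[perm, 1, drop = FALSE], grid,
                                n_traits = 1, n_perm = 250, seed = 63,
                                alpha = 0.05)
  expect_lt(abs(thr3$threshold - thr4$threshold), 2.5)
})

test_that("greedy peak calling enforces the exclusion window and support regions", {
  # synthetic scan: two peaks 3 cM apart -> one call; 20 cM apart -> two
  pos <- 0:60
  mk_scan <- function(lrt) {
    s <- data.frame(chrom = "1", pos = pos, lrt = lrt,
                    lod = lrt / (2 * log(10)), effect = 1)
    attr(s, "trait_id") <- "t"
    class(s) <- c("qtl_scan", "data.frame")
    s
  }
  lrt <- rep(0, 61)
  lrt[pos == 20] <- 30; lrt[pos == 23] <- 25
  calls <- call_qtl(mk_scan(lrt), threshold = 10)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 20)

  lrt2 <- rep(0, 61)
  lrt2[pos == 20] <- 30; lrt2[pos == 40] <- 25
  calls2 <- call_qtl(mk_scan(lrt2), threshold = 10)
  expect_equal(sort(calls2$pos), c(20, 40))

  # all below threshold -> empty
  expect_equal(nrow(call_qtl(mk_scan(rep(1, 61)), threshold = 10)), 0)

  # support region = contiguous above-threshold span
  lrt3 <- rep(0, 61)
  lrt3[pos >= 18 & pos <= 26] <- 15
  lrt3[pos == 22] <- 35
  calls3 <- call_qtl(mk_scan(lrt3), threshold = 10)
  expect_equal(calls3$support_start[1], 18)
  expect_equal(calls3$support_end[1], 26)

  # LRT ties break to the leftmost genome position
  lrt4 <- rep(0, 61)
  lrt4[pos %in% c(10, 50)] <- 20
  calls4 <- call_qtl(mk_scan(lrt4), threshold = 10)
  expect_equal(calls4$pos[1], 10)
})

test_that("cis/trans classification uses a closed 5 cM window", {
  calls <- data.frame(chrom = c("1", "1", "2", "1"),
                      pos = c(30, 35.1, 30, 35))
  cls <- classify_cis_trans(calls, list(chrom = "1", pos = 30))
  expect_equal(cls, c("cis", "trans", "trans", "cis"))
  expect_equal(classify_cis_trans(calls, NULL),
               rep("unclassified", 4))
})
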