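test_that("quantile normalization equalizes per-sample distributions", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  # identical samples are unchanged
  m2 <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(m2), m2)

  # any input: per-sample means equal, per-sample sorted values identical
  set.seed(1)
  m3 <- matrix(rlnorm(200), 50, 4)
  out3 <- quantile_normalize(m3)
  expect_equal(diff(range(colMeans(out3))), 0, tolerance = 1e-12)
  ref <- sort(out3[, 1])
  for (j in 2:4) expect_equal(sort(out3[, j]), ref, tolerance = 1e-12)
  # rank order within each sample preserved
  for (j in 1:4) expect_equal(order(out3[, j]), order(m3[, j]))

  expect_warning(quantile_normalize(matrix(1:3, 3, 1)), "single-sample")
  expect_error(quantile_normalize(matrix(c(1, NA), 1, 2)), "missing")
})

test_that("compute_cv matches hand values and its invariances", {
  expect_equal(compute_cv(c(5, 5, 5)), 0)
  expect_equal(compute_cv(c(2, 4)), sqrt(2) / 3)
  expect_equal(compute_cv(c(20, 40)), compute_cv(c(2, 4)))
  expect_true(is.na(compute_cv(c(-2, 1))))   # non-positive mean -> undefined
  expect_true(is.na(compute_cv(3)))          # < 2 replicates

  # scale invariance under random positive rescaling (property)
  set.seed(2)
  for (i in 1:25) {
    x <- rlnorm(sample(2:8, 1))
    k <- runif(1, 0.1, 50)
    expect_equal(compute_cv(k * x), compute_cv(x), tolerance = 1e-12)
  }
})

test_that("cv_phenotypes averages per-experiment CVs and propagates missingness", {
  # layout with hand-checkable CVs: one line, one trait, two experiments
  v <- array(NA_real_, c(1, 1, 2, 2),
             dimnames = list("L1", "T1", c("E1", "E2"), c("R1", "R2")))
  v[1, 1, 1, ] <- c(2, 4)     # CV = sqrt(2)/3
  v[1, 1, 2, ] <- c(20, 40)   # same CV
  cvp <- cv_phenotypes(replicated_traits(v))
  expect_equal(unname(cvp$cv[1, 1, ]), rep(sqrt(2) / 3, 2))
  expect_equal(unname(cvp$cv_mean[1, 1]), sqrt(2) / 3)

  # experiment CVs 0.10 and 0.20 -> mean 0.15 (construct exactly)
  # CV of (a, b) is |a-b|/sqrt(2) / mean; choose pairs giving 0.1 and 0.2
  mk <- function(cv) {
    m <- 10
    d <- cv * m * sqrt(2)
    c(m - d / 2, m + d / 2)
  }
  v2 <- v
  v2[1, 1, 1, ] <- mk(0.10)
  v2[1, 1, 2, ] <- mk(0.20)
  cvp2 <- cv_phenotypes(replicated_traits(v2))
  expect_equal(unname(cvp2$cv_mean[1, 1]), 0.15, tolerance = 1e-12)

  # all replicates equal -> all CVs zero
  v3 <- array(7, c(3, 2, 2, 2),
              dimnames = list(paste0("L", 1:3), c("A", "B"), NULL, NULL))
  expect_true(all(cv_phenotypes(replicated_traits(v3))$cv_mean == 0))

  # a missing experiment cell: cv_mean uses the remaining experiment, and
  # no CV is fabricated (non-missing CVs <= valid input cells)
  v4 <- v2
  v4[1, 1, 2, 2] <- NA
  cvp4 <- cv_phenotypes(replicated_traits(v4))
  expect_true(is.na(cvp4$cv[1, 1, 2]))
  expect_equal(unname(cvp4$cv_mean[1, 1]), 0.10, tolerance = 1e-12)
  expect_lte(sum(!is.na(cvp4$cv)), 1)

  # pooled alternative: one CV over all four replicates
  cvp5 <- cv_phenotypes(replicated_traits(v2), pooled = TRUE)
  expect_equal(unname(cvp5$cv_pooled[1, 1]),
               compute_cv(as.vector(v2[1, 1, , ])))
})

test_that("network values equal z-score averages (hand oracle) and are linear", {
  set.seed(3)
  # 2 lines x 3 traits x 2 experiments x 1+1 replicates = 4 samples/trait
  v <- array(rlnorm(2 * 3 * 2 * 2, meanlog = 3), c(2, 3, 2, 2),
             dimnames = list(c("L1", "L2"), c("g1", "g2", "g3"), NULL, NULL))
  tr <- replicated_traits(v)

  nv <- network_values(tr, list(net = c("g1", "g2", "g3")))
  # independent oracle: z-score each trait over its 8 pooled samples, average
  z <- sapply(1:3, function(j) {
    s <- as.vector(v[, j, , ])
    (s - mean(s)) / sd(s)
  })
  oracle <- rowMeans(z)
  expect_equal(as.vector(nv$values[, 1, , ]), oracle, tolerance = 1e-12)

  # a single-member network returns that trait's z-scores
  nv1 <- network_values(tr, list(solo = "g2"))
  expect_equal(as.vector(nv1$values[, 1, , ]), z[, 2], tolerance = 1e-12)

  # two members with identical profiles: network equals either z-profile
  v2 <- v
  v2[, 3, , ] <- v2[, 1, , ]
  nv2 <- network_values(replicated_traits(v2), list(pair = c("g1", "g3")))
  z1 <- (as.vector(v2[, 1, , ]) - mean(v2[, 1, , ])) / sd(as.vector(v2[, 1, , ]))
  expect_equal(as.vector(nv2$values[, 1, , ]), z1, tolerance = 1e-12)

  # union of two disjoint equally sized networks = mean of the two
  nvu <- network_values(tr, list(u = c("g1", "g2")))
  nva <- network_values(tr, list(a = "g1"))
  nvb <- network_values(tr, list(b = "g2"))
  expect_equal(nvu$values[, 1, , ],
               (nva$values[, 1, , ] + nvb$values[, 1, , ]) / 2,
               tolerance = 1e-12)

  # zero-variance member excluded with a message
  v3 <- v
  v3[, 2, , ] <- 5
  expect_message(
    nv3 <- network_values(replicated_traits(v3), list(n = c("g1", "g2"))),
    "zero-variance")
  expect_equal(as.vector(nv3$values[, 1, , ]), z[, 1], tolerance = 1e-12)

  expect_error(network_values(tr, list(bad = "nope")), "absent")
})

test_that("global CV is the unweighted mean across traits", {
  cvm <- rbind(L1 = c(0.1, 0.3), L2 = c(0.2, 0.2))
  colnames(cvm) <- c("a", "b")
  fake <- structure(list(cv = array(cvm, c(2, 2, 1)), cv_mean = cvm,
                         lines = rownames(cvm), traits = colnames(cvm)),
                    class = "cv_phenotypes")
  expect_equal(unname(global_cv(fake)), c(0.2, 0.2))

  # all traits identical CV c -> c; and large case vs independent summation
  set.seed(4)
  big <- matrix(runif(100 * 500, 0.05, 0.5), 100, 500,
                dimnames = list(paste0("L", 1:100), paste0("t", 1:500)))
  fake2 <- structure(list(cv = array(big, c(100, 500, 1)), cv_mean = big,
                          lines = rownames(big), traits = colnames(big)),
                     class = "cv_phenotypes")
  oracle <- apply(big, 1, function(r) sum(r) / length(r))
  expect_equal(global_cv(fake2), oracle, tolerance = 1e-12)
})

test_that("phase groups reduce to networks keyed by circadian time", {
  set.seed(5)
  v <- array(rlnorm(4 * 6 * 2 * 2, 3), c(4, 6, 2, 2),
             dimnames = list(paste0("L", 1:4), paste0("g", 1:6), NULL, NULL))
  tr <- replicated_traits(v)

  # all traits in one group == a single network over all traits
  pg <- suppressWarnings(
    phase_group_values(tr, setNames(rep(0L, 6), paste0("g", 1:6))))
  nv <- network_values(tr, list(CT0 = paste0("g", 1:6)))
  expect_equal(pg$values[, 1, , ], nv$values[, 1, , ])

  # six singleton groups -> six z-score vectors
  pg6 <- suppressWarnings(
    phase_group_values(tr, setNames(0:5, paste0("g", 1:6))))
  expect_equal(dim(pg6$values)[2], 6L)
  for (j in 1:6) {
    s <- as.vector(v[, j, , ])
    expect_equal(as.vector(pg6$values[, j, , ]), (s - mean(s)) / sd(s),
                 tolerance = 1e-12)
  }

  # empty groups warned about; out-of-range groups rejected
  expect_warning(phase_group_values(tr, setNames(rep(3L, 6), paste0("g", 1:6))),
                 "empty")
  expect_error(phase_group_values(tr, setNames(rep(25L, 6), paste0("g", 1:6))),
               "0..23")
})
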