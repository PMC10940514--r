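test_that("module assignment is balanced, labeled 0..M-1, and seeded", {
  lab <- assign_modules(600, 6, seed = 1)
  expect_equal(sort(unique(lab)), 0:5)
  expect_true(all(table(lab) == 100))
  expect_identical(assign_modules(600, 6, seed = 1), lab)
  expect_setequal(as.integer(table(assign_modules(5, 2, seed = 3))), c(3L, 2L))
  expect_identical(unique(assign_modules(6, 1, seed = 2)), 0L)
  expect_error(assign_modules(5, 6), "invalid configuration")
  expect_error(assign_modules(5, 0), "invalid configuration")
})

test_that("pair sampling respects the intra/inter probabilities and p2 <= p1", {
  lab4 <- c(0L, 0L, 1L, 1L)
  pr <- sample_pairs(lab4, 1, 0, seed = 1)
  expect_equal(nrow(pr), 2L)
  expect_true(all(lab4[pr[, 1]] == lab4[pr[, 2]]))
  expect_equal(nrow(sample_pairs(lab4, 0, 0, seed = 1)), 0L)
  expect_error(sample_pairs(lab4, 0.1, 0.5), "p2 > p1")
  expect_warning(sample_pairs(lab4, 0.1, 0.5, on_p2_greater = "warn"),
                 "p2 > p1")

  lab <- assign_modules(100, 4, seed = 9)
  pr <- sample_pairs(lab, 0.5, 0.2, seed = 10)
  expect_true(all(pr[, 1] < pr[, 2]))          # unordered, no self-pairs
  expect_equal(anyDuplicated(pr), 0L)
})

test_that("pair counts at N=600 concentrate around their binomial expectations", {
  lab <- assign_modules(600, 6, seed = 42)
  pr <- sample_pairs(lab, 0.05, 0.02, seed = 43)
  n_intra <- 6 * choose(100, 2)
  n_inter <- choose(600, 2) - n_intra
  same <- lab[pr[, 1]] == lab[pr[, 2]]
  expect_lt(abs(sum(same) - n_intra * 0.05),
            4 * sqrt(n_intra * 0.05 * 0.95))
  expect_lt(abs(sum(!same) - n_inter * 0.02),
            4 * sqrt(n_inter * 0.02 * 0.98))
})

test_that("weight assignment is bidirectional with truncated-normal magnitudes", {
  n <- 6L
  expect_equal(assign_weights(matrix(integer(0), ncol = 2), n, seed = 1),
               matrix(0, n, n))
  w1 <- assign_weights(cbind(1L, 2L), n, seed = 2)
  nz <- which(w1 != 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 2L)
  expect_setequal(paste(nz[, 1], nz[, 2]), c("1 2", "2 1"))
  expect_true(all(abs(w1[nz]) > 0 & abs(w1[nz]) < 1))

  lab <- assign_modules(300, 3, seed = 5)
  pr <- sample_pairs(lab, 0.6, 0.3, seed = 6)
  w <- assign_weights(pr, 300, seed = 7)
  expect_identical(w != 0, t(w) != 0)          # structural symmetry
  expect_true(all(abs(w[w != 0]) < 1))
  # the two directions of a pair are independent draws
  expect_false(any(abs(w[pr]) == abs(w[pr[, 2:1]])))
})

test_that("about half of all connected pairs carry opposite signs", {
  pairs <- which(upper.tri(matrix(FALSE, 160, 160)), arr.ind = TRUE)[1:10000, ]
  w <- assign_weights(pairs, 160, seed = 11)
  fwd <- w[pairs]
  rev <- w[pairs[, 2:1]]
  frac_opposite <- mean(sign(fwd) != sign(rev))
  expect_gte(frac_opposite, 0.48)              # 4-sigma binomial band, n = 1e4
  expect_lte(frac_opposite, 0.52)
})

test_that("spectral-radius scaling hits the target and rejects nilpotent input", {
  expect_equal(scale_spectral_radius(diag(2), 0.85), 0.85 * diag(2))
  upper <- matrix(c(0, 3, 0, 0), 2, 2)
  expect_error(scale_spectral_radius(upper, 0.85), "degenerate reservoir")
  expect_error(scale_spectral_radius(matrix(0, 3, 3), 0.5),
               "degenerate reservoir")

  set.seed(12)
  w <- matrix(rnorm(64), 8, 8)
  ws <- scale_spectral_radius(w, 0.85)
  expect_equal(charpoly_radius(ws), 0.85, tolerance = 1e-8)
})

test_that("input weights are uniform on (-scale, scale)", {
  w <- generate_input_weights(600, 128, 0.1, seed = 3)
  expect_equal(dim(w), c(600L, 128L))
  expect_true(all(w > -0.1 & w < 0.1))
  se4 <- 4 * (0.1 / sqrt(3)) / sqrt(600 * 128)
  expect_lt(abs(mean(w)), se4)
  expect_error(generate_input_weights(10, 2, scale = 0), "scale")
})

test_that("generate_reservoir satisfies its invariants and is seed-reproducible", {
  res <- generate_reservoir(n = 200, modules = 4, p1 = 0.1, p2 = 0.04,
                            rho = 0.85, d = 16, seed = 21)
  expect_s3_class(res, "mesn_reservoir")
  expect_identical(res$w_rc != 0, t(res$w_rc) != 0)
  expect_equal(spectral_radius(res$w_rc), 0.85, tolerance = 1e-8)
  expect_true(all(res$w_ir > -0.1 & res$w_ir < 0.1))
  expect_true(all(diag(res$w_rc) == 0))
  res2 <- generate_reservoir(n = 200, modules = 4, p1 = 0.1, p2 = 0.04,
                             rho = 0.85, d = 16, seed = 21)
  expect_identical(res$w_rc, res2$w_rc)
  expect_identical(res$w_ir, res2$w_ir)
  expect_error(generate_reservoir(n = 50, modules = 2, p1 = 0, p2 = 0,
                                  rho = 0.85, d = 2, seed = 1),
               "degenerate reservoir")
})

test_that("M=1 with P1=P2 reduces to an Erdos-Renyi reservoir", {
  res <- generate_reservoir(n = 400, modules = 1, p1 = 0.1, p2 = 0.1,
                            rho = 0.85, d = 2, seed = 31)
  n_pairs <- choose(400, 2)
  expect_lt(abs(nrow(res$pairs) - n_pairs * 0.1),
            4 * sqrt(n_pairs * 0.1 * 0.9))
  # binary degrees should look binomial(399, 0.1): compare variance
  deg <- in_degree(res$w_rc, mode = "binary")
  expect_equal(mean(deg), 399 * 0.1, tolerance = 0.05)
  expect_equal(stats::var(deg), 399 * 0.1 * 0.9, tolerance = 0.25)
})

test_that("reservoir save/load round-trips losslessly", {
  res <- generate_reservoir(n = 40, modules = 2, p1 = 0.4, p2 = 0.1,
                            rho = 0.9, d = 3, seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  write_reservoir(res, path)
  expect_identical(read_reservoir(path), res)
})
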