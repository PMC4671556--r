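test_that("cheng_church returns the whole matrix when it is coherent", {
  A <- matrix(3, 20, 10)
  bcs <- cheng_church(A, cc_params(n_biclusters = 5, seed = 1))
  expect_equal(bcs[[1]]$rows, 1:20)
  expect_equal(bcs[[1]]$cols, 1:10)
  expect_equal(msr(A, bcs[[1]]$rows, bcs[[1]]$cols), 0)
})

test_that("cheng_church respects the delta bound and masks rediscovery", {
  p <- synth_params(n_genes = 60, m_conditions = 20, n_complexes = 2,
                    complex_size_range = c(8, 10),
                    n_planted_conditions = 8, noise_sd = 0.2, seed = 3)
  em <- generate_expression(p)$expression
  params <- cc_params(delta = 0.5, n_biclusters = 8, seed = 3)
  bcs <- cheng_church(em, params)
  expect_lte(length(bcs), 8L)
  for (b in bcs) expect_lte(msr(em, b$rows, b$cols), params$delta)
  sig <- vapply(bcs, function(b) {
    paste(paste(b$rows, collapse = ","), paste(b$cols, collapse = ","))
  }, "")
  expect_false(any(duplicated(sig)))
})

test_that("cheng_church is deterministic under a fixed seed", {
  withr::local_seed(9)
  A <- matrix(rnorm(400), 20, 20)
  b1 <- cheng_church(A, cc_params(n_biclusters = 3, seed = 7))
  b2 <- cheng_church(A, cc_params(n_biclusters = 3, seed = 7))
  expect_identical(b1, b2)
})

test_that("kmeans_rows covers the trivial partitions", {
  withr::local_seed(2)
  A <- matrix(rnorm(80), 8, 10)
  one <- kmeans_rows(A, kmeans_params(k = 1, seed = 1))
  expect_length(one, 1L)
  expect_equal(one[[1]]$rows, 1:8)
  expect_equal(one[[1]]$cols, 1:10)

  all_own <- kmeans_rows(A, kmeans_params(k = 8, seed = 1))
  expect_equal(sort(unlist(lapply(all_own, `[[`, "rows"))), 1:8)
  expect_true(all(lengths(lapply(all_own, `[[`, "rows")) == 1L))
})

test_that("kmeans_rows separates opposite expression patterns", {
  withr::local_seed(4)
  up <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4) + rnorm(20, 0, 0.01)
  down <- matrix(rep(c(4, 3, 2, 1), each = 5), 5, 4) + rnorm(20, 0, 0.01)
  A <- rbind(up, down)
  cl <- kmeans_rows(A, kmeans_params(k = 2, seed = 1))
  groups <- lapply(cl, `[[`, "rows")
  expect_setequal(sort(unlist(groups)), 1:10)
  expect_true(setequal(groups[[1]], 1:5) || setequal(groups[[1]], 6:10))
})

test_that("kmeans_rows output is a partition and handles flat rows", {
  withr::local_seed(6)
  A <- matrix(rnorm(200), 20, 10)
  A[4, ] <- 2  # zero-variance row
  expect_warning(cl <- kmeans_rows(A, kmeans_params(k = 4, seed = 2)),
                 "zero-variance")
  rows <- unlist(lapply(cl, `[[`, "rows"))
  expect_equal(sort(rows), 1:20)   # covering
  expect_false(any(duplicated(rows)))  # disjoint
})
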