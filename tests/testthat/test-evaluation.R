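test_that("overlap score matches the set formula", {
  expect_equal(overlap_score(c("p1", "p2", "p3"), c("p1", "p2", "p3")), 1)
  expect_equal(overlap_score(c("a", "b"), c("x", "y")), 0)
  expect_equal(overlap_score(c("a", "b", "c"),
                             c("a", "b", "u", "v", "w", "x")), 4 / 18)
  expect_error(overlap_score(character(), "a"), "non-empty")
  withr::local_seed(50)
  for (rep in 1:20) {
    A <- sample(letters, sample(2:8, 1))
    B <- sample(letters, sample(2:8, 1))
    expect_equal(overlap_score(A, B), overlap_score(B, A))
    expect_equal(overlap_score(A, B) == 1, setequal(A, B))
  }
})

test_that("matched reference counting uses an inclusive threshold", {
  ref <- complex_set(list(c("a", "b", "c"), c("x", "y")))
  pred <- complex_set(list(c("a", "b", "c")))
  expect_equal(matched_reference_count(pred, ref), 1L)
  expect_equal(matched_reference_count(ref, ref), 2L)
  expect_equal(matched_reference_count(complex_set(), ref), 0L)
  # OS exactly at threshold counts (|int|=2, sizes 3 and 6 -> 4/18 = 0.2222)
  ref2 <- complex_set(list(c("a", "b", "q", "r", "s", "t")))
  pred2 <- complex_set(list(c("a", "b", "z")))
  expect_equal(matched_reference_count(pred2, ref2,
                                       eval_params(4 / 18)), 1L)
})

test_that("Sn/PPV/Acc reproduce the worked example", {
  ref <- complex_set(list(R1 = c("a", "b", "c", "d"), R2 = c("e", "f")))
  pred <- complex_set(list(P1 = c("a", "b", "c"), P2 = c("e", "f", "g")))
  s <- sn_ppv_acc(pred, ref)
  expect_equal(s$sn, 5 / 6)
  expect_equal(s$ppv, 1)
  expect_equal(s$acc, sqrt(5 / 6))

  # a prediction disjoint from every reference complex changes nothing
  pred2 <- complex_set(list(c("a", "b", "c"), c("e", "f", "g"),
                            c("zz1", "zz2")))
  s2 <- sn_ppv_acc(pred2, ref)
  expect_equal(s2$sn, s$sn)
  expect_equal(s2$ppv, s$ppv)

  expect_equal(sn_ppv_acc(ref, ref), list(sn = 1, ppv = 1, acc = 1))
  expect_equal(sn_ppv_acc(complex_set(), ref), list(sn = 0, ppv = 0, acc = 0))
})

test_that("Sn never decreases as predictions are added; PPV may", {
  withr::local_seed(51)
  universe <- sprintf("u%02d", 1:20)
  ref <- random_complex_set(4, universe)
  pred <- unclass(random_complex_set(1, universe))
  prev_sn <- sn_ppv_acc(complex_set(pred, allow_duplicates = TRUE), ref)$sn
  for (step in 1:6) {
    pred <- c(pred, unclass(random_complex_set(1, universe)))
    now <- sn_ppv_acc(complex_set(pred, allow_duplicates = TRUE), ref)$sn
    expect_gte(now, prev_sn)
    prev_sn <- now
  }
})

test_that("mmr solves the exact matching, not the greedy one", {
  ref <- complex_set(list(c("a", "b"), c("c", "d")))
  pred <- complex_set(list(c("a", "b")))
  expect_equal(mmr(pred, ref), 0.5)
  expect_equal(mmr(ref, ref), 1)
  # engineered 2x2 OS matrix [[0.6, 0.5], [0.5, 0]]: optimum 0.5 + 0.5
  w <- matrix(c(0.6, 0.5, 0.5, 0), 2, 2, byrow = TRUE)
  expect_equal(mmr_oracle(w), 0.5)
})

test_that("mmr equals the exhaustive-enumeration oracle", {
  withr::local_seed(52)
  universe <- sprintf("v%02d", 1:14)
  for (rep in 1:100) {
    ref <- random_complex_set(sample(1:5, 1), universe)
    pred <- random_complex_set(sample(1:5, 1), universe)
    w <- matrix(0, length(ref), length(pred))
    for (i in seq_along(ref)) {
      for (j in seq_along(pred)) {
        w[i, j] <- overlap_score(ref[[i]], pred[[j]])
      }
    }
    expect_equal(mmr(pred, ref), mmr_oracle(w, 0.2), tolerance = 1e-9)
  }
})

test_that("metrics are invariant to relabelling and reordering", {
  withr::local_seed(53)
  universe <- sprintf("w%02d", 1:16)
  ref <- random_complex_set(3, universe)
  pred <- random_complex_set(4, universe)
  base <- evaluate_complexes(pred, ref)
  map <- setNames(sprintf("X%02d", sample(16)), universe)
  relab <- function(cs) {
    complex_set(lapply(unclass(cs), function(m) unname(map[m])),
                allow_duplicates = TRUE)
  }
  perm <- evaluate_complexes(relab(pred)[sample(length(pred))],
                             relab(ref)[sample(length(ref))])
  for (f in c("n_matched", "sn", "ppv", "acc", "mmr")) {
    expect_equal(perm[[f]], base[[f]])
  }
})

test_that("paired t-test matches the closed form and conventions", {
  res <- paired_t_test(c(1, 2, 3), c(2, 3, 5))
  expect_equal(res$statistic, 4)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-4, 2))

  same <- paired_t_test(1:4, 1:4)
  expect_equal(same$p_value, 1)
  const <- paired_t_test(1:4, 1:4 + 2)
  expect_equal(const$p_value, 0)
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("evaluate_complexes assembles a coherent report", {
  ref <- complex_set(list(c("a", "b", "c", "d"), c("e", "f")))
  pred <- complex_set(list(c("a", "b", "c"), c("e", "f", "g")))
  rep_ <- evaluate_complexes(pred, ref)
  expect_equal(rep_$n_matched, 2L)
  expect_equal(rep_$n_detected, 2L)
  expect_equal(rep_$acc, sqrt(rep_$sn * rep_$ppv), tolerance = 1e-12)
  td <- tidy(rep_)
  expect_identical(td$metric[1:2], c("n_matched", "n_detected"))
  expect_s3_class(glance(rep_), "tbl_df")
  expect_s3_class(autoplot(rep_), "ggplot")

  empty <- evaluate_complexes(complex_set(), ref)
  expect_equal(empty$n_detected, 0L)
  expect_equal(empty$sn + empty$ppv + empty$acc + empty$mmr, 0)

  perfect <- evaluate_complexes(ref, ref)
  expect_equal(perfect$mmr, 1)
  expect_equal(perfect$n_matched, 2L)
})
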