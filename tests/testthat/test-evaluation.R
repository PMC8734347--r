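cs <- function(...) suppressWarnings(complex_set(list(...)))

test_that("match matrix holds exact overlap, affinity and Jaccard entries", {
  mm <- build_match_matrix(cs(c("a", "b", "c")), cs(c("b", "c", "d")))
  expect_equal(mm$overlap[1, 1], 2L)
  expect_equal(mm$na[1, 1], 4 / 9)
  expect_equal(mm$jaccard[1, 1], 0.5)

  ident <- build_match_matrix(cs(letters[1:5]), cs(letters[1:5]))
  expect_equal(ident$overlap[1, 1], 5L)
  expect_equal(ident$na[1, 1], 1)
  expect_equal(ident$jaccard[1, 1], 1)

  disj <- build_match_matrix(cs(c("a", "b")), cs(c("x", "y")))
  expect_equal(disj$overlap[1, 1], 0L)
  expect_equal(disj$na[1, 1], 0)
  expect_equal(disj$jaccard[1, 1], 0)

  none <- deduplicate(list())  # an empty prediction set
  expect_error(build_match_matrix(none, cs("a")), "empty")
  expect_error(build_match_matrix(cs("a"), none), "empty")
})

test_that("Sn, PPV and ACC follow the overlap-ratio definitions", {
  R <- cs(c("a", "b", "c"), c("d", "e"))
  v <- sn_ppv_acc(build_match_matrix(R, R))
  expect_equal(unname(v), c(1, 1, 1))

  v2 <- sn_ppv_acc(build_match_matrix(cs(c("a", "b", "c", "d")),
                                      cs(c("a", "b"))))
  expect_equal(unname(v2), c(0.5, 1, sqrt(0.5)))

  v3 <- sn_ppv_acc(build_match_matrix(cs(c("a", "b")), cs(c("x", "y"))))
  expect_equal(unname(v3), c(0, 0, 0))
})

test_that("Jaccard matching is strict at 0.5", {
  # J = 2/4 = 0.5 exactly: not a match
  mm <- build_match_matrix(cs(c("a", "b", "c")), cs(c("b", "c", "d")))
  expect_equal(unname(jaccard_prf(mm)), c(0, 0, 0))
  # J = 3/4 > 0.5: full match
  mm2 <- build_match_matrix(cs(c("a", "b", "c")), cs(c("a", "b", "c", "d")))
  expect_equal(unname(jaccard_prf(mm2)), c(1, 1, 1))
  mm3 <- build_match_matrix(cs(letters[1:4]), cs(letters[1:4]))
  expect_equal(unname(jaccard_prf(mm3)), c(1, 1, 1))
})

test_that("affinity matching is inclusive at the threshold", {
  mm <- build_match_matrix(cs(c("a", "b", "c")), cs(c("b", "c", "d")))
  expect_equal(unname(plus_prf(mm, t = 0.2)), c(1, 1, 1))  # 4/9 >= 0.2
  # NA exactly at t matches
  # R = 5 members, P = 5 members, overlap 1 would give 1/25; build 0.2:
  # |R|=5, |P|=1, T=1 -> NA = 1/5 = 0.2
  mm2 <- build_match_matrix(cs(letters[1:5]), cs("a"))
  expect_equal(mm2$na[1, 1], 0.2)
  expect_equal(unname(plus_prf(mm2, t = 0.2)), c(1, 1, 1))
  expect_equal(unname(plus_prf(mm2, t = 0.21)), c(0, 0, 0))
})

test_that("maximum matching ratio equals the exhaustive optimum", {
  mm <- build_match_matrix(cs(c("a", "b", "c")), cs(c("b", "c", "d")))
  expect_equal(mmr(mm), 4 / 9)
  ident <- build_match_matrix(cs(letters[1:3], letters[4:6]),
                              cs(letters[1:3], letters[4:6]))
  expect_equal(mmr(ident), 1)
  disj <- build_match_matrix(cs(c("a", "b")), cs(c("x", "y")))
  expect_equal(mmr(disj), 0)

  set.seed(5)
  for (k in 1:40) {
    n <- sample(1:7, 1); m <- sample(1:7, 1)
    na_mat <- matrix(ifelse(runif(n * m) < 0.5, 0, runif(n * m)), n, m)
    mm_fake <- list(na = na_mat, n = n, m = m)
    expect_equal(mmr(mm_fake), oracle_mmr(na_mat), tolerance = 1e-9)
  }
})

test_that("fraction match counts benchmarks matched at affinity 0.25", {
  ident <- build_match_matrix(cs(letters[1:3]), cs(letters[1:3]))
  expect_equal(frm(ident), 1)
  mixed <- build_match_matrix(cs(c("a", "b", "c"), c("x", "y", "z")),
                              cs(c("a", "b", "c")))
  expect_equal(frm(mixed), 0.5)
  disj <- build_match_matrix(cs(c("a", "b")), cs(c("p", "q")))
  expect_equal(frm(disj), 0)
})

test_that("separation reflects concentration of the overlap matrix", {
  ident <- build_match_matrix(cs(letters[1:3], letters[4:6]),
                              cs(letters[1:3], letters[4:6]))
  expect_equal(separation(ident), 1)
  disj <- build_match_matrix(cs(c("a", "b")), cs(c("x", "y")))
  expect_equal(separation(disj), 0)
  # one benchmark split across two disjoint predictions covering it:
  # sep_1j = (2/4)(2/2) = 1/2 each, total 1; complex-wise 1/1,
  # cluster-wise 1/2 -> SEP = sqrt(1 * 0.5)
  split <- build_match_matrix(cs(c("a", "b", "c", "d")),
                              cs(c("a", "b"), c("c", "d")))
  expect_equal(separation(split), sqrt(0.5))
})

test_that("the full report is self-consistent and hits its identities", {
  R <- suppressWarnings(complex_set(list(letters[1:4], letters[5:7],
                                         letters[8:12])))
  rep <- score_complexes(R, R)
  for (f in c("sn", "ppv", "acc", "precision", "recall", "f_measure",
              "precision_plus", "recall_plus", "f_measure_plus",
              "mmr", "frm", "sep")) {
    expect_equal(rep[[f]], 1)
  }
  expect_equal(rep$cs, 5)
  expect_equal(rep$f_mmr, 2)

  P <- suppressWarnings(complex_set(list(LETTERS[1:4], LETTERS[5:7])))
  rep0 <- score_complexes(R, P)
  for (f in c("sn", "ppv", "acc", "precision", "recall", "f_measure",
              "precision_plus", "recall_plus", "f_measure_plus",
              "mmr", "frm", "sep", "cs", "f_mmr")) {
    expect_equal(rep0[[f]], 0)
  }

  # cross-check against the individually called operations
  set.seed(9)
  R2 <- random_complex_set(5, sprintf("p%02d", 1:25), 31)
  P2 <- random_complex_set(6, sprintf("p%02d", 1:25), 32)
  rep2 <- score_complexes(R2, P2, t = 0.2)
  mm <- build_match_matrix(R2, P2)
  expect_equal(rep2$acc, unname(sn_ppv_acc(mm)["acc"]))
  expect_equal(rep2$f_measure, unname(jaccard_prf(mm)["f_measure"]))
  expect_equal(rep2$f_measure_plus,
               unname(plus_prf(mm, 0.2)["f_measure_plus"]))
  expect_equal(rep2$mmr, mmr(mm))
  expect_equal(rep2$frm, frm(mm))
  expect_equal(rep2$sep, separation(mm))
})

test_that("component metrics stay within their bounds on random sets", {
  for (seed in 1:20) {
    R <- random_complex_set(sample(2:8, 1), sprintf("p%02d", 1:30),
                            seed)
    P <- random_complex_set(sample(2:8, 1), sprintf("p%02d", 1:30),
                            seed + 500)
    rep <- score_complexes(R, P)
    comps <- c("sn", "ppv", "acc", "precision", "recall", "f_measure",
               "precision_plus", "recall_plus", "f_measure_plus",
               "mmr", "frm", "sep")
    for (f in comps) {
      expect_gte(rep[[f]], 0)
      expect_lte(rep[[f]], 1)
    }
    expect_lte(rep$cs, 5)
    expect_lte(rep$f_mmr, 2)
  }
})

test_that("adding a perfect prediction for an unmatched benchmark never hurts", {
  for (seed in 1:10) {
    alphabet <- sprintf("p%02d", 1:40)
    R <- random_complex_set(4, alphabet[1:25], seed, c(3L, 6L))
    P <- random_complex_set(3, alphabet[1:25], seed + 100, c(3L, 6L))
    mm <- build_match_matrix(R, P)
    matched <- apply(mm$na >= 0.2, 1L, any)
    if (all(matched)) next
    target <- which(!matched)[1L]
    P2 <- suppressWarnings(complex_set(c(P$complexes,
                                         R$complexes[target])))
    r1 <- score_complexes(R, P)
    r2 <- score_complexes(R, P2)
    expect_gte(r2$recall, r1$recall)
    expect_gte(r2$recall_plus, r1$recall_plus)
    expect_gte(r2$frm, r1$frm)
    expect_gte(r2$mmr, r1$mmr)
  }
})
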