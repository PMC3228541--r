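test_that("hand-enumerable profiles are exact", {
  # both strands of AAAA: 3 AA windows forward, 3 TT windows on the revcomp
  p <- kmer_profile(seq_records("a", "AAAA"), k = 2)
  expect_equal(p$counts[order(names(p$counts))], c(AA = 3, TT = 3))
  expect_equal(p$total, 6)

  # empty record set gives an empty profile at any k
  e <- kmer_profile(generate_synthetic(0), k = 11)
  expect_equal(e$total, 0)
  expect_length(e$counts, 0)

  # a 200-nt sequence at k=11 contributes 2*(200-11+1) windows
  rec <- generate_synthetic(1, 200, 200, seed = 4)
  p200 <- kmer_profile(rec, k = 11)
  expect_equal(p200$total, 2 * (200 - 11 + 1))
})

test_that("profiles equal the brute-force window oracle", {
  for (alpha in c("dna", "protein")) {
    recs <- generate_synthetic(100, 15, 60, alphabet = alpha, seed = 21)
    ks <- if (alpha == "dna") c(2, 3, 11) else c(2, 3)
    for (k in ks) {
      got <- kmer_profile(recs, k = k)
      want <- oracle_profile(recs, k, include_revcomp = alpha == "dna")
      expect_equal(got$counts[order(names(got$counts))], want,
                   info = sprintf("%s k=%d", alpha, k))
    }
  }
})

test_that("windows containing ambiguity codes are skipped", {
  p <- kmer_profile(seq_records("a", "ACNGT"), k = 2)
  # forward: AC, GT; revcomp ACNGT -> ACNGT: AC, GT again
  expect_equal(p$total, 4)
  expect_false(any(grepl("N", names(p$counts))))
})

test_that("dna profiles are strand-symmetric", {
  recs <- generate_synthetic(25, 30, 90, seed = 31)
  for (i in c(1, 7, 25)) {
    fwd <- kmer_profile(recs[i, ], k = 5)
    rev <- kmer_profile(
      seq_records(recs$id[i], reverse_complement(recs$seq[i])), k = 5
    )
    expect_equal(fwd$counts[order(names(fwd$counts))],
                 rev$counts[order(names(rev$counts))])
  }
})

test_that("profile defaults and guards follow the estimation convention", {
  dna <- generate_synthetic(2, 30, 30, seed = 1)
  prot <- generate_synthetic(2, 30, 30, alphabet = "protein", seed = 1)
  expect_equal(kmer_profile(dna)$k, 11L)
  expect_true(kmer_profile(dna)$include_revcomp)
  expect_equal(kmer_profile(prot)$k, 3L)
  expect_false(kmer_profile(prot)$include_revcomp)
  expect_error(kmer_profile(prot, include_revcomp = TRUE), "dna")
  expect_error(kmer_profile(dna, k = 0), "k must be")
})

test_that("overlap statistic is a dot product, linear in query counts", {
  w <- c(AAA = 0.5, CCC = 0.25, GGG = 0.25)
  q <- kmer_profile(seq_records("q", "AAAACCC"), k = 3, include_revcomp = FALSE)
  # windows: AAA x2, AAC, ACC, CCC -> dot product 2*0.5 + 1*0.25
  expect_equal(overlap_statistic(q, w), 2 * 0.5 + 0.25)

  # doubling every count doubles x
  q2 <- q
  q2$counts <- q$counts * 2
  expect_equal(overlap_statistic(q2, w), 2 * overlap_statistic(q, w))

  # empty query, disjoint keys, k mismatch
  expect_equal(overlap_statistic(kmer_profile(generate_synthetic(0), k = 3), w), 0)
  expect_equal(overlap_statistic(q, c(TTT = 1)), 0)
  expect_error(overlap_statistic(q, w, k = 11), "mismatch")
})

test_that("noiseless calibration recovers the generating line exactly", {
  runs <- tibble::tibble(overlap = c(0, 1, 2, 5, 10),
                         cpu_hours = 0.5 + 2.0 * c(0, 1, 2, 5, 10))
  m <- fit_runtime_model(runs, k = 11, weights = c(A = 1))
  expect_equal(m$alpha, 0.5, tolerance = 1e-10)
  expect_equal(m$beta, 2.0, tolerance = 1e-10)
})

test_that("noisy calibration recovers alpha within 0.1 and beta within 0.05", {
  set.seed(101)
  x <- runif(50, 0, 10)
  runs <- tibble::tibble(overlap = x,
                         cpu_hours = 0.5 + 2.0 * x + rnorm(50, 0, 0.05))
  m <- fit_runtime_model(runs, k = 11, weights = c(A = 1))
  expect_lt(abs(m$alpha - 0.5), 0.1)
  expect_lt(abs(m$beta - 2.0), 0.05)
})

test_that("a negative fitted intercept is clamped to zero", {
  x <- c(1, 2, 3, 4)
  runs <- tibble::tibble(overlap = x, cpu_hours = 2 * x - 0.05)
  m <- fit_runtime_model(runs, k = 11, weights = c(A = 1))
  expect_equal(m$alpha, 0)
  expect_gt(m$beta, 0)
  expect_error(fit_runtime_model(runs[1, ], 11, c(A = 1)), "at least 2")
  same_x <- tibble::tibble(overlap = c(1, 1), cpu_hours = c(1, 2))
  expect_error(fit_runtime_model(same_x, 11, c(A = 1)), "distinct")
})

test_that("predictions follow T = alpha + beta * x and are monotone", {
  w <- c(AAA = 0.5, CCC = 0.5)
  m <- runtime_model(alpha = 0, beta = 1, weights = w, k = 3)
  q <- kmer_profile(seq_records("q", "AAAA"), k = 3, include_revcomp = FALSE)
  x <- overlap_statistic(q, w)
  expect_equal(predict_cpu_hours(m, q), x)

  # empty query predicts the fixed overhead alone
  m2 <- runtime_model(alpha = 0.7, beta = 3, weights = w, k = 3)
  expect_equal(predict_cpu_hours(m2, kmer_profile(generate_synthetic(0), k = 3)), 0.7)

  # monotone non-decreasing in every query count
  q_up <- q
  q_up$counts["AAA"] <- q_up$counts["AAA"] + 1
  expect_gte(predict_cpu_hours(m2, q_up), predict_cpu_hours(m2, q))
})

test_that("held-out prediction error is small when the cost law is linear", {
  ref <- generate_synthetic(30, 200, 300, seed = 51, prefix = "ref")
  w <- reference_weights(kmer_profile(ref, k = 5))
  law <- function(records) {
    0.5 + 2.0 * overlap_statistic(kmer_profile(records, k = 5), w)
  }
  set.seed(52)
  cal <- lapply(1:12, function(i) {
    recs <- generate_synthetic(sample(5:40, 1), 100, 300,
                               seed = 500 + i, prefix = "cal")
    tibble::tibble(
      overlap = overlap_statistic(kmer_profile(recs, k = 5), w),
      cpu_hours = law(recs)
    )
  })
  m <- fit_runtime_model(dplyr::bind_rows(cal), k = 5, weights = w)
  held <- generate_synthetic(60, 100, 300, seed = 999, prefix = "held")
  truth <- law(held)
  pred <- predict_cpu_hours(m, kmer_profile(held, k = 5))
  expect_lt(abs(pred - truth) / truth, 0.05)
})

test_that("profiles and models serialize through the text format", {
  recs <- generate_synthetic(10, 30, 60, seed = 61)
  p <- kmer_profile(recs, k = 4)
  pf <- withr::local_tempfile(fileext = ".json")
  write_profile(p, pf)
  p2 <- read_profile(pf)
  expect_equal(p2$counts[order(names(p2$counts))],
               p$counts[order(names(p$counts))])
  expect_equal(p2$k, p$k)

  m <- runtime_model(0.5, 2, reference_weights(p), 4)
  mf <- withr::local_tempfile(fileext = ".json")
  write_runtime_model(m, mf)
  m2 <- read_runtime_model(mf)
  expect_equal(m2$alpha, m$alpha)
  expect_equal(m2$beta, m$beta)
  q <- kmer_profile(generate_synthetic(5, 30, 60, seed = 62), k = 4)
  expect_equal(predict_cpu_hours(m2, q), predict_cpu_hours(m, q))
})

test_that("tidy and glance expose the calibrated coefficients", {
  m <- runtime_model(0.5, 2, c(AA = 1), 2)
  td <- generics::tidy(m)
  expect_equal(nrow(td), 2L)
  expect_equal(td$estimate, c(0.5, 2))
  g <- generics::glance(m)
  expect_equal(g$alpha, 0.5)
  expect_equal(g$k, 2L)
})
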