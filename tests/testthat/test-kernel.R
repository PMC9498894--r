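test_that("multinomial_transform matches the softmax closed form", {
  # symmetric and shift-invariant cases
  for (alpha in c(1, 100, 140)) {
    k0 <- multinomial_transform(raw_convolution(matrix(0, 3, 4)), alpha)
    expect_equal(unname(k0$probs), matrix(0.25, 3, 4), tolerance = 1e-12)
    kc <- multinomial_transform(raw_convolution(matrix(7.3, 2, 4)), alpha)
    expect_equal(unname(kc$probs), matrix(0.25, 2, 4), tolerance = 1e-12)
  }
  # closed form on an asymmetric row, against the independent scalar oracle
  k <- multinomial_transform(raw_convolution(matrix(c(1, 0, 0, 0), 1)), alpha = 1)
  expect_equal(unname(k$probs[1, ]), oracle_softmax_row(c(1, 0, 0, 0), 1),
               tolerance = 1e-12)
  expect_equal(unname(k$probs[1, ]),
               c(exp(1), 1, 1, 1) / (exp(1) + 3), tolerance = 1e-12)
  # oracle agreement on random rows across the searched temperature range
  set.seed(1)
  for (alpha in c(1, 100, 140)) {
    x <- matrix(rnorm(4 * 5, sd = 0.05), 5, 4)
    k <- multinomial_transform(raw_convolution(x), alpha)
    for (i in 1:5) {
      expect_equal(unname(k$probs[i, ]), oracle_softmax_row(x[i, ], alpha),
                   tolerance = 1e-9)
    }
  }
})

test_that("kernel rows are normalized and entries lie in (0, 1)", {
  set.seed(7)
  for (alpha in c(1, 100, 140)) {
    for (rep in 1:10) {
      k <- multinomial_transform(raw_convolution(matrix(rnorm(48), 12, 4)), alpha)
      expect_true(all(abs(rowSums(k$probs) - 1) < 1e-6))
      expect_true(all(k$probs >= 0 & k$probs <= 1))
      # in (0,1) exactly in log space: probabilities can underflow to 0 in
      # double precision at alpha ~ 100+, but ln T stays finite and < 0
      expect_true(all(is.finite(k$log_probs) & k$log_probs <= 0))
      if (alpha == 1) expect_true(all(k$probs > 0 & k$probs < 1))
    }
  }
})

test_that("shift invariance: adding a constant to a row of X leaves T unchanged", {
  set.seed(3)
  x <- matrix(rnorm(20), 5, 4)
  x2 <- x
  x2[3, ] <- x2[3, ] + 11.5
  for (alpha in c(1, 120)) {
    expect_equal(multinomial_transform(raw_convolution(x), alpha)$probs,
                 multinomial_transform(raw_convolution(x2), alpha)$probs,
                 tolerance = 1e-9)
  }
})

test_that("multinomial_transform validates its input", {
  expect_error(multinomial_transform(matrix(c(1, NA, 1, 1), 1), 1),
               class = "motifconv_numeric_error")
  expect_error(multinomial_transform(matrix(0, 2, 4), alpha = 0),
               class = "motifconv_input_error")
  expect_error(multinomial_transform(matrix(0, 2, 4), alpha = -3),
               class = "motifconv_input_error")
})

logsumexp_ref <- function(v) log(sum(exp(v - max(v)))) + max(v)

test_that("ln T is stable at large alpha (no underflow to -Inf probabilities)", {
  x <- matrix(c(1, 0, 0, 0), 1)
  k <- multinomial_transform(raw_convolution(x), alpha = 140)
  expect_true(all(is.finite(k$log_probs)))
  expect_equal(unname(k$log_probs[1, ]), 140 * x[1, ] - logsumexp_ref(140 * x[1, ]),
               tolerance = 1e-10)
})

test_that("llr_score matches the likelihood-ratio closed form", {
  B <- background_distribution()
  # kernel equal to the background scores 0 on any window
  kb <- background_kernel(4)
  expect_equal(unname(kb$probs[1, ]), unname(B$probs), tolerance = 1e-12)
  for (s in c("ACGT", "TTTT", "GATC")) {
    expect_equal(llr_score(kb, one_hot_encode(s)), 0, tolerance = 1e-9)
  }
  # single-position closed form
  k1 <- multinomial_transform(raw_convolution(matrix(log(c(0.7, 0.1, 0.1, 0.1)), 1)), 1)
  expect_equal(llr_score(k1, one_hot_encode("A")), log(0.7 / 0.295), tolerance = 1e-9)
  # independent scalar oracle on random kernels/windows
  set.seed(11)
  for (rep in 1:10) {
    k <- random_kernel(5)
    w <- random_dna(1, 5)
    expect_equal(llr_score(k, one_hot_encode(w)), oracle_llr(k$probs, w),
                 tolerance = 1e-9)
  }
})

test_that("ambiguous bases contribute zero to the LLR", {
  set.seed(2)
  k <- random_kernel(4)
  full <- llr_score(k, one_hot_encode("ACGT"))
  with_n <- llr_score(k, one_hot_encode("ACNT"))
  pos3 <- unname(log(k$probs[3, 3] / 0.205))  # the G term it replaced
  expect_equal(with_n, full - pos3, tolerance = 1e-9)
})

test_that("llr_score rejects a length mismatch", {
  k <- random_kernel(4)
  expect_error(llr_score(k, one_hot_encode("ACGTA")), class = "motifconv_dim_error")
})

test_that("scan_llr returns N - L + 1 unpadded window scores", {
  set.seed(4)
  k12 <- random_kernel(12)
  s20 <- one_hot_encode(random_dna(1, 20))
  expect_length(scan_llr(k12, s20), 9L)
  expect_length(scan_llr(random_kernel(5), s20), 16L)
  # every element equals llr_score on that window
  k <- random_kernel(3)
  s <- one_hot_encode("ACGTNAGGA")
  sc <- scan_llr(k, s)
  expect_length(sc, 7L)
  for (p in 1:7) {
    win <- new_win <- s$matrix[p:(p + 2L), , drop = FALSE]
    expect_equal(sc[p], sum(log(sweep(k$probs, 2, c(0.295, 0.205, 0.205, 0.295), "/")) * win),
                 tolerance = 1e-9)
  }
  expect_error(scan_llr(k12, one_hot_encode("ACGT")), class = "motifconv_dim_error")
})

test_that("scan of a background-equal kernel is the zero vector", {
  kb <- background_kernel(6)
  sc <- scan_llr(kb, one_hot_encode(random_dna(1, 25)))
  expect_length(sc, 20L)
  expect_equal(sc, rep(0, 20), tolerance = 1e-9)
})

test_that("brute-force enumeration: no window outscores the best k-mer", {
  set.seed(9)
  k <- multinomial_transform(raw_convolution(matrix(rnorm(12, sd = 2), 3, 4)), 1)
  kmers <- all_kmers(3)
  scores <- vapply(kmers, function(w) oracle_llr(k$probs, w), 0)
  best <- names(which.max(scores))
  seq_with_best <- paste0(random_dna(1, 10), best, random_dna(1, 10))
  sc <- scan_llr(k, one_hot_encode(seq_with_best))
  expect_equal(max(sc), max(scores), tolerance = 1e-9)
  expect_true(all(sc <= max(scores) + 1e-9))
})

test_that("likelihood conservation: sum over all windows of exp(LLR) * P(w|B) = 1", {
  set.seed(10)
  bg <- background_distribution()
  for (L in c(2, 3)) {
    k <- random_kernel(L)
    kmers <- all_kmers(L)
    total <- sum(vapply(kmers, function(w) {
      idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
      exp(llr_score(k, one_hot_encode(w), bg)) * prod(bg$probs[idx])
    }, 0))
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("gradient identity: d ln T[i,j] / d X[i,j] = alpha * (1 - T[i,j])", {
  set.seed(12)
  x <- matrix(rnorm(12, sd = 0.02), 3, 4)
  h <- 1e-6
  for (alpha in c(1, 120)) {
    k <- multinomial_transform(raw_convolution(x), alpha)
    for (i in 1:3) for (j in 1:4) {
      xp <- x; xp[i, j] <- x[i, j] + h
      xm <- x; xm[i, j] <- x[i, j] - h
      num <- (multinomial_transform(raw_convolution(xp), alpha)$log_probs[i, j] -
              multinomial_transform(raw_convolution(xm), alpha)$log_probs[i, j]) / (2 * h)
      expect_equal(num, alpha * (1 - k$probs[i, j]), tolerance = 1e-5)
    }
  }
})

test_that("strand consistency: scanning the reverse complement mirrors the scan", {
  set.seed(13)
  for (rep in 1:5) {
    k <- random_kernel(4)
    s <- one_hot_encode(random_dna(1, 18))
    lhs <- scan_llr(k, reverse_complement(s))
    rhs <- rev(scan_llr(motifconv:::rc_kernel(k), s))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("background_distribution enforces its invariants", {
  expect_equal(unname(background_distribution()$probs), c(0.295, 0.205, 0.205, 0.295))
  expect_error(background_distribution(c(0.3, 0.3, 0.3, 0.2)),
               class = "motifconv_input_error")
  expect_error(background_distribution(c(0.5, 0.5, 0, 0)),
               class = "motifconv_input_error")
})
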