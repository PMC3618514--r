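# Wavelet decomposition and wavelet-correlation networks.

test_that("band_bounds reproduces the octave band rule", {
  expect_equal(unname(band_bounds(2.5, 3)), c(0.025, 0.05))
  expect_equal(unname(band_bounds(2.5, 1)), c(0.1, 0.2))
  expect_equal(unname(band_bounds(1.0, 1)), c(0.25, 0.5))
  # the full four-band table at TR = 2.5 s
  tab <- t(vapply(1:4, function(k) band_bounds(2.5, k), numeric(2)))
  expect_equal(unname(tab),
               cbind(c(0.1, 0.05, 0.025, 0.0125),
                     c(0.2, 0.1, 0.05, 0.025)))
  expect_error(band_bounds(0, 1), "positive")
  expect_error(band_bounds(2.5, 0), "integer")
})

test_that("MODWT satisfies the energy identity and shift covariance", {
  set.seed(42)
  for (family in c("la8", "haar")) {
    x <- rnorm(260)
    d <- modwt(x, levels = 4, family = family)
    energy <- sum(vapply(d$W, function(w) sum(w^2), numeric(1))) +
      sum(d$V^2)
    expect_equal(energy, sum(x^2), tolerance = 1e-10)
    # circular shift of the input shifts every level's coefficients
    s <- 17
    ds <- modwt(c(x[-seq_len(s)], x[seq_len(s)]), levels = 4,
                family = family)
    for (j in 1:4) {
      expect_equal(ds$W[[j]],
                   c(d$W[[j]][-seq_len(s)], d$W[[j]][seq_len(s)]))
    }
  }
})

test_that("MODWT handles degenerate and invalid inputs", {
  d <- modwt(rep(0, 150), levels = 4)
  expect_true(all(vapply(d$W, function(w) all(w == 0), logical(1))))
  expect_error(modwt(rnorm(50), levels = 4), "at least 106")
  expect_error(modwt(rnorm(10), levels = 4, family = "haar"), "at least 16")
  # matrix input decomposes columns independently
  m <- matrix(rnorm(300 * 2), 300, 2)
  dm <- modwt(m, levels = 3)
  d1 <- modwt(m[, 1], levels = 3)
  expect_equal(dm$W[[2]][, 1], d1$W[[2]])
})

test_that("MODWT matches an independent frequency-domain computation", {
  set.seed(7)
  for (family in c("la8", "haar")) {
    x <- rnorm(128)
    d <- modwt(x, levels = 4, family = family)
    o <- fft_modwt_oracle(x, levels = 4, family = family)
    for (j in 1:4) expect_equal(d$W[[j]], o[[j]], tolerance = 1e-8)
  }
})

test_that("a 0.035 Hz sinusoid concentrates in level 3 at TR 2.5", {
  t <- (0:1023) * 2.5
  d <- modwt(sin(2 * pi * 0.035 * t), levels = 4)
  v <- vapply(d$W, var, numeric(1))
  expect_equal(which.max(v), 3L)
})

test_that("wavelet correlation behaves at its analytic anchors", {
  set.seed(3)
  x <- rnorm(260)
  dx <- modwt(x)
  expect_equal(wavelet_correlation(dx, dx, 3), 1)
  dneg <- modwt(-x)
  expect_equal(wavelet_correlation(dx, dneg, 3), -1)
  expect_error(wavelet_correlation(dx, modwt(rnorm(300)), 3), "share")
  # boundary exclusion drops a fixed prefix but stays a correlation
  y <- rnorm(260)
  r <- wavelet_correlation(dx, modwt(y), 3, exclude_boundary = TRUE)
  expect_true(abs(r) <= 1)
})

test_that("white-noise wavelet correlations concentrate near zero", {
  set.seed(99)
  n_pairs <- 1000
  m <- matrix(rnorm(260 * 2 * n_pairs), 260)
  d <- modwt(m, levels = 4)
  co <- d$W[[3]]
  r <- vapply(seq_len(n_pairs), function(i) {
    cor(co[, 2 * i - 1], co[, 2 * i])
  }, numeric(1))
  expect_gt(mean(abs(r) < 0.35), 0.95)
})

test_that("level-3 wavelet correlation tracks band-passed Pearson correlation", {
  # long band-limited signals: the band-restricted association measured
  # by the wavelet correlation agrees with the Pearson correlation of
  # ideally filtered signals to within 0.1
  set.seed(5)
  n <- 4096
  tr <- 2.5
  bp <- function() costnet:::.bandlimited_signal(n, tr, 0.025, 0.05)
  shared <- bp()
  for (lambda in c(0.3, 0.7, 0.95)) {
    a <- lambda * shared + sqrt(1 - lambda^2) * bp()
    b <- lambda * shared + sqrt(1 - lambda^2) * bp()
    r_pearson <- cor(a, b)
    da <- modwt(a, tr = tr)
    db <- modwt(b, tr = tr)
    expect_equal(wavelet_correlation(da, db, 3), r_pearson,
                 tolerance = 0.1)
  }
})

test_that("build_connectivity applies the soft threshold w = r^2", {
  set.seed(11)
  bold <- matrix(rnorm(6 * 260), 6, 260)
  rownames(bold) <- sprintf("R%d", 1:6)
  out <- build_connectivity(bold, tr = 2.5, level = 3)
  r <- out$correlation$r
  w <- out$network$w
  expect_equal(r, t(r))
  expect_equal(unname(diag(w)), rep(0, 6))
  off <- upper.tri(r)
  expect_equal(w[off], abs(r[off])^2) # negative r maps to positive weight
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(out$correlation$band_index, 3L)
})

test_that("connectivity is equivariant under region reordering", {
  set.seed(12)
  bold <- matrix(rnorm(8 * 260), 8, 260)
  rownames(bold) <- sprintf("R%d", 1:8)
  perm <- sample(8)
  w1 <- build_connectivity(bold)$network$w
  w2 <- build_connectivity(bold[perm, ])$network$w
  expect_equal(w2, w1[perm, perm])
})

test_that("constant regions raise a named undefined-correlation error", {
  bold <- matrix(rnorm(3 * 260), 3, 260)
  bold[2, ] <- 5
  rownames(bold) <- c("ok1", "flatliner", "ok2")
  expect_error(build_connectivity(bold), "flatliner")
  expect_error(build_connectivity(bold[1, , drop = FALSE]), "2 regions")
})
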