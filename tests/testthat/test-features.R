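# Oracles for the five descriptors and the concatenated vector.

test_that("row standardization gives mean 0, population sd 1 per row", {
  p <- random_pssm(60, seed = 2)
  f <- normalize_pssm(p)$values
  expect_lt(max(abs(rowMeans(f))), 1e-12)
  expect_lt(max(abs(sqrt(rowMeans(f^2)) - 1)), 1e-12)

  # constant rows map to zeros; alternating rows map to exactly +/-1
  m <- rbind(rep(5, 20), rep(c(1, -1), 10))
  f2 <- normalize_pssm(pssm(m))$values
  expect_equal(unname(f2[1, ]), rep(0, 20))
  expect_equal(unname(f2[2, ]), rep(c(1, -1), 10))
})

test_that("Pse-PSSM reduces to column means at lag 0 and matches the
           brute-force lag sum", {
  p <- random_pssm(40, seed = 3)
  nf <- normalize_pssm(p)
  expect_equal(pse_pssm_features(nf, lambda = 0), unname(colMeans(nf$values)))

  # identical rows: lag terms vanish
  flat <- normalize_pssm(pssm(matrix(rep(1:20, each = 6), 6, 20, byrow = FALSE)))
  expect_equal(pse_pssm_features(flat, 1)[21:40], rep(0, 20))

  # 3-row toy: lag entry j = ((r1j - r2j)^2 + (r2j - r3j)^2) / 2
  p3 <- random_pssm(3, seed = 4)
  f <- normalize_pssm(p3)$values
  got <- pse_pssm_features(normalize_pssm(p3), 1)
  expected <- ((f[1, ] - f[2, ])^2 + (f[2, ] - f[3, ])^2) / 2
  expect_equal(got[21:40], unname(expected))
  expect_equal(got[1:20], unname(colMeans(f)))

  expect_error(pse_pssm_features(normalize_pssm(random_pssm(2)), 2), "lag")
})

test_that("average blocks: constant matrix, row identity at L=20, and
           brute-force block means", {
  expect_equal(avblock_features(pssm(matrix(7, 33, 20))), rep(7, 400))

  p20 <- random_pssm(20, seed = 5)
  expect_equal(avblock_features(p20), as.vector(t(p20$scores)))

  # L = 40, column j filled with 1..40: block i mean = (4i - 1)/2
  m <- matrix(rep(1:40, 20), 40, 20)
  got <- avblock_features(pssm(m))
  expect_equal(got, rep((4 * (1:20) - 1) / 2, each = 20))

  # general brute force at awkward L
  p <- random_pssm(33, seed = 6)
  got <- avblock_features(p)
  bnd <- round((1:20) * 33 / 20); lo <- c(0, bnd[-20]) + 1
  for (i in 1:20) for (j in c(1, 11, 20)) {
    exp_ij <- if (lo[i] > bnd[i]) 0 else mean(p$scores[lo[i]:bnd[i], j])
    expect_equal(got[j + 20 * (i - 1)], exp_ij)
  }
})

test_that("wavelet cascade equals the direct convolution definition at
           every level", {
  for (wn in c("haar", "db4")) {
    filt <- memdsn:::wavelet_filters(wn)
    set.seed(17)
    for (rep in 1:50) {
      x <- rnorm(sample(16:120, 1))
      a <- x
      for (lv in 1:4) {
        expect_equal(memdsn:::dwt_step_mat(matrix(a, ncol = 1), filt$hi)[, 1],
                     oracle_dwt_step(a, filt$hi), tolerance = 1e-12)
        a_fast <- memdsn:::dwt_step_mat(matrix(a, ncol = 1), filt$lo)[, 1]
        expect_equal(a_fast, oracle_dwt_step(a, filt$lo), tolerance = 1e-12)
        a <- a_fast
      }
    }
  }
})

test_that("wavelet filters are orthonormal quadrature-mirror pairs", {
  for (wn in c("haar", "db2", "db4")) {
    filt <- memdsn:::wavelet_filters(wn)
    expect_equal(sum(filt$lo^2), 1)
    expect_equal(sum(filt$lo), sqrt(2))
    expect_equal(sum(filt$hi), 0)
  }
  expect_error(memdsn:::wavelet_filters("nope"), "unknown wavelet")
})

test_that("constant columns have all-zero detail statistics under haar", {
  p <- pssm(matrix(rep(seq(-9.5, 9.5), each = 32), 32, 20))
  v <- dwt_features(p, wavelet = "haar")
  idx <- rep(rep(c(TRUE, FALSE), each = 4), times = 4 * 20)  # detail stats
  expect_equal(v[idx], rep(0, sum(idx)))
})

test_that("wavelet descriptor length is independent of sequence length", {
  for (L in c(16, 57, 3000))
    expect_length(dwt_features(random_pssm(L, seed = L)), 640L)
})

test_that("2-D DCT matches the definition, is orthonormal, and keeps a
           fixed low-frequency block", {
  # constant matrix closed form: F(0,0) = c * sqrt(M * N), rest 0
  d <- dct_features(pssm(matrix(3, 7, 20)), 20, 20)
  expect_equal(d[1], 3 * sqrt(7 * 20))
  expect_lt(max(abs(d[-1])), 1e-10)

  # full transform equals the brute-force double sum on a small matrix
  set.seed(8)
  x <- matrix(rnorm(5 * 4), 5, 4)
  expect_equal(memdsn:::dct2(x), oracle_dct2(x), tolerance = 1e-10)

  # Parseval / orthonormality and exact inversion
  p <- random_pssm(30, seed = 9)
  C <- memdsn:::dct2(p$scores)
  expect_equal(sqrt(sum(C^2)), sqrt(sum(p$scores^2)), tolerance = 1e-8)
  B20 <- memdsn:::dct_basis(nrow(p$scores))
  back <- t(B20) %*% C %*% memdsn:::dct_basis(20)
  expect_lt(max(abs(back - p$scores)), 1e-8)

  for (L in c(5, 20, 500))
    expect_length(dct_features(random_pssm(L, seed = L)), 400L)
  # short profiles zero-pad the missing high-order rows
  short <- dct_features(random_pssm(5, seed = 10), 20, 20)
  expect_equal(matrix(short, 20, byrow = TRUE)[6:20, ], matrix(0, 15, 20))
})

test_that("HOG conserves gradient mass and vanishes on constant input", {
  expect_equal(hog_features(pssm(matrix(4, 25, 20))), rep(0, 250))

  for (L in c(16, 444)) {
    p <- random_pssm(L, seed = L + 1)
    h <- hog_features(p, normalize = FALSE)
    expect_length(h, 250L)
    expect_equal(sum(h), oracle_gradient_mass(p$scores), tolerance = 1e-9)
    expect_length(hog_features(p), 250L)
  }
  # normalized histograms have at most unit L2 norm per sub-matrix
  hn <- matrix(hog_features(random_pssm(50, seed = 12)), nrow = 10)
  expect_true(all(colSums(hn^2) <= 1 + 1e-9))
  expect_error(hog_features(pssm(matrix(0, 1, 20))), "at least 2")
})

test_that("concatenated features have the fixed 1730-length layout and
           compose the standalone extractors", {
  cfg <- feature_config()
  p <- random_pssm(100, seed = 13)
  v <- extract_features(p, cfg)
  expect_length(v, 1730L)
  lay <- attr(v, "layout")
  expect_equal(lay$segment, c("pse_pssm", "avblock", "dwt", "dct", "hog"))
  expect_equal(lay$length, c(40L, 400L, 640L, 400L, 250L))
  expect_equal(sum(lay$length), 1730L)
  expect_equal(lay$start, cumsum(c(1L, lay$length[-5])))

  seg <- function(nm) unname(v[lay$start[lay$segment == nm] +
                                 seq_len(lay$length[lay$segment == nm]) - 1])
  expect_equal(seg("pse_pssm"), pse_pssm_features(normalize_pssm(p), 1))
  expect_equal(seg("avblock"), avblock_features(p))
  expect_equal(seg("dwt"), dwt_features(p))
  expect_equal(seg("dct"), dct_features(p))
  expect_equal(seg("hog"), hog_features(p))
})

test_that("output dimension is invariant in L and single-entry changes
           propagate", {
  for (L in c(16, 57, 444, 3000))
    expect_length(extract_features(random_pssm(L, seed = L)), 1730L)

  p <- random_pssm(50, seed = 14)
  q <- p; q$scores[10, 3] <- q$scores[10, 3] + 1
  vp <- extract_features(p); vq <- extract_features(q)
  expect_false(isTRUE(all.equal(vp, vq)))
  # the avblock segment containing row 10 must see the change
  blk <- ceiling(10 / (50 / 20))
  expect_false(vp[40 + 3 + 20 * (blk - 1)] == vq[40 + 3 + 20 * (blk - 1)])
})

test_that("batch extraction is stateless across proteins", {
  ps <- lapply(1:4, function(i) random_pssm(20 + i, seed = i, id = paste0("p", i)))
  m <- extract_feature_matrix(ps)
  perm <- c(3, 1, 4, 2)
  m2 <- extract_feature_matrix(ps[perm])
  expect_equal(unname(m2), unname(m[perm, ]), ignore_attr = TRUE)
  expect_equal(rownames(m2), rownames(m)[perm])
})
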