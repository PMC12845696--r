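test_that("time-domain moments match hand arithmetic and degenerate safely", {
  td <- time_domain_features(c(1, 2, 3, 2))
  expect_equal(td[["mean"]], 2)
  expect_equal(td[["std"]]^2, 0.5)
  expect_equal(td[["rms"]], sqrt(4.5))
  expect_equal(td[["skew"]], 0)
  expect_equal(td[["kurt"]], 2)
  expect_equal(td[["min"]], 1)
  expect_equal(td[["max"]], 3)
  expect_equal(td[["energy"]], 18)

  const <- time_domain_features(rep(-3, 10))
  expect_equal(const[["std"]], 0)
  expect_equal(const[["rms"]], 3)
  expect_equal(const[["mean"]], -3)
  expect_equal(const[["skew"]], 0)
  expect_equal(const[["kurt"]], 0)
  expect_true(attr(const, "degenerate"))
  expect_error(time_domain_features(1), ">= 2")
})

test_that("kurtosis follows the non-excess convention (Gaussian -> 3)", {
  set.seed(1)
  expect_equal(time_domain_features(rnorm(1e5))[["kurt"]], 3, tolerance = 0.1)
})

test_that("features obey scale equivariance", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(128)
    c0 <- runif(1, 0.5, 5)
    td1 <- time_domain_features(x); td2 <- time_domain_features(c0 * x)
    for (s in c("mean", "std", "rms", "min", "max"))
      expect_equal(td2[[s]], c0 * td1[[s]])
    expect_equal(td2[["skew"]], td1[["skew"]])
    expect_equal(td2[["kurt"]], td1[["kurt"]])
    expect_equal(td2[["energy"]], c0^2 * td1[["energy"]])
    sp1 <- spectral_features(x, 128); sp2 <- spectral_features(c0 * x, 128)
    expect_equal(sp2[["specent"]], sp1[["specent"]])
    expect_equal(sp2[["fdom"]], sp1[["fdom"]])
    expect_equal(as.numeric(sample_entropy(c0 * x)),
                 as.numeric(sample_entropy(x)))
  }
})

test_that("spectral features identify tones, uniform spectra, and bandpowers", {
  fs <- 256; N <- 256
  t <- (0:(N - 1)) / fs
  tone <- sin(2 * pi * 4 * t)
  sp <- spectral_features(tone, fs, band_spec(list(c(3, 5), c(10, 20))))
  expect_equal(sp[["fdom"]], 4)
  expect_lt(sp[["specent"]], 1e-6)    # one-hot spectrum
  total_ac <- sp[["bp1"]] + sp[["bp2"]]
  expect_gt(sp[["bp1"]] / total_ac, 0.99)

  # exactly uniform power over the K = 4 one-sided bins of an N = 8 series
  tt <- 0:7
  x <- cos(2 * pi * tt / 8) + cos(2 * pi * 2 * tt / 8) +
    cos(2 * pi * 3 * tt / 8) + 0.5 * cos(pi * tt)
  expect_equal(spectral_features(x, 8)[["specent"]], log(4), tolerance = 1e-9)

  flat <- spectral_features(rep(2, 64), 64)
  expect_true(is.na(flat[["fdom"]]))
  expect_equal(flat[["specent"]], 0)
  expect_true(attr(flat, "flat_spectrum"))
})

test_that("sample entropy matches the brute-force oracle exactly", {
  expect_equal(sample_entropy(rep(1, 20)), 0)

  alt <- rep(c(0, 1), 4)
  expect_equal(as.numeric(sample_entropy(alt, sampen_params(2, 0.5))),
               sampen_bruteforce(alt, 2, 0.5))

  set.seed(7)
  for (n in c(5, 8, 12, 17, 23, 30)) {
    for (m in 1:2) {
      if (n < m + 2) next
      x <- round(rnorm(n), 2)
      got <- as.numeric(sample_entropy(x, sampen_params(m, 0.25)))
      want <- sampen_bruteforce(x, m, 0.25)
      expect_equal(got, want, label = sprintf("n=%d m=%d", n, m))
    }
  }

  # no template matches at a vanishing tolerance -> incomputable sentinel
  res <- sample_entropy(2^(1:8), sampen_params(2, 1e-4))
  expect_true(is.na(res))
  expect_true(attr(res, "incomputable"))
  expect_error(sample_entropy(c(1, 2, 3), sampen_params(2, 0.2)), "length")
})

test_that("shuffling a series never lowers its sample entropy below the sorted version", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- runif(500)
    se_shuffled <- as.numeric(sample_entropy(x))
    se_sorted <- as.numeric(sample_entropy(sort(x)))
    expect_gte(se_shuffled, se_sorted)
  }
})

test_that("the feature table has the canonical 64-column base registry", {
  set.seed(11)
  mats <- lapply(1:10, function(i) matrix(rnorm(64 * 8), 64, 8))
  ft <- build_feature_table(make_windows(mats), extended = TRUE)
  expect_equal(nrow(ft), 10)
  base <- attr(ft, "base_features")
  expect_length(base, 64)
  published_top <- c("acc_z_mean", "acc_mag_mean", "acc_mag_kurt",
                     "acc_x_mean", "acc_y_min", "gyro_y_energy",
                     "acc_mag_skew", "gyro_y_rms", "gyro_y_min",
                     "gyro_z_std", "acc_y_kurt", "gyro_z_energy",
                     "gyro_z_rms", "gyro_y_std", "acc_x_max", "acc_z_min",
                     "acc_x_rms", "gyro_z_skew", "gyro_mag_energy",
                     "acc_x_energy")
  expect_true(all(published_top %in% base))
  expect_true(all(c("acc_z_sampen", "acc_z_specent", "acc_z_fdom",
                    "acc_z_bp1", "acc_z_bp3") %in% names(ft)))
  expect_false(anyNA(ft[, base]))

  # permuting the window order permutes rows but leaves keyed rows identical
  ft_rev <- build_feature_table(make_windows(rev(mats),
                                             indices = rev(seq_along(mats))),
                                extended = FALSE)
  for (i in c(1, 5, 10)) {
    a <- ft[ft$stride_index == i, base]
    b <- ft_rev[ft_rev$stride_index == i, base]
    expect_equal(unname(unlist(a)), unname(unlist(b)))
  }
})
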