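test_that("block partition follows the floor/remainder rule", {
  p <- partition_blocks(10, 3)
  expect_equal(p$sizes, c(4L, 3L, 3L))
  expect_equal(partition_blocks(7, 7)$sizes, rep(1L, 7))
  expect_equal(sum(partition_blocks(93166, 3327)$sizes), 93166L)
  expect_error(partition_blocks(5, 6), "more sites")
  expect_error(partition_blocks(0, 1), "positive")
  d <- tidy(p)
  expect_equal(d$start, c(1L, 5L, 8L))
  expect_equal(d$end, c(4L, 7L, 10L))
})

test_that("profile entries are per-sample block missingness proportions", {
  # N=4, M=2: blocks {1,2} and {3,4}; sample 1 missing at sites 1-2 only
  m <- mat_from_tokens(rbind(
    c("./.", "0/0"), c("./.", "0/1"), c("0/0", "0/0"), c("1/1", "./.")
  ))
  prof <- fit_profile(m, 2)
  expect_equal(prof$p["sample1", ], c(1, 0), ignore_attr = TRUE)
  expect_equal(prof$p["sample2", ], c(0, 0.5), ignore_attr = TRUE)

  # degenerate M = N recovers the exact 0/1 indicator
  prof_id <- fit_profile(m, 4)
  expect_equal(unname(prof_id$p), unname(t(missing_mask(m)) + 0))
})

test_that("all-missing and fully-called samples give constant profile rows", {
  m <- generate_matrix(fixture_spec(
    3, 30, tracks = data.frame(sample = 2, start = 1, end = 30), seed = 4
  ))
  prof <- fit_profile(m, 6)
  expect_equal(unname(prof$p[2, ]), rep(1, 6))
  expect_equal(unname(prof$p[1, ]), rep(0, 6))
})

test_that("hand-enumerated blocks agree with fit_profile on tiny cases", {
  set.seed(9)
  m <- generate_matrix(fixture_spec(4, 11, background_missing = 0.4, seed = 91))
  for (M in c(2, 3, 5, 11)) {
    prof <- fit_profile(m, M)
    sizes <- partition_blocks(11, M)$sizes
    stops <- cumsum(sizes)
    manual <- sapply(seq_len(M), function(j) {
      idx <- (stops[j] - sizes[j] + 1L):stops[j]
      colMeans(missing_mask(m)[idx, , drop = FALSE])
    })
    expect_equal(unname(prof$p), unname(manual))
  }
})

test_that("profile replay masks with the resampled probabilities", {
  m <- generate_matrix(fixture_spec(4, 20, seed = 31))
  prof1 <- fit_profile(
    generate_matrix(fixture_spec(
      3, 40, tracks = data.frame(sample = 1:3, start = 1, end = 40), seed = 1
    )),
    20
  )
  expect_true(all(missing_mask(apply_profile(m, prof1))))

  prof0 <- fit_profile(generate_matrix(fixture_spec(3, 40, seed = 2)), 20)
  out <- apply_profile(m, prof0)
  expect_identical(out$left, m$left)
  expect_identical(out$phased, m$phased)

  expect_error(apply_profile(m, fit_profile(m, 10)), "10 blocks")
})

test_that("masking never un-misses and never touches called alleles", {
  set.seed(77)
  m <- generate_matrix(fixture_spec(6, 50, background_missing = 0.3, seed = 7))
  prof <- fit_profile(
    generate_matrix(fixture_spec(5, 120, background_missing = 0.4, seed = 8)),
    50
  )
  before <- missing_mask(m)
  for (out in list(apply_profile(m, prof),
                   apply_beta(m, beta_missingness(0.4, 0.2)))) {
    after <- missing_mask(out)
    expect_true(all(after[before]))           # missing stays missing
    kept <- !after
    expect_identical(out$left[kept], m$left[kept])
    expect_identical(out$right[kept], m$right[kept])
  }
})

test_that("replayed missingness matches the brute-force resampler in expectation", {
  set.seed(123)
  p <- matrix(runif(50), 5, 10)  # 5 empirical samples x 10 blocks
  prof <- structure(
    list(samples = paste0("e", 1:5), partition = partition_blocks(10, 10),
         p = p),
    class = "missingness_profile"
  )
  rep_m <- generate_matrix(fixture_spec(4, 10, seed = 55))
  runs <- 1500
  fast <- matrix(0, 10, 1)
  brute <- matrix(0, 10, 1)
  for (r in seq_len(runs)) {
    fast <- fast + rowSums(missing_mask(apply_profile(rep_m, prof)))
    brute <- brute + rowSums(brute_profile_mask(p, 4))
  }
  fast <- fast / (runs * 4)
  brute <- brute / (runs * 4)
  expected <- colMeans(p)
  se <- sqrt(expected * (1 - expected) / (runs * 4))
  expect_true(all(abs(fast - expected) <= 4 * se))
  expect_true(all(abs(brute - expected) <= 4 * se))
})

test_that("beta method-of-moments matches closed forms and rejects bad input", {
  b <- beta_missingness(0.5, 0.25)
  expect_equal(b$alpha, 1.5)
  expect_equal(b$beta, 1.5)
  b2 <- beta_missingness(0.3, 0.1)
  expect_equal(b2$alpha / (b2$alpha + b2$beta), 0.3)  # mean is reproduced
  expect_error(beta_missingness(0, 0.1), "strictly between")
  expect_error(beta_missingness(1, 0.1), "strictly between")
  expect_error(beta_missingness(0.5, 0.5), "incompatible")
  expect_error(beta_missingness(0.5, 0), "incompatible")

  m <- generate_matrix(fixture_spec(10, 200, background_missing = 0.35,
                                    seed = 14))
  fit <- fit_beta(m)
  f <- site_missing_prop(m)
  expect_equal(fit$mean, mean(f))
  expect_equal(fit$sd, sqrt(mean((f - mean(f))^2)))
})

test_that("beta masking is seed-deterministic and hits its mean missingness", {
  m <- generate_matrix(fixture_spec(40, 400, seed = 61))
  b <- beta_missingness(0.5, 0.25)
  set.seed(99)
  a1 <- apply_beta(m, b)
  set.seed(99)
  a2 <- apply_beta(m, b)
  expect_identical(a1$left, a2$left)

  set.seed(100)
  got <- mean(missing_mask(apply_beta(m, b)))
  # var per genotype = E[q] (1 - E[q]) inflated by Var(q) across 400 sites
  expect_lt(abs(got - 0.5), 0.05)

  tiny <- beta_missingness(0.001, 0.0005)
  set.seed(101)
  expect_lt(mean(missing_mask(apply_beta(m, tiny))), 0.01)
})

test_that("profile replay is seed-deterministic", {
  m <- generate_matrix(fixture_spec(5, 30, seed = 71))
  prof <- fit_profile(
    generate_matrix(fixture_spec(4, 90, background_missing = 0.5, seed = 72)),
    30
  )
  set.seed(5)
  a1 <- apply_profile(m, prof)
  set.seed(5)
  a2 <- apply_profile(m, prof)
  expect_identical(a1$left, a2$left)
  expect_identical(a1$phased, a2$phased)
})

test_that("PLINK-style summary counts per site and per sample", {
  m <- mat_from_tokens(rbind(c("./.", "0/1"), c("0/0", "1/1")))
  s <- summarize_missingness(m)
  expect_equal(s$per_site$f_miss, c(0.5, 0))
  expect_equal(s$per_sample$f_miss, c(0.5, 0))
  expect_equal(s$per_site$n_miss, c(1L, 0L))
  expect_equal(s$mean, 0.25)

  clean <- generate_matrix(fixture_spec(3, 10, seed = 3))
  sc <- summarize_missingness(clean)
  expect_true(all(sc$per_site$f_miss == 0))
  expect_true(all(sc$per_sample$f_miss == 0))

  # double-counting identity: site-mean equals sample-mean
  r <- generate_matrix(fixture_spec(7, 40, background_missing = 0.3, seed = 6))
  sr <- summarize_missingness(r)
  expect_equal(mean(sr$per_site$f_miss), mean(sr$per_sample$f_miss))
})

test_that("missingness reports are written as vmiss/smiss TSV", {
  m <- generate_matrix(fixture_spec(4, 15, background_missing = 0.2, seed = 9))
  prefix <- file.path(withr::local_tempdir(), "rep")
  write_missingness_report(summarize_missingness(m), prefix)
  v <- read.delim(paste0(prefix, ".vmiss"))
  s <- read.delim(paste0(prefix, ".smiss"))
  expect_equal(names(v), c("CHROM", "POS", "N_MISS", "F_MISS"))
  expect_equal(names(s), c("SAMPLE", "N_MISS", "F_MISS"))
  expect_equal(v$F_MISS, unname(site_missing_prop(m)))
  expect_equal(s$N_MISS, unname(colSums(missing_mask(m))))
})
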