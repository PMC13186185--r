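# Shared fixtures and independent oracles for the test suite.

# Build a geno_matrix from VCF-style genotype tokens ("0/1", ".|.", "0/.").
mat_from_tokens <- function(tokens, alleles = "A,T", chrom = "1",
                            pos = NULL, samples = NULL) {
  tokens <- as.matrix(tokens)
  n <- nrow(tokens)
  if (is.null(pos)) pos <- seq_len(n)
  if (length(alleles) == 1L) alleles <- rep(alleles, n)
  re <- "^(\\.|[0-9]+)([/|])(\\.|[0-9]+)$"
  stopifnot(all(grepl(re, tokens)))
  toi <- function(a) {
    matrix(suppressWarnings(as.integer(ifelse(a == ".", NA, a))), n)
  }
  geno_matrix(chrom, pos, alleles,
              left = toi(sub(re, "\\1", tokens)),
              right = toi(sub(re, "\\3", tokens)),
              phased = matrix(sub(re, "\\2", tokens) == "|", n),
              samples = samples)
}

# Exhaustive DTW oracle: enumerate every monotone warping path from (1,1)
# to (n,m) and return the minimal summed |a_i - b_k|. Exponential; only for
# tiny signals.
dtw_enum <- function(a, b) {
  n <- length(a)
  m <- length(b)
  best <- Inf
  walk <- function(i, k, acc) {
    acc <- acc + abs(a[i] - b[k])
    if (acc >= best) return(invisible(NULL))
    if (i == n && k == m) {
      best <<- acc
      return(invisible(NULL))
    }
    if (i < n) walk(i + 1L, k, acc)
    if (k < m) walk(i, k + 1L, acc)
    if (i < n && k < m) walk(i + 1L, k + 1L, acc)
  }
  walk(1L, 1L, 0)
  best
}

# Brute-force profile resampler: explicit per-(sample, site) loops, kept
# deliberately independent of apply_profile()'s vectorised code path.
# Returns an M x T logical mask.
brute_profile_mask <- function(p, T_) {
  S <- nrow(p)
  M <- ncol(p)
  mask <- matrix(FALSE, M, T_)
  for (t in seq_len(T_)) {
    for (j in seq_len(M)) {
      s <- sample.int(S, 1L)
      mask[j, t] <- runif(1L) < p[s, j]
    }
  }
  mask
}

# Set the first genotype of a matrix fully missing (for negative-path tests).
mask_genotypes_for_test <- function(m) {
  m$left[1, 1] <- NA_integer_
  m$right[1, 1] <- NA_integer_
  m$phased[1, 1] <- FALSE
  m
}

# Numeric method-of-moments oracle for beta shapes: recover (alpha, beta)
# from a target mean/sd by minimising the squared moment mismatch, instead
# of the closed form used by the implementation.
beta_shapes_numeric <- function(mean, sd) {
  obj <- function(par) {
    a <- exp(par[1])
    b <- exp(par[2])
    mu <- a / (a + b)
    v <- a * b / ((a + b)^2 * (a + b + 1))
    (mu - mean)^2 + (v - sd^2)^2
  }
  fit <- optim(c(0, 0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  exp(fit$par)
}

# Synthetic "empirical" segment with three high-missingness regions shared
# across samples (each sample carries a full track over a region with
# probability 0.7) over 10% background missingness.
make_structured_empirical <- function(seed, S = 25L, N = 1000L) {
  set.seed(seed)
  regions <- list(c(101L, 250L), c(451L, 650L), c(851L, 950L))
  rows <- list()
  for (s in seq_len(S)) {
    for (r in which(runif(3) < 0.7)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, start = regions[[r]][1], end = regions[[r]][2]
      )
    }
  }
  generate_matrix(fixture_spec(
    S, N,
    tracks = do.call(rbind, rows),
    background_missing = 0.1, seed = seed + 1L
  ))
}
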