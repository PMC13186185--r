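#' Partition empirical sites into replicate-sized blocks
#'
#' Divides `N` empirical sites into `M` contiguous blocks so that each of the
#' `M` replicate sites can inherit one block's missingness statistics. Each
#' block holds `floor(N/M)` sites except the first `N %% M` blocks, which
#' hold `floor(N/M) + 1`. `M = N` is the degenerate identity partition
#' (every block one site); `M > N` is an error.
#'
#' @param N Empirical site count.
#' @param M Replicate site count (number of blocks).
#' @return A `block_partition`: list with `N`, `M` and integer `sizes`
#'   (length `M`, summing to `N`).
#' @examples
#' partition_blocks(10, 3)$sizes   # 4 3 3
#' min(partition_blocks(93166, 3327)$sizes)
#' @export
partition_blocks <- function(N, M) {
  N <- as.integer(N)
  M <- as.integer(M)
  if (is.na(N) || is.na(M) || N < 1L || M < 1L) {
    stop("N and M must be positive integers")
  }
  if (M > N) {
    stop("replicate has more sites (M=", M,
         ") than the empirical segment (N=", N, ")")
  }
  q <- N %/% M
  r <- N %% M
  structure(
    list(N = N, M = M, sizes = rep(c(q + 1L, q), times = c(r, M - r))),
    class = "block_partition"
  )
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> N=%d sites in M=%d blocks (sizes %d%s)\n",
              x$N, x$M, min(x$sizes),
              if (x$N %% x$M > 0L) paste0("-", max(x$sizes)) else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.block_partition <- function(x, ...) {
  end <- cumsum(x$sizes)
  tibble::tibble(
    block = seq_len(x$M),
    size = x$sizes,
    start = end - x$sizes + 1L,
    end = end
  )
}

#' Fit a per-sample, per-block missingness profile
#'
#' For each empirical sample `i` and block `j` of [partition_blocks()], the
#' profile entry `p[i, j]` is the proportion of that sample's genotypes
#' inside block `j` that are fully missing. Blocks are contiguous in genomic
#' order, so the profile compresses each sample's track structure of missing
#' genotypes down to `M` values.
#'
#' @param empirical A [geno_matrix] of `S` samples at `N` sites.
#' @param M Number of blocks = site count of the replicate to be masked.
#' @return A `missingness_profile`: list with `samples`, `partition` and the
#'   `S x M` matrix `p`.
#' @export
fit_profile <- function(empirical, M) {
  part <- partition_blocks(n_sites(empirical), M)
  block <- rep.int(seq_len(part$M), part$sizes)
  counts <- rowsum(missing_mask(empirical) + 0, block, reorder = FALSE)
  p <- t(counts / part$sizes)
  rownames(p) <- empirical$samples
  structure(
    list(samples = empirical$samples, partition = part, p = p),
    class = "missingness_profile"
  )
}

#' @export
print.missingness_profile <- function(x, ...) {
  cat(sprintf("<missingness_profile> %d samples x %d blocks (N=%d sites)\n",
              nrow(x$p), x$partition$M, x$partition$N))
  cat(sprintf("  mean p = %.3f\n", mean(x$p)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.missingness_profile <- function(x, ...) {
  tibble::tibble(
    sample = rep(x$samples, times = x$partition$M),
    block = rep(seq_len(x$partition$M), each = length(x$samples)),
    block_size = rep(x$partition$sizes, each = length(x$samples)),
    p = as.vector(x$p)
  )
}

#' @exportS3Method generics::glance
glance.missingness_profile <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$p),
    n_blocks = x$partition$M,
    n_sites = x$partition$N,
    min_block_size = min(x$partition$sizes),
    mean_p = mean(x$p)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.missingness_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$block, y = .data$sample,
                                  fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "block", y = "empirical sample",
                  fill = "missing\nproportion")
}

#' Replay a missingness profile onto a replicate
#'
#' For every replicate sample independently and every site `j`, one
#' empirical sample `s` is drawn uniformly from the profile's `S` samples and
#' the genotype is set fully missing (`./.`, unphased) with probability
#' `p[s, j]`. Called genotypes that are not masked are untouched; masking
#' never un-misses a genotype. The replicate's sample count is unrestricted.
#'
#' Randomness comes from R's global RNG; for each replicate sample in turn,
#' the `M` uniform empirical-sample draws are consumed first, then the
#' masking uniforms.
#'
#' @param replicate A [geno_matrix] whose site count equals the profile's
#'   block count `M`.
#' @param profile A `missingness_profile` from [fit_profile()].
#' @return The masked [geno_matrix].
#' @export
apply_profile <- function(replicate, profile) {
  M <- profile$partition$M
  if (n_sites(replicate) != M) {
    stop("replicate has ", n_sites(replicate),
         " sites but the profile has ", M, " blocks")
  }
  S <- nrow(profile$p)
  T_ <- n_samples(replicate)
  s <- matrix(sample.int(S, M * T_, replace = TRUE), M, T_)
  u <- matrix(runif(M * T_), M, T_)
  prob <- matrix(profile$p[cbind(as.vector(s), rep.int(seq_len(M), T_))],
                 M, T_)
  mask_genotypes(replicate, u < prob)
}

#' Beta-distribution missingness parameters
#'
#' `fit_beta()` computes the mean and (population) standard deviation of the
#' per-site missing-genotype proportion of `source` and converts them to
#' beta shape parameters by the method of moments:
#' `nu = mean(1-mean)/sd^2 - 1`, `alpha = mean * nu`, `beta = (1-mean) * nu`.
#' `beta_missingness()` builds the same object from a mean/sd supplied
#' directly.
#'
#' @param source A [geno_matrix] with at least two sites.
#' @return A `beta_missingness`: list with `mean`, `sd`, `alpha`, `beta`.
#' @examples
#' beta_missingness(0.5, 0.25)   # alpha = beta = 1.5
#' @export
fit_beta <- function(source) {
  if (n_sites(source) < 2L) stop("need at least two sites to fit")
  f <- site_missing_prop(source)
  beta_missingness(mean(f), sd_pop(f))
}

#' @rdname fit_beta
#' @param mean,sd Mean and standard deviation of per-site missingness, both
#'   interpreted as proportions.
#' @export
beta_missingness <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop("mean missingness must lie strictly between 0 and 1 (got ",
         format(mean), ")")
  }
  if (!is.finite(sd) || sd <= 0 || sd^2 >= mean * (1 - mean)) {
    stop("variance incompatible with a beta distribution: need 0 < sd^2 < ",
         "mean*(1-mean)")
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  structure(
    list(mean = mean, sd = sd, alpha = mean * nu, beta = (1 - mean) * nu),
    class = "beta_missingness"
  )
}

#' @export
print.beta_missingness <- function(x, ...) {
  cat(sprintf(
    "<beta_missingness> mean=%.4g sd=%.4g -> alpha=%.4g beta=%.4g\n",
    x$mean, x$sd, x$alpha, x$beta
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.beta_missingness <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = c(x$alpha, x$beta))
}

#' @exportS3Method generics::glance
glance.beta_missingness <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, alpha = x$alpha, beta = x$beta)
}

#' Mask a replicate with beta-distributed per-site missingness
#'
#' For each site independently a missing proportion
#' `q ~ Beta(alpha, beta)` is drawn, and each sample's genotype at that site
#' is set fully missing independently with probability `q` (per-sample
#' Bernoulli masking, so the expected per-site missingness equals `q`). The
#' `M` beta draws are consumed first, then the masking uniforms.
#'
#' @param replicate A [geno_matrix].
#' @param params A `beta_missingness`.
#' @return The masked [geno_matrix].
#' @export
apply_beta <- function(replicate, params) {
  stopifnot(inherits(params, "beta_missingness"))
  M <- n_sites(replicate)
  T_ <- n_samples(replicate)
  q <- rbeta(M, params$alpha, params$beta)
  u <- matrix(runif(M * T_), M, T_)
  mask_genotypes(replicate, u < q)
}

#' PLINK-style missingness summary
#'
#' Per-site and per-sample missing-genotype counts and proportions, plus the
#' mean and population standard deviation of the per-site proportions (the
#' two numbers that parameterize the beta baseline).
#'
#' @param x A non-empty [geno_matrix].
#' @return A `missingness_summary`: list with tibbles `per_site` (`chrom`,
#'   `pos`, `n_miss`, `f_miss`) and `per_sample` (`sample`, `n_miss`,
#'   `f_miss`), and scalars `mean`, `sd`.
#' @export
summarize_missingness <- function(x) {
  if (n_sites(x) < 1L || n_samples(x) < 1L) {
    stop("matrix must have at least one site and one sample")
  }
  m <- missing_mask(x)
  f_site <- rowMeans(m)
  structure(
    list(
      per_site = tibble::tibble(chrom = x$chrom, pos = x$pos,
                                n_miss = as.integer(rowSums(m)),
                                f_miss = f_site),
      per_sample = tibble::tibble(sample = x$samples,
                                  n_miss = as.integer(colSums(m)),
                                  f_miss = colMeans(m)),
      mean = mean(f_site),
      sd = sd_pop(f_site)
    ),
    class = "missingness_summary"
  )
}

#' @export
print.missingness_summary <- function(x, ...) {
  cat(sprintf(
    "<missingness_summary> %d sites, %d samples; per-site f_miss mean=%.4f sd=%.4f\n",
    nrow(x$per_site), nrow(x$per_sample), x$mean, x$sd
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.missingness_summary <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$per_site),
    n_samples = nrow(x$per_sample),
    mean_f_miss = x$mean,
    sd_f_miss = x$sd
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.missingness_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_site,
                  ggplot2::aes(x = .data$pos, y = .data$f_miss)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (bp)", y = "proportion of samples missing")
}

#' Write PLINK-like missingness reports
#'
#' Writes `<prefix>.vmiss` (CHROM, POS, N_MISS, F_MISS) and `<prefix>.smiss`
#' (SAMPLE, N_MISS, F_MISS) as tab-separated text.
#'
#' @param summary A `missingness_summary`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_missingness_report <- function(summary, prefix) {
  stopifnot(inherits(summary, "missingness_summary"))
  vmiss <- paste0(prefix, ".vmiss")
  smiss <- paste0(prefix, ".smiss")
  v <- summary$per_site
  names(v) <- c("CHROM", "POS", "N_MISS", "F_MISS")
  s <- summary$per_sample
  names(s) <- c("SAMPLE", "N_MISS", "F_MISS")
  readr::write_tsv(v, vmiss)
  readr::write_tsv(s, smiss)
  invisible(c(vmiss, smiss))
}
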