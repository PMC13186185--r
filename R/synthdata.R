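# Fixture generator: genotype matrices with controllable allele frequencies
# and engineered missingness structure. Stands in for empirical data (long
# contiguous tracks of missing genotypes, as seen over low-complexity
# regions) and for coalescent replicates in all tests.

#' Specify a synthetic genotype fixture
#'
#' @param S Sample count.
#' @param N Site count (positions are `1..N`).
#' @param maf_range Interval in `(0, 0.5]` from which each site's derived
#'   allele frequency is drawn uniformly.
#' @param tracks Data frame with columns `sample`, `start`, `end`: hard
#'   (probability-1) runs of missing genotypes laid over the matrix, the
#'   discrete analogue of low-mappability stretches.
#' @param background_missing Independent per-genotype missingness probability
#'   applied after the tracks.
#' @param seed Optional seed consumed at the start of generation.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(S, N, maf_range = c(0.05, 0.5), tracks = NULL,
                         background_missing = 0, seed = NULL) {
  stopifnot(S >= 1L, N >= 1L,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            background_missing >= 0, background_missing <= 1)
  if (is.null(tracks)) {
    tracks <- tibble::tibble(sample = integer(0), start = integer(0),
                             end = integer(0))
  }
  tracks <- tibble::as_tibble(tracks)
  stopifnot(all(c("sample", "start", "end") %in% names(tracks)))
  if (nrow(tracks)) {
    if (any(tracks$sample < 1L | tracks$sample > S)) {
      stop("track sample index outside 1..S")
    }
    if (any(tracks$start < 1L | tracks$end > N | tracks$start > tracks$end)) {
      stop("track interval outside 1..N")
    }
  }
  structure(
    list(S = as.integer(S), N = as.integer(N), maf_range = maf_range,
         tracks = tracks, background_missing = background_missing,
         seed = seed),
    class = "fixture_spec"
  )
}

#' Generate a genotype matrix from a fixture spec
#'
#' Sites are biallelic (`A`/`T`) at positions `1..N`, phased, with both
#' alleles of each genotype drawn independently as Bernoulli(f) where
#' `f ~ Uniform(maf_range)` per site. Missingness tracks are then applied
#' (both alleles set uncalled), followed by independent background
#' missingness.
#'
#' @param spec A [fixture_spec()].
#' @return A [geno_matrix].
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  N <- spec$N
  S <- spec$S
  f <- runif(N, spec$maf_range[1], spec$maf_range[2])
  left <- matrix(rbinom(N * S, 1L, f), N, S)
  right <- matrix(rbinom(N * S, 1L, f), N, S)
  x <- geno_matrix(
    chrom = "1", pos = seq_len(N),
    alleles = rep(list(c("A", "T")), N),
    left = left, right = right, phased = TRUE
  )
  mask <- matrix(FALSE, N, S)
  if (nrow(spec$tracks)) {
    for (t in seq_len(nrow(spec$tracks))) {
      mask[spec$tracks$start[t]:spec$tracks$end[t], spec$tracks$sample[t]] <- TRUE
    }
  }
  if (spec$background_missing > 0) {
    mask <- mask | matrix(runif(N * S) < spec$background_missing, N, S)
  }
  mask_genotypes(x, mask)
}

#' Generate ms-style text from a fixture spec
#'
#' Produces one replicate block parseable by [read_ms()]: `2 * S` haplotype
#' rows over `N` segregating sites at evenly spaced positions
#' `(i - 0.5) / N`. ms text cannot encode missing alleles, so the spec must
#' not request tracks or background missingness.
#'
#' @param spec A [fixture_spec()] without missingness.
#' @param path Optional path; when given the lines are written there.
#' @return The lines of ms-style text, invisibly when `path` is given.
#' @export
generate_ms_text <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$background_missing > 0 || nrow(spec$tracks) > 0L) {
    stop("ms text cannot encode missing data; use generate_matrix()")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  N <- spec$N
  S <- spec$S
  f <- runif(N, spec$maf_range[1], spec$maf_range[2])
  haps <- matrix(rbinom(N * 2L * S, 1L, f), N, 2L * S)
  lines <- c(
    "missweave ms-style fixture",
    "",
    "//",
    paste0("segsites: ", N),
    paste("positions:",
          paste(sprintf("%.8f", (seq_len(N) - 0.5) / N), collapse = " ")),
    apply(haps, 2L, paste, collapse = "")
  )
  if (is.null(path)) {
    return(lines)
  }
  writeLines(lines, path)
  invisible(lines)
}
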