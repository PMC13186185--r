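#' Diploid genotype matrix
#'
#' The in-memory container shared by every operation in the package: an
#' ordered set of sites (rows) genotyped in a set of diploid samples
#' (columns). Each genotype is a pair of site-local allele indices (`0` is
#' always REF) held in the `left` and `right` matrices, with `NA` marking an
#' uncalled allele. A *missing genotype* is one where **both** alleles are
#' `NA` (`./.` in VCF); a half-missing genotype (one allele called, e.g.
#' `0/.`) is representable and is never counted as missing.
#'
#' Sites are sorted by (chromosome, position) with strictly increasing
#' positions within a chromosome. Ploidy is fixed at two; multiallelic sites
#' are supported. Fully missing genotypes are normalised to unphased.
#'
#' @param chrom Chromosome name per site (recycled).
#' @param pos 1-based base-pair positions, one per site.
#' @param alleles List with one character vector per site (index 1 = REF /
#'   ancestral); a character vector of comma-separated allele strings is also
#'   accepted.
#' @param left,right Integer site-by-sample matrices of allele indices
#'   (0-based); `NA` = allele not called.
#' @param phased Logical site-by-sample matrix, or a single logical recycled
#'   to all genotypes.
#' @param samples Sample names; defaults to `sample1`, `sample2`, ...
#'
#' @return An object of class `geno_matrix`.
#' @examples
#' m <- geno_matrix(
#'   chrom = "1", pos = c(10, 20),
#'   alleles = list(c("A", "T"), c("C", "G")),
#'   left = matrix(c(0L, NA, 1L, NA), 2, 2),
#'   right = matrix(c(1L, NA, 1L, NA), 2, 2)
#' )
#' site_missing_prop(m)
#' @export
geno_matrix <- function(chrom, pos, alleles, left, right, phased = TRUE,
                        samples = NULL) {
  left <- as_allele_matrix(left)
  right <- as_allele_matrix(right)
  n <- nrow(left)
  s <- ncol(left)
  if (is.character(alleles)) alleles <- strsplit(alleles, ",", fixed = TRUE)
  alleles <- lapply(alleles, as.character)
  if (length(phased) == 1L) phased <- matrix(as.logical(phased), n, s)
  if (is.null(samples)) samples <- paste0("sample", seq_len(s))
  x <- structure(
    list(
      chrom = rep_len(as.character(chrom), n),
      pos = as.integer(pos),
      alleles = alleles,
      left = left, right = right,
      phased = phased,
      samples = as.character(samples)
    ),
    class = "geno_matrix"
  )
  # sort by (chrom in order of appearance, pos)
  ord <- order(match(x$chrom, unique(x$chrom)), x$pos)
  if (is.unsorted(ord, strictly = TRUE)) {
    x$chrom <- x$chrom[ord]
    x$pos <- x$pos[ord]
    x$alleles <- x$alleles[ord]
    x$left <- x$left[ord, , drop = FALSE]
    x$right <- x$right[ord, , drop = FALSE]
    x$phased <- x$phased[ord, , drop = FALSE]
  }
  # a fully missing genotype carries no phase
  miss <- is.na(x$left) & is.na(x$right)
  x$phased[miss] <- FALSE
  validate_geno_matrix(x)
}

as_allele_matrix <- function(m) {
  if (!is.matrix(m)) m <- matrix(m, ncol = 1L)
  storage.mode(m) <- "integer"
  m
}

validate_geno_matrix <- function(x) {
  n <- nrow(x$left)
  s <- ncol(x$left)
  stopifnot(
    length(x$chrom) == n, length(x$pos) == n, length(x$alleles) == n,
    identical(dim(x$right), dim(x$left)),
    identical(dim(x$phased), dim(x$left)),
    length(x$samples) == s
  )
  if (n > 0L) {
    if (anyNA(x$pos)) stop("site positions must be non-missing integers")
    d <- unlist(lapply(split(x$pos, match(x$chrom, unique(x$chrom))), diff),
                use.names = FALSE)
    if (length(d) && any(d <= 0L)) {
      stop("site positions must be strictly increasing within a chromosome")
    }
    nall <- lengths(x$alleles)
    if (any(nall < 1L) || any(!nzchar(unlist(x$alleles)))) {
      stop("every site needs at least one non-empty allele string")
    }
    rng <- suppressWarnings(range(c(x$left, x$right), na.rm = TRUE))
    if (is.finite(rng[1]) && rng[1] < 0L) stop("negative allele index")
    hi <- suppressWarnings(
      apply(cbind(x$left, x$right), 1L, max, na.rm = TRUE)
    )
    if (any(is.finite(hi) & hi >= nall)) {
      stop("allele index out of range for its site's allele list")
    }
  }
  x
}

#' Matrix dimensions and missingness helpers
#'
#' `n_sites()`/`n_samples()` return the dimensions; `missing_mask()` returns
#' the site-by-sample logical matrix that is `TRUE` where a genotype is fully
#' missing (both alleles uncalled); `site_missing_prop()` returns, per site,
#' the proportion of samples whose genotype is missing. Half-missing
#' genotypes never count as missing.
#'
#' @param x A [geno_matrix].
#' @return `n_sites()`/`n_samples()`: an integer. `missing_mask()`: a logical
#'   matrix. `site_missing_prop()`: a numeric vector in `[0, 1]`.
#' @export
n_sites <- function(x) length(x$pos)

#' @rdname n_sites
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname n_sites
#' @export
missing_mask <- function(x) is.na(x$left) & is.na(x$right)

#' @rdname n_sites
#' @export
site_missing_prop <- function(x) {
  if (n_samples(x) == 0L) stop("matrix has no samples")
  rowMeans(missing_mask(x))
}

biallelic_sites <- function(x) lengths(x$alleles) == 2L

# set the given genotypes fully missing ("./.", unphased)
mask_genotypes <- function(x, mask) {
  x$left[mask] <- NA_integer_
  x$right[mask] <- NA_integer_
  x$phased[mask] <- FALSE
  x
}

# site-by-sample matrix of VCF-style GT tokens ("0|1", "0/.", "./.")
gt_tokens <- function(x) {
  l <- ifelse(is.na(x$left), ".", as.character(x$left))
  r <- ifelse(is.na(x$right), ".", as.character(x$right))
  sep <- ifelse(x$phased, "|", "/")
  matrix(paste0(l, sep, r), nrow = n_sites(x),
         dimnames = list(NULL, x$samples))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d site%s x %d sample%s\n",
    n_sites(x), if (n_sites(x) == 1L) "" else "s",
    n_samples(x), if (n_samples(x) == 1L) "" else "s"
  ))
  if (n_sites(x) > 0L && n_samples(x) > 0L) {
    cat(sprintf("  chrom: %s\n", paste(unique(x$chrom), collapse = ", ")))
    cat(sprintf("  missing genotypes: %.1f%%\n", 100 * mean(missing_mask(x))))
    cat(sprintf("  multiallelic sites: %d\n", sum(lengths(x$alleles) > 2L)))
  }
  invisible(x)
}

#' Tidy a genotype matrix into long format
#'
#' One row per (site, sample) with the VCF-style genotype token.
#'
#' @param x A [geno_matrix].
#' @param ... Unused.
#' @return A tibble with columns `chrom`, `pos`, `sample`, `gt`, `phased`,
#'   `missing`.
#' @exportS3Method tibble::as_tibble
as_tibble.geno_matrix <- function(x, ...) {
  tok <- gt_tokens(x)
  tibble::tibble(
    chrom = rep(x$chrom, times = n_samples(x)),
    pos = rep(x$pos, times = n_samples(x)),
    sample = rep(x$samples, each = n_sites(x)),
    gt = as.vector(tok),
    phased = as.vector(x$phased),
    missing = as.vector(missing_mask(x))
  )
}
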