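# Hudson ms-style text: replicates delimited by "//", then "segsites: k",
# "positions: p1 ... pk" in [0,1), and one 0/1 (or 0..9 for multiallelic
# simulators) haplotype row per lineage.

#' Read ms-style replicates
#'
#' Parses Hudson-style coalescent simulator text. Any preamble before the
#' first `//` (command line, seeds) is ignored. Each `//` block yields one
#' replicate.
#'
#' @param path Path to an ms-style text file.
#' @return A list of `ms_replicate` objects, each with fields `segsites`
#'   (integer), `positions` (numeric in `[0,1)`), and `haplotypes` (character
#'   vector of per-lineage allele strings).
#' @export
read_ms <- function(path) {
  lines <- readLines(path)
  delim <- which(trimws(lines) == "//")
  if (length(delim) == 0L) stop("no '//' replicate delimiter found in ", path)
  bounds <- c(delim, length(lines) + 1L)
  lapply(seq_along(delim), function(b) {
    lo <- delim[b] + 1L
    hi <- bounds[b + 1L] - 1L
    chunk <- if (lo <= hi) lines[lo:hi] else character(0)
    chunk <- trimws(chunk)
    chunk <- chunk[nzchar(chunk)]
    if (length(chunk) == 0L || !startsWith(chunk[1], "segsites:")) {
      stop("replicate ", b, ": expected a 'segsites:' line after //")
    }
    k <- as.integer(trimws(sub("^segsites:", "", chunk[1])))
    if (is.na(k) || k < 0L) stop("replicate ", b, ": bad segsites count")
    if (k == 0L) {
      return(new_ms_replicate(0L, numeric(0), character(0)))
    }
    if (length(chunk) < 2L || !startsWith(chunk[2], "positions:")) {
      stop("replicate ", b, ": expected a 'positions:' line")
    }
    positions <- as.numeric(
      strsplit(trimws(sub("^positions:", "", chunk[2])), "\\s+")[[1]]
    )
    if (length(positions) != k) {
      stop("replicate ", b, ": ", length(positions),
           " positions for segsites ", k)
    }
    if (is.unsorted(positions)) {
      stop("replicate ", b, ": positions must be nondecreasing")
    }
    haps <- chunk[-(1:2)]
    if (length(haps) == 0L) stop("replicate ", b, ": no haplotype rows")
    if (any(nchar(haps) != k)) {
      stop("replicate ", b, ": haplotype length differs from segsites (",
           k, ")")
    }
    if (any(!grepl("^[0-9]+$", haps))) {
      stop("replicate ", b, ": haplotype rows must be digit strings")
    }
    new_ms_replicate(k, positions, haps)
  })
}

new_ms_replicate <- function(segsites, positions, haplotypes) {
  structure(
    list(segsites = segsites, positions = positions, haplotypes = haplotypes),
    class = "ms_replicate"
  )
}

#' @export
print.ms_replicate <- function(x, ...) {
  cat(sprintf("<ms_replicate> %d segsites, %d lineages\n",
              x$segsites, length(x$haplotypes)))
  invisible(x)
}

# allele letter for ms state k (0-based): ancestral "A", derived "T", then
# further states take successive unused letters
ms_allele_labels <- c("A", "T", "G", "C", setdiff(LETTERS, c("A", "T", "G", "C")))

#' Convert an ms replicate to a genotype matrix
#'
#' Positions in `[0,1)` are mapped to integer base pairs by
#' `max(1, round(p * segment_length_bp))`; collisions are resolved by bumping
#' subsequent positions up by 1 so ordering stays strict. With
#' `split_lineages = FALSE` consecutive lineage pairs (1,2), (3,4), ... form
#' phased diploid samples; with `split_lineages = TRUE` every lineage becomes
#' its own sample, homozygous for its allele. Ancestral state 0 is labelled
#' `A`, derived state 1 `T`, and any further states take successive letters.
#'
#' @param rep An `ms_replicate` from [read_ms()].
#' @param segment_length_bp Length in base pairs of the simulated segment.
#' @param split_lineages Treat each lineage as a separate (homozygous
#'   diploid) sample.
#' @param chrom Chromosome name to assign (ms carries none).
#' @return A [geno_matrix].
#' @export
ms_to_matrix <- function(rep, segment_length_bp, split_lineages = FALSE,
                         chrom = "1") {
  h <- length(rep$haplotypes)
  if (!split_lineages && h %% 2L != 0L) {
    stop("odd lineage count (", h, ") cannot form diploid samples; ",
         "use split_lineages = TRUE")
  }
  k <- rep$segsites
  bp <- pmax(1L, as.integer(round(rep$positions * segment_length_bp)))
  if (k > 1L) {
    for (i in 2:k) if (bp[i] <= bp[i - 1L]) bp[i] <- bp[i - 1L] + 1L
  }
  st <- matrix(0L, nrow = k, ncol = h)
  if (k > 0L) {
    st <- do.call(cbind, lapply(strsplit(rep$haplotypes, "", fixed = TRUE),
                                as.integer))
  }
  n_alleles <- if (k > 0L) {
    pmax(2L, apply(st, 1L, max) + 1L)
  } else {
    integer(0)
  }
  alleles <- lapply(n_alleles, function(na) ms_allele_labels[seq_len(na)])
  if (split_lineages) {
    geno_matrix(chrom, bp, alleles, left = st, right = st, phased = TRUE,
                samples = paste0("lin", seq_len(h)))
  } else {
    geno_matrix(chrom, bp, alleles,
                left = st[, seq(1L, h, by = 2L), drop = FALSE],
                right = st[, seq(2L, h, by = 2L), drop = FALSE],
                phased = TRUE,
                samples = paste0("dip", seq_len(h %/% 2L)))
  }
}

#' Write a genotype matrix as one ms-style replicate
#'
#' ms text cannot encode missing alleles, so the matrix must be fully called,
#' and only biallelic sites are representable. Each diploid sample emits two
#' haplotype rows (left allele row first); positions are
#' `pos / segment_length_bp`.
#'
#' @param x A fully called, biallelic [geno_matrix].
#' @param segment_length_bp Segment length used to rescale positions to
#'   `[0,1)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ms <- function(x, segment_length_bp, path) {
  if (anyNA(x$left) || anyNA(x$right)) {
    stop("ms output is incompatible with missing data")
  }
  if (any(!biallelic_sites(x))) {
    stop("ms output supports biallelic sites only")
  }
  n <- n_sites(x)
  haps <- character(2L * n_samples(x))
  for (j in seq_len(n_samples(x))) {
    haps[2L * j - 1L] <- paste(x$left[, j], collapse = "")
    haps[2L * j] <- paste(x$right[, j], collapse = "")
  }
  lines <- c(
    "missweave ms-style output",
    "",
    "//",
    paste0("segsites: ", n)
  )
  if (n > 0L) {
    lines <- c(
      lines,
      paste("positions:",
            paste(sprintf("%.8f", x$pos / segment_length_bp), collapse = " ")),
      haps
    )
  }
  writeLines(lines, path)
  invisible(path)
}
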