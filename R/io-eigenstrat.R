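# EIGENSTRAT / ANCESTRYMAP text triplet: .geno (one digit string per site
# over {0,1,2,9}, one character per sample, counting copies of the reference
# allele, 9 = missing), .snp (name chrom genetic-pos physical-pos ref alt),
# .ind (sample sex label). Packed binary ANCESTRYMAP is out of scope.

#' Read an EIGENSTRAT text triplet
#'
#' @param geno,snp,ind Paths to the `.geno`, `.snp` and `.ind` files.
#' @return An `eigenstrat_triplet`: a list with `geno` (character vector of
#'   per-site code strings), `snp` (tibble: `name`, `chrom`, `gpos`, `ppos`,
#'   `ref`, `alt`) and `ind` (tibble: `sample`, `sex`, `label`).
#' @export
read_eigenstrat <- function(geno, snp, ind) {
  geno_lines <- readLines(geno)
  snp_df <- read.table(snp, header = FALSE, stringsAsFactors = FALSE,
                       colClasses = c("character", "character", "numeric",
                                      "integer", "character", "character"))
  names(snp_df) <- c("name", "chrom", "gpos", "ppos", "ref", "alt")
  ind_df <- read.table(ind, header = FALSE, stringsAsFactors = FALSE,
                       colClasses = "character")
  names(ind_df) <- c("sample", "sex", "label")
  eigenstrat_triplet(geno_lines, tibble::as_tibble(snp_df),
                     tibble::as_tibble(ind_df))
}

#' Construct an EIGENSTRAT triplet from in-memory pieces
#'
#' @param geno Character vector of per-site genotype code strings over
#'   `{0,1,2,9}`.
#' @param snp Data frame with columns `name`, `chrom`, `gpos`, `ppos`, `ref`,
#'   `alt` (one row per site).
#' @param ind Data frame with columns `sample`, `sex`, `label` (one row per
#'   sample).
#' @return An `eigenstrat_triplet`.
#' @export
eigenstrat_triplet <- function(geno, snp, ind) {
  if (length(geno) != nrow(snp)) {
    stop("geno line count (", length(geno), ") differs from snp record count (",
         nrow(snp), ")")
  }
  if (any(nchar(geno) != nrow(ind))) {
    stop("every geno line must have one character per individual (",
         nrow(ind), ")")
  }
  structure(list(geno = geno, snp = tibble::as_tibble(snp),
                 ind = tibble::as_tibble(ind)),
            class = "eigenstrat_triplet")
}

#' Convert an EIGENSTRAT triplet to a genotype matrix
#'
#' Codes count copies of the reference allele: `2` becomes `0/0`, `1`
#' becomes `0/1`, `0` becomes `1/1` and `9` a missing genotype `./.`.
#' All output genotypes are biallelic and unphased, with REF/ALT taken from
#' the `.snp` records.
#'
#' @param triplet An `eigenstrat_triplet`.
#' @return A [geno_matrix].
#' @export
eigenstrat_to_matrix <- function(triplet) {
  codes <- do.call(rbind, strsplit(triplet$geno, "", fixed = TRUE))
  if (length(codes) == 0L) codes <- matrix(character(0), 0L, nrow(triplet$ind))
  bad <- !(codes %in% c("0", "1", "2", "9"))
  if (any(bad)) {
    ii <- which(bad)[1]
    stop("invalid geno character '", codes[ii], "' at site ",
         (ii - 1L) %% nrow(codes) + 1L)
  }
  # code -> (left, right) allele indices; 0 = REF
  left <- matrix(c(`2` = 0L, `1` = 0L, `0` = 1L, `9` = NA_integer_)[codes],
                 nrow = nrow(codes))
  right <- matrix(c(`2` = 0L, `1` = 1L, `0` = 1L, `9` = NA_integer_)[codes],
                  nrow = nrow(codes))
  geno_matrix(
    chrom = triplet$snp$chrom,
    pos = triplet$snp$ppos,
    alleles = lapply(seq_len(nrow(triplet$snp)),
                     function(i) c(triplet$snp$ref[i], triplet$snp$alt[i])),
    left = left, right = right, phased = FALSE,
    samples = triplet$ind$sample
  )
}
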