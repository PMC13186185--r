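#' Read a VCF file into a genotype matrix
#'
#' Parsing is delegated to [vcfR::read.vcfR()]; only the GT field is
#' interpreted. Multiallelic sites are preserved, `|`/`/` set the per-genotype
#' phase flag, and `./.` (or a bare `.`) becomes a fully missing genotype.
#' All records must carry GT in FORMAT.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return A [geno_matrix].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || !("FORMAT" %in% colnames(gt)) || ncol(gt) < 2L) {
    stop("VCF has no FORMAT/sample columns: ", path)
  }
  nrec <- nrow(fix)
  gt_idx <- vapply(strsplit(gt[, "FORMAT"], ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx)) {
    stop("record ", which(is.na(gt_idx))[1], " has no GT field in FORMAT")
  }
  tok <- gt[, -1L, drop = FALSE]
  if (all(gt_idx == 1L)) {
    gtv <- sub(":.*$", "", tok)
  } else {
    parts <- strsplit(as.vector(tok), ":", fixed = TRUE)
    gtv <- vapply(seq_along(parts), function(ii) {
      parts[[ii]][gt_idx[(ii - 1L) %% nrec + 1L]]
    }, character(1))
  }
  gtv[is.na(gtv)] <- "."
  re <- "^(\\.|[0-9]+)([/|])(\\.|[0-9]+)$"
  bare <- gtv == "."
  bad <- !bare & !grepl(re, gtv)
  if (any(bad)) {
    ii <- which(bad)[1]
    stop("malformed genotype '", gtv[ii], "' at record ",
         (ii - 1L) %% nrec + 1L)
  }
  lstr <- ifelse(bare, ".", sub(re, "\\1", gtv))
  rstr <- ifelse(bare, ".", sub(re, "\\3", gtv))
  sep <- ifelse(bare, "/", sub(re, "\\2", gtv))
  to_idx <- function(a) {
    matrix(suppressWarnings(as.integer(ifelse(a == ".", NA, a))), nrow = nrec)
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alleles <- lapply(seq_len(nrec), function(i) {
    if (is.na(alt[i]) || alt[i] == ".") ref[i]
    else c(ref[i], strsplit(alt[i], ",", fixed = TRUE)[[1]])
  })
  geno_matrix(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    alleles = alleles,
    left = to_idx(lstr),
    right = to_idx(rstr),
    phased = matrix(sep == "|", nrow = nrec),
    samples = colnames(gt)[-1L]
  )
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a minimal VCF v4.2 with a GT-only FORMAT, contig lines synthesised
#' from the observed chromosomes, phased genotypes separated by `|`, unphased
#' by `/`, and missing genotypes written `./.`. `read_vcf(write_vcf(m))`
#' reproduces `m`'s genotypes, phase flags, alleles and positions.
#'
#' @param x A [geno_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  ref <- vapply(x$alleles, `[`, character(1), 1L)
  alt <- vapply(x$alleles, function(a) {
    if (length(a) > 1L) paste(a[-1L], collapse = ",") else "."
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=missweave"),
    paste0("##contig=<ID=", unique(x$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  body <- character(0)
  if (n_sites(x) > 0L) {
    tok <- gt_tokens(x)
    body <- do.call(paste, c(
      list(x$chrom, x$pos, ".", ref, alt, ".", ".", ".", "GT"),
      lapply(seq_len(ncol(tok)), function(j) tok[, j]),
      list(sep = "\t")
    ))
  }
  writeLines(c(header, body), path)
  invisible(path)
}
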