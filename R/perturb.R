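# Genotype-degradation operators. All of them preserve site count, sample
# count, positions, and the set of fully missing genotypes; none creates or
# removes missingness. Per-operator RNG draw order is documented so runs are
# reproducible under a fixed seed.

#' Perturbation configuration
#'
#' Bundles the degradation options and validates their compatibility.
#' Deamination and sequencing error model the same kind of allele-level noise
#' for different data vintages and cannot be combined.
#'
#' @param unphase `"none"`, `"random"` (swap left/right with probability 1/2
#'   per genotype) or `"sort"` (smaller allele index first).
#' @param depolarize Per-site probability of swapping the ancestral/derived
#'   labelling at biallelic sites.
#' @param deam_transition Probability that a biallelic site is a transition
#'   (deamination model, first parameter).
#' @param deam_rate Probability that a called reference allele at a
#'   transition site deaminates to the alternative allele (second parameter).
#' @param seq_error Per-allele flip probability for sequencing error at
#'   biallelic sites.
#' @param pseudohaploid Collapse every genotype to a homozygote by random
#'   allele draw.
#' @return A `perturbation_config`.
#' @export
perturbation_config <- function(unphase = c("none", "random", "sort"),
                                depolarize = 0,
                                deam_transition = 0, deam_rate = 0,
                                seq_error = 0,
                                pseudohaploid = FALSE) {
  unphase <- match.arg(unphase)
  probs <- c(depolarize = depolarize, deam_transition = deam_transition,
             deam_rate = deam_rate, seq_error = seq_error)
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    bad <- names(probs)[which(!is.finite(probs) | probs < 0 | probs > 1)[1]]
    stop("probability '", bad, "' must lie in [0, 1]")
  }
  if ((deam_transition > 0 || deam_rate > 0) && seq_error > 0) {
    stop("deamination (--deaminate) and sequencing error (--seq-error) ",
         "cannot be combined")
  }
  structure(
    list(unphase = unphase, depolarize = depolarize,
         deam_transition = deam_transition, deam_rate = deam_rate,
         seq_error = seq_error, pseudohaploid = isTRUE(pseudohaploid)),
    class = "perturbation_config"
  )
}

#' Remove phase from all genotypes
#'
#' `mode = "random"` exchanges the left and right allele of each genotype
#' independently with probability 1/2 (one uniform per genotype, column-major
#' order). `mode = "sort"` puts the smaller allele index first; against a
#' missing allele the called allele sorts first, so sorting is deterministic
#' and idempotent. Either way every genotype is marked unphased (`/`).
#'
#' @param x A [geno_matrix].
#' @param mode `"random"` or `"sort"`.
#' @return The unphased [geno_matrix].
#' @export
unphase <- function(x, mode = c("random", "sort")) {
  mode <- match.arg(mode)
  l <- x$left
  r <- x$right
  if (mode == "random") {
    sw <- matrix(runif(length(l)) < 0.5, nrow(l))
    x$left <- ifelse(sw, r, l)
    x$right <- ifelse(sw, l, r)
  } else {
    lo <- pmin(l, r, na.rm = TRUE)
    hi <- pmax(l, r, na.rm = TRUE)
    hi[is.na(l) | is.na(r)] <- NA_integer_
    x$left <- lo
    x$right <- hi
  }
  x$phased[] <- FALSE
  x
}

#' Randomly remove polarization from biallelic sites
#'
#' Each biallelic site independently, with probability `prob`, has its
#' ancestral/derived labelling removed: the REF and ALT allele strings are
#' exchanged and every allele code at the site is flipped (0 <-> 1), so each
#' sample still carries the same bases. Multiallelic sites are untouched.
#' One uniform is drawn per biallelic site, in genomic order.
#'
#' @param x A [geno_matrix].
#' @param prob Per-site swap probability.
#' @return The [geno_matrix] with labels swapped at the chosen sites.
#' @export
depolarize <- function(x, prob) {
  bi <- which(biallelic_sites(x))
  sw <- bi[runif(length(bi)) < prob]
  if (length(sw)) {
    x$alleles[sw] <- lapply(x$alleles[sw], rev)
    x$left[sw, ] <- 1L - x$left[sw, , drop = FALSE]
    x$right[sw, ] <- 1L - x$right[sw, , drop = FALSE]
  }
  x
}

#' Simulate post-mortem deamination
#'
#' A two-parameter model of ancient-DNA damage: each biallelic site is
#' designated a transition once, with probability `transition_prob`; at
#' transition sites every *called reference* allele (code 0) independently
#' becomes the alternative allele (code 1) with probability `deam_rate`.
#' Missing alleles and non-transition sites are untouched. Draw order: one
#' uniform per biallelic site for the transition labels, then uniforms for
#' all left alleles at transition sites (column-major), then all right
#' alleles.
#'
#' @param x A [geno_matrix].
#' @param transition_prob Probability a biallelic site is a transition.
#' @param deam_rate Reference-to-alternative flip rate at transition sites.
#' @return The damaged [geno_matrix].
#' @export
deaminate <- function(x, transition_prob, deam_rate) {
  bi <- which(biallelic_sites(x))
  ts <- bi[runif(length(bi)) < transition_prob]
  if (length(ts)) {
    for (side in c("left", "right")) {
      a <- x[[side]][ts, , drop = FALSE]
      u <- matrix(runif(length(a)), nrow(a))
      flip <- !is.na(a) & a == 0L & u < deam_rate
      a[flip] <- 1L
      x[[side]][ts, ] <- a
    }
  }
  x
}

#' Pseudohaploidize all genotypes
#'
#' Mimics the random-allele genotype calls standard for low-coverage ancient
#' DNA: a heterozygote becomes homozygous for one of its two alleles with
#' equal probability; a half-missing genotype becomes homozygous for its
#' called allele; homozygotes and fully missing genotypes are unchanged.
#' Output genotypes are unphased. One uniform is drawn per genotype
#' (column-major), used only where the genotype is heterozygous.
#'
#' @param x A [geno_matrix].
#' @return The pseudohaploid [geno_matrix] (no heterozygotes remain).
#' @export
pseudohaploidize <- function(x) {
  l <- x$left
  r <- x$right
  take_left <- matrix(runif(length(l)) < 0.5, nrow(l))
  het <- !is.na(l) & !is.na(r) & l != r
  pick <- ifelse(take_left, l, r)
  x$left[het] <- pick[het]
  x$right[het] <- pick[het]
  only_right <- is.na(l) & !is.na(r)
  only_left <- !is.na(l) & is.na(r)
  x$left[only_right] <- r[only_right]
  x$right[only_left] <- l[only_left]
  x$phased[] <- FALSE
  x
}

#' Add sequencing error at biallelic sites
#'
#' Every called allele at a biallelic site flips state (0 <-> 1)
#' independently with probability `error_prob`. Missing alleles and
#' multiallelic sites are untouched. Draw order: uniforms for all left
#' alleles at biallelic sites (column-major), then all right alleles.
#'
#' @param x A [geno_matrix].
#' @param error_prob Per-allele flip probability.
#' @return The [geno_matrix] with errors introduced.
#' @export
add_sequencing_error <- function(x, error_prob) {
  bi <- which(biallelic_sites(x))
  if (length(bi)) {
    for (side in c("left", "right")) {
      a <- x[[side]][bi, , drop = FALSE]
      u <- matrix(runif(length(a)), nrow(a))
      flip <- !is.na(a) & u < error_prob
      a[flip] <- 1L - a[flip]
      x[[side]][bi, ] <- a
    }
  }
  x
}

#' Apply a perturbation configuration in canonical order
#'
#' Operators run in a fixed, documented order so results are reproducible:
#' depolarize, then deamination or sequencing error, then
#' pseudohaploidization, then unphasing. (Missingness masking, when
#' requested, is applied after all of these by [run_pipeline()].) An
#' operator runs only if its option is set.
#'
#' @param x A [geno_matrix].
#' @param config A [perturbation_config()].
#' @return The perturbed [geno_matrix].
#' @export
apply_perturbations <- function(x, config) {
  stopifnot(inherits(config, "perturbation_config"))
  if (config$depolarize > 0) x <- depolarize(x, config$depolarize)
  if (config$deam_transition > 0) {
    x <- deaminate(x, config$deam_transition, config$deam_rate)
  }
  if (config$seq_error > 0) x <- add_sequencing_error(x, config$seq_error)
  if (config$pseudohaploid) x <- pseudohaploidize(x)
  if (config$unphase != "none") x <- unphase(x, config$unphase)
  x
}
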