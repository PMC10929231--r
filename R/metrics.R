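#' Ambler-class composition of the beta-lactamase catalogue
#'
#' Number of genes per beta-lactamase family in the non-redundant catalogue
#' of 19,061 antibiotic-resistance determinants used as the reference
#' annotation: 627 class-A, 463 class-B1/B2, 463 class-B3, 181 class-C and
#' 89 class-D genes (1823 beta-lactamase genes in total).
#'
#' @return Named integer vector over the five Ambler families.
#' @export
ambler_class_counts <- function() {
  c(blaA = 627L, blaB1B2 = 463L, blaB3 = 463L, blaC = 181L, blaD = 89L)
}

#' Reference ARD catalogue as a one-copy-per-gene annotation table
#'
#' Expands the published catalogue composition (19,061 antibiotic-resistance
#' determinants, of which 1823 beta-lactamases split over the five Ambler
#' families) into a gene-level annotation table, one row per gene.
#'
#' @param total_ard Total catalogue size (default 19061).
#' @return Data frame with columns `gene_id` and `family` (`blaA`,
#'   `blaB1B2`, `blaB3`, `blaC`, `blaD` or `otherARD`).
#' @export
reference_ard_catalogue <- function(total_ard = 19061L) {
  bla <- ambler_class_counts()
  if (sum(bla) > total_ard) stop("total_ard smaller than the bla families")
  fam <- c(rep(names(bla), bla), rep("otherARD", total_ard - sum(bla)))
  data.frame(gene_id = sprintf("ard_%05d", seq_len(total_ard)),
             family = fam, stringsAsFactors = FALSE)
}

#' Metagenomic-species abundance from marker genes
#'
#' The abundance of a metagenomic species (MGS) in a sample is the mean
#' count of its marker genes. If fewer than `detection_fraction` (default
#' 10%) of the markers are seen (count strictly greater than 0), the MGS is
#' set to 0. The resulting profile is renormalised to sum to 1; an all-zero
#' profile stays all-zero.
#'
#' @param gene_counts Named numeric vector of gene counts for one sample.
#'   Marker genes absent from the vector count as 0.
#' @param marker_sets Named list: MGS id -> character vector of marker gene
#'   ids. No set may be empty.
#' @param detection_fraction Minimum fraction of detected markers.
#' @return Named numeric vector of relative MGS abundances (sums to 1
#'   unless all zero).
#' @examples
#' mgs_abundance(c(g1 = 3, g2 = 3, g3 = 1, g4 = 1),
#'               list(m1 = c("g1", "g2"), m2 = c("g3", "g4")))
#' @export
mgs_abundance <- function(gene_counts, marker_sets,
                          detection_fraction = 0.10) {
  if (length(marker_sets) == 0) stop("marker_sets must be nonempty")
  if (any(lengths(marker_sets) == 0))
    stop("every MGS must have a nonempty marker list")
  if (any(gene_counts < 0, na.rm = TRUE))
    stop("gene counts must be nonnegative")
  ab <- vapply(marker_sets, function(genes) {
    cnt <- gene_counts[genes]
    cnt[is.na(cnt)] <- 0
    if (mean(cnt > 0) < detection_fraction) 0 else mean(cnt)
  }, numeric(1))
  tot <- sum(ab)
  if (tot > 0) ab <- ab / tot
  ab
}

#' Rarefy a count vector without replacement
#'
#' Draws a multivariate-hypergeometric subsample of total size `depth` from
#' an integer count vector (random sampling without replacement), so
#' observed richness can be compared at equal sequencing effort.
#'
#' @param counts Nonnegative integer vector (names preserved).
#' @param depth Target total; must not exceed `sum(counts)`.
#' @param seed Integer seed; same seed gives an identical draw.
#' @return Integer vector of the same length as `counts`, summing to
#'   `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = 1) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  total <- sum(counts)
  if (depth > total)
    stop("rarefaction depth exceeds the sample total; sample excluded",
         call. = FALSE)
  set.seed(seed)
  urn <- rep(seq_along(counts), counts)
  drawn <- urn[sample.int(length(urn), depth)]
  out <- tabulate(drawn, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Observed richness of a profile
#'
#' Number of features with abundance strictly greater than 0 (unique
#' species, phage contigs, fungal OTUs or chemical species, depending on
#' the layer).
#'
#' @param abundances Numeric vector; `NA`s are ignored.
#' @return Integer count.
#' @export
observed_richness <- function(abundances) {
  sum(abundances > 0, na.rm = TRUE)
}

#' Relative abundance of the beta-lactamasome
#'
#' Proportion of gene copies mapping to any beta-lactamase family among all
#' copies mapping to an identified antibiotic-resistance determinant. The
#' operation is agnostic to the copy unit (raw copies or length-normalised
#' coverage).
#'
#' @param counts Numeric vector of per-gene copies.
#' @param family Character vector of the same length: ARD family per gene.
#' @param bla_families Families counted as beta-lactamases (default the
#'   five Ambler groups).
#' @return Proportion in \[0, 1\], or `NA` if the total ARD copy count is
#'   zero.
#' @export
betalactamasome_abundance <- function(counts, family,
                                      bla_families = names(ambler_class_counts())) {
  stopifnot(length(counts) == length(family))
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  total <- sum(counts, na.rm = TRUE)
  if (total == 0) {
    warning("zero ARD copies in total; beta-lactamasome abundance undefined")
    return(NA_real_)
  }
  sum(counts[family %in% bla_families], na.rm = TRUE) / total
}

#' Cholesterol conversion rate
#'
#' Ratio of the faecal coprostanol concentration to the sum of the faecal
#' coprostanol and cholesterol concentrations: the microbiota's capacity to
#' reduce cholesterol to coprostanol.
#'
#' @param coprostanol,cholesterol Nonnegative concentrations.
#' @return Ratio in \[0, 1\]; `NA` if both are zero.
#' @export
cholesterol_conversion_rate <- function(coprostanol, cholesterol) {
  if (any(c(coprostanol, cholesterol) < 0, na.rm = TRUE))
    stop("concentrations must be nonnegative")
  out <- coprostanol / (coprostanol + cholesterol)
  out[coprostanol + cholesterol == 0] <- NA_real_
  out
}

#' Bile-acid transformation capacity
#'
#' Ratio of the secondary bile acids (lithocholic and deoxycholic acid) to
#' the total faecal bile-acid concentration: the microbiota's capacity to
#' transform primary into secondary bile acids.
#'
#' @param lca,dca Secondary bile-acid concentrations (LCA, DCA).
#' @param total Total bile-acid concentration; must be at least `lca + dca`.
#' @return Ratio in \[0, 1\]; `NA` where `total` is zero.
#' @export
bile_acid_transformation <- function(lca, dca, total) {
  if (any(c(lca, dca) < 0, na.rm = TRUE))
    stop("concentrations must be nonnegative")
  if (any(lca + dca > total, na.rm = TRUE))
    stop("lca + dca exceeds the total bile-acid concentration")
  out <- (lca + dca) / total
  out[total == 0] <- NA_real_
  out
}

#' Fungal load
#'
#' Ratio of fungal DNA to total faecal DNA. Samples whose faecal DNA
#' concentration does not exceed `threshold` (default 50, in the
#' concentration unit of the assay) are excluded (`NA`).
#'
#' @param fungal_dna,faecal_dna Nonnegative DNA levels.
#' @param threshold Minimum faecal DNA concentration for a sample to be
#'   retained.
#' @return Ratio, or `NA` for excluded samples.
#' @export
fungal_load <- function(fungal_dna, faecal_dna, threshold = 50) {
  if (any(c(fungal_dna, faecal_dna) < 0, na.rm = TRUE))
    stop("DNA levels must be nonnegative")
  out <- fungal_dna / faecal_dna
  out[faecal_dna <= threshold] <- NA_real_
  out
}
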