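#' Genotype panel for a single region
#'
#' A `genotype_panel` holds the unit of analysis for region-based
#' rare-variant testing: a subjects-by-sites matrix of minor-allele counts
#' together with the base-pair position of every site.  Positions are
#' 1-based coordinates on a single chromosome/region and must be strictly
#' increasing in site order; counts are integers in \{0, 1, 2\}.  Missing
#' genotypes are not representable: subjects with missing calls are dropped
#' at load time (see [read_vcf()]).
#'
#' @param counts integer matrix, subjects in rows and sites in columns,
#'   entries in \{0, 1, 2\} (minor-allele dosage).
#' @param positions integer vector of per-site base-pair coordinates,
#'   strictly increasing, one per column of `counts`.
#' @param subject_ids,site_ids optional character identifiers; defaults are
#'   taken from `dimnames(counts)` or generated.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `counts`, `positions`, `subject_ids`, `site_ids`.
#' @seealso [read_vcf()], [read_genotype_matrix()], [maf_filter()]
#' @export
genotype_panel <- function(counts, positions, subject_ids = NULL,
                           site_ids = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("panel must have at least 1 subject and 1 site")
  if (anyNA(counts) || !all(counts %in% c(0L, 1L, 2L)))
    stop("genotype counts must all be in {0, 1, 2} with no missing values")
  storage.mode(counts) <- "integer"
  positions <- as.integer(positions)
  if (length(positions) != ncol(counts))
    stop("need exactly one position per site")
  if (anyNA(positions) || any(diff(positions) <= 0L))
    stop("positions must be strictly increasing in site order")
  if (is.null(subject_ids)) {
    subject_ids <- rownames(counts)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(site_ids)) {
    site_ids <- colnames(counts)
    if (is.null(site_ids)) site_ids <- paste0("site", seq_len(ncol(counts)))
  }
  subject_ids <- as.character(subject_ids)
  site_ids <- as.character(site_ids)
  if (length(subject_ids) != nrow(counts) || anyDuplicated(subject_ids))
    stop("subject_ids must be unique and match the number of subjects")
  if (length(site_ids) != ncol(counts) || anyDuplicated(site_ids))
    stop("site_ids must be unique and match the number of sites")
  dimnames(counts) <- list(subject_ids, site_ids)
  structure(
    list(counts = counts, positions = positions,
         subject_ids = subject_ids, site_ids = site_ids),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d subjects x %d sites, positions %d..%d bp\n",
              nrow(x$counts), ncol(x$counts),
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$counts)

# restrict a panel to a subset of sites (logical or integer index),
# preserving site order
subset_sites <- function(panel, keep) {
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  genotype_panel(panel$counts[, idx, drop = FALSE],
                 panel$positions[idx],
                 subject_ids = panel$subject_ids,
                 site_ids = panel$site_ids[idx])
}

#' Case/control phenotype vector
#'
#' Validates a binary phenotype aligned to a panel's subjects: 1 = case,
#' 0 = control.  At least one case and one control are required (the
#' permutation null is undefined otherwise).
#'
#' @param status numeric/integer vector of 0/1 labels; names, if present,
#'   are subject identifiers.
#' @param subject_ids optional identifiers; must match `names(status)` in
#'   length.
#' @return Named integer vector of class `phenotype_vector`.
#' @export
phenotype_vector <- function(status, subject_ids = NULL) {
  status <- as.integer(status)
  if (anyNA(status) || !all(status %in% c(0L, 1L)))
    stop("phenotype status must be binary 0/1 with no missing values")
  if (sum(status == 1L) < 1L || sum(status == 0L) < 1L)
    stop("need at least one case and one control")
  if (!is.null(subject_ids)) {
    if (length(subject_ids) != length(status))
      stop("subject_ids length must match status length")
    names(status) <- as.character(subject_ids)
  }
  class(status) <- "phenotype_vector"
  status
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("phenotype_vector: %d cases / %d controls\n",
              sum(unclass(x) == 1L), sum(unclass(x) == 0L)))
  invisible(x)
}

# check a phenotype against a panel and return it as a plain integer vector
align_phenotype <- function(panel, pheno) {
  status <- as.integer(unclass(pheno))
  if (length(status) != nrow(panel$counts))
    stop("phenotype length does not match the number of subjects in the panel")
  nm <- names(pheno)
  if (!is.null(nm) && !identical(nm, panel$subject_ids))
    stop("phenotype subject ids do not match the panel's subject order")
  status
}

#' Pooled minor-allele frequencies of a panel
#'
#' MAF per site over all subjects (cases and controls pooled), on the
#' allele scale: sum of minor-allele counts divided by 2n.
#'
#' @param panel a [genotype_panel()].
#' @return Numeric vector, one frequency per site.
#' @export
panel_maf <- function(panel) {
  colSums(panel$counts) / (2 * nrow(panel$counts))
}
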