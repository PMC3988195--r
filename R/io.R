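#' Read a genotype panel from a VCF file
#'
#' Loads biallelic SNV records from a VCF 4.x file into a
#' [genotype_panel()].  Genotypes are recoded as minor-allele dosages: the
#' minor allele at each site is the allele with frequency <= 0.5 in the
#' loaded sample (ties go to ALT).  Multi-allelic and non-SNV records are
#' skipped with a warning, as are subjects carrying any missing genotype in
#' the region (no imputation is attempted).  A single chromosome is
#' required; multi-chromosome input is an error.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param region optional numeric length-2 vector `c(start, end)`; only
#'   records with POS inside the closed interval are kept.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@gt) == 0L)
    stop("no records in VCF file: ", path)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))

  chrom <- fix[, "CHROM"]
  if (length(unique(chrom)) > 1L)
    stop("multi-chromosome VCF input is not supported; supply one region")
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    if (length(region) != 2L) stop("region must be c(start, end)")
    keep <- keep & pos >= region[1] & pos <= region[2]
  }
  biallelic_snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(keep & !biallelic_snv)
  if (n_skipped > 0L)
    warning(sprintf("skipped %d multi-allelic or non-SNV record(s)", n_skipped))
  keep <- keep & biallelic_snv
  if (!any(keep)) stop("no biallelic SNV records remain after filtering")

  gt <- vcf@gt[keep, -1L, drop = FALSE]
  pos <- pos[keep]
  site_ids <- ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                     paste0("site", pos), fix[keep, "ID"])

  # ALT-allele dosage from the GT field (first colon-separated entry)
  gt_only <- sub(":.*$", "", gt)
  dose <- matrix(NA_integer_, nrow = nrow(gt_only), ncol = ncol(gt_only))
  dose[gt_only %in% c("0/0", "0|0")] <- 0L
  dose[gt_only %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt_only %in% c("1/1", "1|1")] <- 2L
  dose <- t(dose)  # subjects x sites
  rownames(dose) <- colnames(gt)

  miss <- rowSums(is.na(dose)) > 0L
  if (any(miss))
    warning(sprintf("dropped %d subject(s) with missing genotypes", sum(miss)))
  dose <- dose[!miss, , drop = FALSE]
  if (nrow(dose) == 0L) stop("all subjects dropped due to missing genotypes")

  # minor-allele orientation from the loaded sample; tie -> ALT
  alt_freq <- colSums(dose) / (2 * nrow(dose))
  flip <- alt_freq > 0.5
  if (any(flip)) dose[, flip] <- 2L - dose[, flip, drop = FALSE]

  ord <- order(pos)
  if (anyDuplicated(pos)) stop("duplicate positions in VCF region")
  genotype_panel(dose[, ord, drop = FALSE], pos[ord],
                 site_ids = site_ids[ord])
}

#' Read genotype and phenotype tables
#'
#' Reads the plain-text exchange format: a TSV genotype matrix whose header
#' row gives per-site base-pair positions (columns `pos_<bp>` or bare
#' integers), rows are subjects (first column = subject id), and cells are
#' minor-allele counts in \{0, 1, 2\}; plus a two-column TSV phenotype table
#' (subject id, status 0/1).  Subjects present in only one of the files are
#' dropped with a warning; the result is aligned on the intersection.
#'
#' @param genotype_path,phenotype_path file paths.
#' @return A list with elements `panel` ([genotype_panel()]) and `pheno`
#'   ([phenotype_vector()]).
#' @export
read_genotype_matrix <- function(genotype_path, phenotype_path) {
  g <- utils::read.table(genotype_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(g) < 2L) stop("genotype table needs an id column and >= 1 site")
  ids <- as.character(g[[1L]])
  counts <- as.matrix(g[, -1L, drop = FALSE])
  pos <- suppressWarnings(as.integer(sub("^pos_", "", colnames(counts))))
  if (anyNA(pos)) stop("genotype header columns must be positions (pos_<bp>)")
  if (any(diff(pos) <= 0L)) stop("positions must be strictly increasing")
  bad <- which(!(counts %in% c(0L, 1L, 2L)) | is.na(counts))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(counts)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(counts)) + 1L
    stop(sprintf("genotype cell out of range at subject '%s', position %d: %s",
                 ids[i], pos[j], as.character(counts[i, j])))
  }

  p <- utils::read.table(phenotype_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(p) < 2L) stop("phenotype table needs id and status columns")
  pid <- as.character(p[[1L]])
  status <- p[[2L]]

  common <- intersect(ids, pid)
  if (length(common) == 0L)
    stop("no subjects shared between genotype and phenotype files")
  dropped <- (length(ids) - length(common)) + (length(pid) - length(common))
  if (dropped > 0L)
    warning(sprintf("dropped %d subject(s) present in only one file", dropped))

  counts <- counts[match(common, ids), , drop = FALSE]
  storage.mode(counts) <- "integer"
  panel <- genotype_panel(counts, pos, subject_ids = common,
                          site_ids = paste0("pos_", pos))
  pheno <- phenotype_vector(status[match(common, pid)], subject_ids = common)
  list(panel = panel, pheno = pheno)
}

#' Write a genotype panel (and optionally a phenotype) as TSV
#'
#' Inverse of [read_genotype_matrix()]: `write_genotype_matrix()` writes the
#' subjects-by-sites count matrix with `pos_<bp>` header columns, and
#' `write_phenotype()` writes the two-column id/status table.  A panel
#' round-trips bit-exactly through these functions.
#'
#' @param panel a [genotype_panel()].
#' @param pheno a [phenotype_vector()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_genotype_matrix <- function(panel, path) {
  df <- data.frame(subject = panel$subject_ids,
                   panel$counts, check.names = FALSE)
  colnames(df) <- c("subject", paste0("pos_", panel$positions))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
write_phenotype <- function(pheno, path) {
  df <- data.frame(subject = names(pheno), status = as.integer(unclass(pheno)))
  if (is.null(names(pheno))) df$subject <- paste0("S", seq_along(pheno))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype panel as a minimal VCF
#'
#' Emits a VCF 4.2 file with one biallelic SNV record per site (CHROM "1",
#' REF "A", ALT "C") and diploid GT genotypes encoding each subject's
#' minor-allele count (minor allele written as ALT).  A panel round-trips
#' through [read_vcf()] provided every site's minor-allele frequency is
#' at most 0.5, which holds by construction for minor-allele counts.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(panel, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$subject_ids), collapse = "\t")),
             con)
  for (j in seq_along(panel$positions)) {
    gts <- gt_code[panel$counts[, j] + 1L]
    writeLines(paste(c("1", panel$positions[j], panel$site_ids[j], "A", "C",
                       ".", "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Remove common and monomorphic sites
#'
#' Restricts a panel to rare sites before region testing: sites whose
#' minor-allele frequency in the combined sample of cases and controls
#' exceeds `max_maf` are removed, as are monomorphic sites (MAF 0), which
#' carry no association information.  Sites with MAF exactly `max_maf` are
#' retained.  Site order is preserved and the operation is idempotent.
#'
#' @param panel a [genotype_panel()].
#' @param pheno optional [phenotype_vector()]; used only to check alignment
#'   (the MAF is pooled over all subjects regardless of status).
#' @param max_maf retention threshold on the pooled MAF (default 0.05).
#' @return The filtered [genotype_panel()].
#' @export
maf_filter <- function(panel, pheno = NULL, max_maf = 0.05) {
  if (!is.null(pheno)) align_phenotype(panel, pheno)
  maf <- panel_maf(panel)
  keep <- maf > 0 & maf <= max_maf
  if (!any(keep))
    stop("no polymorphic sites with MAF <= ", max_maf, ": nothing to test")
  subset_sites(panel, keep)
}
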