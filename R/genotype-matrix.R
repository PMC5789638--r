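#' Diploid genotype matrix for one technology channel
#'
#' The central container of the package: biallelic autosomal genotype calls
#' for a set of individuals on one technology channel ("array" or "wgs").
#' Genotypes are stored as an integer matrix with one row per site and one
#' column per individual, coded 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing. Heterozygosity is genotype-level
#' (two different alleles); phase is ignored.
#'
#' @param geno Integer matrix, sites x individuals, values in {0, 1, 2, NA}.
#' @param sites Data frame with columns `chrom` (integer 1-22), `pos`
#'   (1-based bp), `id` (site identifier), `ref`, `alt` (single-character
#'   alleles, `ref != alt`).
#' @param individuals Character vector of individual IDs, one per column.
#' @param channel Either `"array"` or `"wgs"`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, individuals, channel = c("array", "wgs")) {
  channel <- match.arg(channel)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(sites)))
  sites$chrom <- as.integer(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$id <- as.character(sites$id)
  if (nrow(sites) != nrow(geno))
    stop("sites (", nrow(sites), ") and genotype rows (", nrow(geno), ") differ")
  if (length(individuals) != ncol(geno))
    stop("individuals (", length(individuals), ") and genotype columns (",
         ncol(geno), ") differ")
  if (anyDuplicated(individuals))
    stop("duplicate individual IDs")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (nrow(sites)) {
    if (any(is.na(sites$chrom)) || any(sites$chrom < 1L) || any(sites$chrom > 22L))
      stop("chromosomes must be autosomes 1-22")
    if (any(sites$pos < 1L)) stop("positions must be >= 1")
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
    o <- order(sites$chrom, sites$pos)
    if (!identical(o, seq_len(nrow(sites)))) {
      sites <- sites[o, , drop = FALSE]
      geno <- geno[o, , drop = FALSE]
    }
    if (anyDuplicated(sites[c("chrom", "pos")]))
      stop("duplicate (chromosome, position) pairs")
  }
  rownames(geno) <- NULL
  colnames(geno) <- individuals
  rownames(sites) <- NULL
  structure(list(geno = geno, sites = sites,
                 individuals = as.character(individuals), channel = channel),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix [", x$channel, "]: ", nrow(x$sites), " sites x ",
      length(x$individuals), " individuals\n", sep = "")
  if (nrow(x$sites)) {
    cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
    nhet <- sum(x$geno == 1L, na.rm = TRUE)
    cat("  het calls:", nhet, " missing:", sum(is.na(x$geno)), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$individuals))

#' Subset a genotype matrix by site index
#'
#' @param gm A [genotype_matrix()].
#' @param keep Integer or logical index over sites (rows).
#' @return A `genotype_matrix` restricted to the selected sites.
#' @export
subset_sites <- function(gm, keep) {
  genotype_matrix(gm$geno[keep, , drop = FALSE],
                  gm$sites[keep, , drop = FALSE],
                  gm$individuals, gm$channel)
}

# shared GT-string -> {0,1,2,NA} mapping; anything half-missing is missing
.map_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[gt == "0/0"] <- 0L
  out[gt == "0/1" | gt == "1/0"] <- 1L
  out[gt == "1/1"] <- 2L
  out
}

.norm_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  suppressWarnings(as.integer(chrom))
}

#' Read a VCF file into a genotype matrix
#'
#' Reads a VCF 4.x file (only the GT subfield is consulted), retaining
#' biallelic SNP records on autosomes 1-22. Contig labels with a leading
#' "chr" prefix are normalised by stripping it. Multi-allelic records,
#' non-SNP records and records on other contigs are skipped with a logged
#' count. Phased and unphased genotypes are treated identically; half-missing
#' genotypes become missing.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param channel Channel tag for the resulting matrix.
#' @param verbose Emit a message with the number of skipped records.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, channel = c("array", "wgs"), verbose = TRUE) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0L) stop("VCF contains no records: ", path)
  chrom <- .norm_chrom(fix$CHROM)
  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  autosome <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  keep <- snp & autosome
  n_skip_contig <- sum(!autosome)
  n_skip_snp <- sum(autosome & !snp)
  if (verbose && (n_skip_contig || n_skip_snp))
    message("read_vcf: skipped ", n_skip_contig, " record(s) on non-autosomal ",
            "contigs and ", n_skip_snp, " non-biallelic-SNP record(s)")
  if (!any(keep)) stop("no biallelic autosomal SNP records retained from ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  geno <- matrix(.map_gt(gt), nrow = nrow(gt), ncol = ncol(gt))
  id <- fix$ID[keep]
  id[is.na(id) | id == "."] <- paste0(chrom[keep], ":", fix$POS[keep])[is.na(id) | id == "."]
  sites <- data.frame(chrom = chrom[keep],
                      pos = as.integer(fix$POS[keep]),
                      id = id, ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  genotype_matrix(geno, sites, colnames(gt), channel)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits one biallelic SNP record per site with a GT-only FORMAT field
#' (`0/0`, `0/1`, `1/1`, `./.`). Writing then reading reproduces the matrix
#' exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  s <- gm$sites
  header <- c("##fileformat=VCFv4.2",
              paste0("##source=rohcompare_", as.character(utils::packageVersion("rohcompare"))),
              paste0("##channel=", gm$channel),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$individuals), collapse = "\t"))
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(gm$geno), ncol = ncol(gm$geno))
  ok <- !is.na(gm$geno)
  gt[ok] <- code[gm$geno[ok] + 1L]
  body <- paste(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  if (nrow(s) == 0L) body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read PLINK text PED/MAP files into a genotype matrix
#'
#' Allele pairs are mapped to the four-state genotype code; `0 0` (and any
#' half-missing pair) is missing. The reference allele per site is taken from
#' `ref_alleles` when supplied, otherwise the major allele among observed
#' calls is used (alphabetic tie-break), so `A A` at a site where A is the
#' only/major allele codes as homozygous reference.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param channel Channel tag.
#' @param ref_alleles Optional character vector of reference alleles, one per
#'   MAP row.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path, channel = c("array", "wgs"),
                         ref_alleles = NULL) {
  channel <- match.arg(channel)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stop("MAP file must have 4 columns")
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  n_sites <- nrow(map)
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  expected <- 6L + 2L * n_sites
  if (ncol(ped) != expected)
    stop("PED has ", ncol(ped), " columns but MAP implies ", expected,
         " (6 + 2 x ", n_sites, ")")
  iid <- ped[[2L]]
  a1 <- t(as.matrix(ped[, 6L + 2L * seq_len(n_sites) - 1L, drop = FALSE]))
  a2 <- t(as.matrix(ped[, 6L + 2L * seq_len(n_sites), drop = FALSE]))
  miss <- a1 == "0" | a2 == "0"
  a1[miss] <- NA; a2[miss] <- NA
  geno <- matrix(NA_integer_, nrow = n_sites, ncol = nrow(ped))
  ref <- character(n_sites); alt <- character(n_sites)
  for (j in seq_len(n_sites)) {
    alleles <- c(a1[j, ], a2[j, ])
    tab <- sort(table(alleles[!is.na(alleles)]), decreasing = TRUE)
    obs <- names(tab)
    if (length(obs) > 2L)
      stop("site ", map$id[j], " has more than two alleles: ",
           paste(obs, collapse = ","))
    if (!is.null(ref_alleles)) {
      ref[j] <- ref_alleles[j]
      alt[j] <- setdiff(obs, ref[j])[1L]
    } else {
      # major allele as reference; alphabetic tie-break for determinism
      if (length(obs) >= 2L && tab[[1L]] == tab[[2L]]) obs <- sort(obs)
      ref[j] <- if (length(obs)) obs[1L] else "A"
      alt[j] <- if (length(obs) >= 2L) obs[2L] else NA_character_
    }
    if (is.na(alt[j]) || !length(alt[j]))
      alt[j] <- setdiff(c("A", "C", "G", "T"), ref[j])[1L]
    het <- !is.na(a1[j, ]) & a1[j, ] != a2[j, ]
    geno[j, het] <- 1L
    hom <- !is.na(a1[j, ]) & a1[j, ] == a2[j, ]
    geno[j, hom & a1[j, ] == ref[j]] <- 0L
    geno[j, hom & a1[j, ] == alt[j]] <- 2L
  }
  sites <- data.frame(chrom = .norm_chrom(map$chrom), pos = as.integer(map$pos),
                      id = as.character(map$id), ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  genotype_matrix(geno, sites, iid, channel)
}
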