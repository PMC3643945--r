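#' Read a LINKAGE pre-makeped pedigree file
#'
#' Whitespace-delimited columns: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female), affection (0 = unknown,
#' 1 = unaffected, 2 = affected); `0` denotes an absent parent.  Any further
#' columns are interpreted as paired marker alleles in 1/2 coding
#' (`0 0` = missing) and returned as a risk-allele dosage matrix in the
#' `"genotypes"` attribute (rows named by id, allele `2` counted).
#'
#' @param path file path.
#' @param flags_path optional sidecar flags file (see [write_flags()]); when
#'   absent, genotyped/phenotyped flags default from `affection != 0`.
#' @return A validated [pedigree()].
#' @export
read_pedfile <- function(path, flags_path = NULL) {
  tab <- read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 6)
    ped_stop("bad_pedfile", "ped file must have at least 6 columns")
  flags <- if (!is.null(flags_path)) read_flags(flags_path) else NULL
  gt <- NULL
  if (ncol(tab) > 6) {
    extra <- ncol(tab) - 6L
    if (extra %% 2L != 0L)
      ped_stop("bad_pedfile", "marker allele columns must come in pairs")
    al <- as.matrix(tab[, -(1:6), drop = FALSE])
    mode(al) <- "integer"
    a1 <- al[, seq(1, extra, by = 2), drop = FALSE]
    a2 <- al[, seq(2, extra, by = 2), drop = FALSE]
    gt <- (a1 == 2L) + (a2 == 2L)
    gt[a1 == 0L | a2 == 0L] <- NA_integer_
    rownames(gt) <- tab[[2]]
  }
  geno <- pheno <- NULL
  if (!is.null(flags)) {
    i <- match(tab[[2]], flags$id)
    if (anyNA(i))
      ped_stop("flag_mismatch", "flags file missing id(s): %s",
               paste(tab[[2]][is.na(i)], collapse = ", "))
    geno <- flags$genotyped[i]
    pheno <- flags$phenotyped[i]
  }
  ped <- pedigree(id = tab[[2]], father = tab[[3]], mother = tab[[4]],
                  sex = tab[[5]], affection = tab[[6]],
                  genotyped = geno, phenotyped = pheno)
  if (!is.null(gt)) attr(ped, "genotypes") <- gt[ped$id, , drop = FALSE]
  ped
}

#' Write a LINKAGE pre-makeped pedigree file
#'
#' One row per member, sorted by id; optional marker genotypes appended as
#' paired allele columns (dosage 0 -> `1 1`, 1 -> `1 2`, 2 -> `2 2`,
#' `NA` -> `0 0`).
#'
#' @param ped a [pedigree()].
#' @param path output file path.
#' @param genotypes optional members x loci dosage matrix with rownames
#'   covering all pedigree ids (e.g. a replicate's genotype matrix).
#' @param family family id written in column 1.
#' @export
write_pedfile <- function(ped, path, genotypes = NULL, family = "FAM1") {
  out <- data.frame(family, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    ped$sex, ped$affection, stringsAsFactors = FALSE)
  if (!is.null(genotypes)) {
    if (is.null(rownames(genotypes)) || !all(ped$id %in% rownames(genotypes)))
      ped_stop("genotype_mismatch", "genotype matrix must be row-named by id and cover all members")
    g <- genotypes[ped$id, , drop = FALSE]
    L <- ncol(g)
    a1 <- ifelse(is.na(g), 0L, ifelse(g >= 2L, 2L, 1L))
    a2 <- ifelse(is.na(g), 0L, ifelse(g >= 1L, 2L, 1L))
    al <- matrix(0L, nrow(g), 2L * L)
    al[, seq(1, 2 * L, by = 2)] <- a1
    al[, seq(2, 2 * L, by = 2)] <- a2
    out <- cbind(out, as.data.frame(al))
  }
  write.table(out, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Write / read the sampling-flags sidecar file
#'
#' The pre-makeped format has no genotyped/phenotyped field, so the flags
#' live in a two-column sidecar: id, flag token (`gp` = genotyped and
#' phenotyped, `g` = genotyped only, `p` = phenotyped only, `-` = neither).
#'
#' @param ped a [pedigree()].
#' @param path file path.
#' @export
write_flags <- function(ped, path) {
  tok <- ifelse(ped$genotyped & ped$phenotyped, "gp",
         ifelse(ped$genotyped, "g", ifelse(ped$phenotyped, "p", "-")))
  write.table(data.frame(ped$id, tok), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' @rdname write_flags
#' @export
read_flags <- function(path) {
  tab <- read.table(path, header = FALSE, colClasses = "character")
  data.frame(id = tab[[1]],
             genotyped = tab[[2]] %in% c("g", "gp"),
             phenotyped = tab[[2]] %in% c("p", "gp"),
             stringsAsFactors = FALSE)
}

#' Write Merlin-style map and dat files
#'
#' @param map a [marker_map()].
#' @param path output file path.
#' @export
write_mapfile <- function(map, path) {
  out <- data.frame(map$chromosome, map$name, format(map$position_cM))
  cat("CHROMOSOME MARKER POSITION\n", file = path)
  write.table(out, path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  invisible(NULL)
}

#' @rdname write_mapfile
#' @export
write_datfile <- function(map, path) {
  writeLines(c("A disease", paste("M", map$name)), path)
  invisible(NULL)
}
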