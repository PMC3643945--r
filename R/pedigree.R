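#' @useDynLib pedpower, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pchisq rbinom rnbinom runif uniroot optimize setNames sd var quantile
#' @importFrom utils read.table write.table
NULL

# distinct, identifiable condition classes for structural errors
ped_stop <- function(class, msg, ...) {
  stop(structure(class = c(paste0("pedpower_", class), "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Construct a pedigree
#'
#' A pedigree is a collection of individuals with parent links, sex,
#' affection status and genotyped/phenotyped sampling flags.  Founders have
#' both parents absent (`NA`); every non-founder has both parents present in
#' the pedigree.  The object is a `data.frame` (rows sorted lexicographically
#' by `id`) of class `"pedigree"` carrying a `generation` attribute
#' (founders 0, otherwise 1 + max parent generation).
#'
#' @param id character vector of unique member ids.
#' @param father,mother character vectors of parent ids; `NA` (or `"0"`) for
#'   founders.  Both must be present or both absent for each member.
#' @param sex integer, 1 = male, 2 = female.
#' @param affection integer, 0 = unknown, 1 = unaffected, 2 = affected.
#' @param genotyped,phenotyped logical sampling flags.  Defaults: `phenotyped`
#'   is `affection != 0` (the two are required to agree); `genotyped` defaults
#'   to `phenotyped`.
#' @return An object of class `"pedigree"`.
#' @export
pedigree <- function(id, father, mother, sex, affection,
                     genotyped = NULL, phenotyped = NULL) {
  id <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  father[father %in% "0"] <- NA_character_
  mother[mother %in% "0"] <- NA_character_
  sex <- as.integer(sex)
  affection <- as.integer(affection)
  if (is.null(phenotyped)) phenotyped <- affection != 0L
  if (is.null(genotyped)) genotyped <- phenotyped
  df <- data.frame(id = id, father = father, mother = mother, sex = sex,
                   affection = affection, genotyped = as.logical(genotyped),
                   phenotyped = as.logical(phenotyped),
                   stringsAsFactors = FALSE)
  validate_pedigree(df)
}

validate_pedigree <- function(df) {
  if (anyDuplicated(df$id))
    ped_stop("duplicate_id", "duplicated id(s): %s",
             paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  single <- xor(is.na(df$father), is.na(df$mother))
  if (any(single))
    ped_stop("single_parent", "single-parent record for id(s): %s",
             paste(df$id[single], collapse = ", "))
  for (col in c("father", "mother")) {
    ref <- df[[col]]
    bad <- !is.na(ref) & !(ref %in% df$id)
    if (any(bad))
      ped_stop("parent_not_found", "%s id not found for id(s): %s",
               col, paste(df$id[bad], collapse = ", "))
  }
  if (!all(df$sex %in% c(1L, 2L)))
    ped_stop("bad_sex", "sex must be 1 (male) or 2 (female)")
  if (!all(df$affection %in% c(0L, 1L, 2L)))
    ped_stop("bad_affection", "affection must be 0/1/2")
  if (any(df$phenotyped != (df$affection != 0L)))
    ped_stop("flag_mismatch",
             "phenotyped flag must agree with affection != unknown")
  fi <- match(df$father, df$id)
  mi <- match(df$mother, df$id)
  badf <- !is.na(fi) & df$sex[fi] != 1L
  badm <- !is.na(mi) & df$sex[mi] != 2L
  if (any(badf | badm))
    ped_stop("parent_sex", "sex-inconsistent parent for id(s): %s",
             paste(df$id[badf | badm], collapse = ", "))
  # generations; failure to make progress means a directed ancestry cycle
  n <- nrow(df)
  gen <- ifelse(is.na(fi), 0L, NA_integer_)
  while (anyNA(gen)) {
    todo <- which(is.na(gen))
    ready <- todo[!is.na(gen[fi[todo]]) & !is.na(gen[mi[todo]])]
    if (!length(ready))
      ped_stop("cyclic_ancestry", "cyclic ancestry involving id(s): %s",
               paste(df$id[todo], collapse = ", "))
    gen[ready] <- pmax(gen[fi[ready]], gen[mi[ready]]) + 1L
  }
  ord <- order(df$id, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "generation") <- gen[ord]
  class(df) <- c("pedigree", "data.frame")
  df
}

#' @export
print.pedigree <- function(x, ...) {
  fo <- is.na(x$father)
  cat(sprintf(paste0("Pedigree: %d members (%d founders, %d non-founders), ",
                     "%d generations, bit size %d\n"),
              nrow(x), sum(fo), sum(!fo), max(attr(x, "generation")) + 1L,
              bit_size(x)))
  cat(sprintf("  genotyped: %d, phenotyped: %d, affected: %d\n",
              sum(x$genotyped), sum(x$phenotyped), sum(x$affection == 2L)))
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  gen <- attr(object, "generation")
  data.frame(generation = sort(unique(gen)),
             members = as.vector(table(gen)),
             genotyped = as.vector(tapply(object$genotyped, gen, sum)),
             affected = as.vector(tapply(object$affection == 2L, gen, sum)))
}

founder_mask <- function(ped) is.na(ped$father)

#' Pedigree bit size
#'
#' The complexity measure governing exact linkage algorithms:
#' `2 * (number of non-founders) - (number of founders)`.
#'
#' @param ped a [pedigree()].
#' @return integer bit size.
#' @export
bit_size <- function(ped) {
  fo <- founder_mask(ped)
  2L * sum(!fo) - sum(fo)
}

# topological (generation, id) order and 1-based parent indices in that order
ped_topology <- function(ped) {
  gen <- attr(ped, "generation")
  ord <- order(gen, ped$id, method = "radix")
  ids <- ped$id[ord]
  fa <- match(ped$father[ord], ids)
  mo <- match(ped$mother[ord], ids)
  fa[is.na(fa)] <- 0L
  mo[is.na(mo)] <- 0L
  list(order = ord, ids = ids, father = fa, mother = mo)
}
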