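#' Kinship-corrected quasi-likelihood score association test
#'
#' A 1-df case-control score statistic for arbitrary (including inbred and
#' looped) pedigrees, in the MQLS family: genotype scores
#' `Y_i = (risk-allele count)/2` are tested against a phenotype-based
#' contrast built from affected (`A_i = 1`), unaffected
#' (`A_i = -k/(1-k)` for assumed prevalence `k`) and unknown (`A_i = 0`)
#' individuals, with phenotypes of phenotyped-but-ungenotyped relatives
#' folded onto their genotyped kin through the kinship matrix:
#' \deqn{\tilde A = A_N + K_{NM} K_{MM}^{-1} A_M}
#' \deqn{\hat\mu = \frac{1^T K_{NN}^{-1} Y}{1^T K_{NN}^{-1} 1},\qquad
#'       \hat\sigma^2 = \hat\mu(1-\hat\mu)/2}
#' \deqn{W = \frac{[\tilde A^T (Y - \hat\mu 1)]^2}
#'       {\hat\sigma^2\,[\tilde A^T K_{NN} \tilde A -
#'        (\tilde A^T 1)^2 / (1^T K_{NN}^{-1} 1)]}}
#' where `K` is the covariance-scale kinship matrix (`K_ij = 2 phi_ij`,
#' `K_ii = 1 + h_i`) and `N`/`M` index genotyped and
#' phenotyped-but-ungenotyped members.  Under the gene-dropping null the
#' denominator is the exact variance of the numerator given the phenotypes,
#' so `W` is asymptotically chi-squared with 1 df, and `W` is invariant to
#' which allele is labelled "risk".
#'
#' [mqls_structure()] does the phenotype-independent work (kinship blocks
#' and factorizations) once per pedigree structure; [mqls_prepare()] adds
#' the phenotype contrast; [mqls_statistic()] then evaluates one locus in
#' O(n).
#'
#' @param km a [kinship()] matrix covering all genotyped and phenotyped
#'   members being analysed (e.g. [subpedigree_kinship_union()] for split
#'   analyses).
#' @param genotyped character vector: ids of the genotyped set `N`.
#' @return `mqls_structure()`: an object of class `"mqls_structure"`.
#' @export
mqls_structure <- function(km, genotyped) {
  ids <- km$ids
  N <- ids[ids %in% genotyped]
  if (!length(N)) ped_stop("member_mismatch", "no genotyped members in kinship")
  K <- kinship_K(km)
  K_NN <- K[N, N, drop = FALSE]
  ch <- tryCatch(chol(K_NN), error = function(e) NULL)
  if (is.null(ch)) # tiny diagonal jitter; failure after jitter is an error
    ch <- chol(K_NN + diag(1e-10, nrow(K_NN)))
  one <- rep(1, length(N))
  Kinv1 <- backsolve(ch, forwardsolve(t(ch), one))
  structure(list(ids = ids, N = N, K = K, K_NN = K_NN, chol_NN = ch,
                 Kinv1 = Kinv1, s11 = sum(Kinv1)),
            class = "mqls_structure")
}

#' @rdname mqls_structure
#' @param affection named integer affection vector (0/1/2) over at least
#'   the members of `km`; missing names are treated as unknown.
#' @param prevalence assumed population prevalence `k` in (0, 1).
#' @param struct optional precomputed [mqls_structure()] to reuse across
#'   replicates sharing the pedigree structure.
#' @return `mqls_prepare()`: an object of class `"mqls_prep"`.
#' @export
mqls_prepare <- function(km, genotyped, affection, prevalence = 106 / 798,
                         struct = NULL) {
  stopifnot(prevalence > 0, prevalence < 1)
  if (is.null(struct)) struct <- mqls_structure(km, genotyped)
  ids <- struct$ids
  aff <- affection[ids]
  aff[is.na(aff)] <- 0L
  N <- struct$N
  M <- ids[!(ids %in% N) & aff != 0L]
  A <- ifelse(aff == 2L, 1, ifelse(aff == 1L, -prevalence / (1 - prevalence), 0))
  names(A) <- ids
  Atil <- A[N]
  if (length(M)) {
    K <- struct$K
    chm <- tryCatch(chol(K[M, M, drop = FALSE]), error = function(e) NULL)
    if (is.null(chm)) {
      warning("singular ungenotyped-relative kinship block; dropping members until it factorizes")
      while (length(M) && is.null(chm)) {
        M <- M[-length(M)]
        chm <- if (!length(M)) NULL else
          tryCatch(chol(K[M, M, drop = FALSE]), error = function(e) NULL)
      }
    }
    if (length(M))
      Atil <- Atil + drop(K[N, M, drop = FALSE] %*%
                            backsolve(chm, forwardsolve(t(chm), A[M])))
  }
  structure(list(N = N, M = M, Atilde = Atil, Kinv1 = struct$Kinv1,
                 s11 = struct$s11, At1 = sum(Atil),
                 denom_struct = drop(crossprod(Atil, struct$K_NN %*% Atil)) -
                   sum(Atil)^2 / struct$s11,
                 prevalence = prevalence),
            class = "mqls_prep")
}

#' Evaluate the quasi-likelihood score statistic at one locus
#'
#' @param prep an `"mqls_prep"` from [mqls_prepare()].
#' @param y dosage vector (0/1/2 risk-allele counts) named by id or aligned
#'   with `prep$N`.
#' @param locus optional locus label carried into the result.
#' @return a one-row data.frame: `locus`, `W`, `p`, `mu_hat`, `testable`.
#'   A monomorphic locus (constant `Y` or degenerate variance) is flagged
#'   `testable = FALSE` with `NA` statistics.
#' @export
mqls_statistic <- function(prep, y, locus = NA_character_) {
  if (!is.null(names(y))) y <- y[prep$N]
  Y <- y / 2
  ok <- !anyNA(Y) && var(Y) > 0
  if (ok) {
    mu <- sum(prep$Kinv1 * Y) / prep$s11
    sig2 <- mu * (1 - mu) / 2
    if (sig2 <= 0 || prep$denom_struct <= 0) ok <- FALSE
  }
  if (!ok)
    return(data.frame(locus = locus, W = NA_real_, p = NA_real_,
                      mu_hat = NA_real_, testable = FALSE,
                      stringsAsFactors = FALSE))
  num <- sum(prep$Atilde * Y) - mu * prep$At1
  W <- num^2 / (sig2 * prep$denom_struct)
  data.frame(locus = locus, W = W, p = pchisq(W, 1, lower.tail = FALSE),
             mu_hat = mu, testable = TRUE, stringsAsFactors = FALSE)
}

#' Scan all loci of a replicate
#'
#' Runs the quasi-likelihood score test at every locus of a simulated (or
#' read-in) replicate, reusing the structure factorization across loci (and
#' across replicates when `struct` is supplied).
#'
#' @param rep a [simulate_replicate()] result, or any list with a
#'   `genotypes` dosage matrix (rows named by id) and named `affection`
#'   vector.
#' @param km [kinship()] matrix over the members to analyse; for
#'   split-pedigree analyses pass [subpedigree_kinship_union()].
#' @param prevalence assumed population prevalence.
#' @param genotyped ids forming the genotyped set; default: members of `km`
#'   with a non-missing genotype row.
#' @param struct optional [mqls_structure()] cache.
#' @return data.frame with one row per locus (`locus`, `W`, `p`, `mu_hat`,
#'   `testable`).
#' @export
run_mqls_scan <- function(rep, km, prevalence = 106 / 798, genotyped = NULL,
                          struct = NULL) {
  gmat <- rep$genotypes
  if (is.null(genotyped))
    genotyped <- intersect(km$ids, rownames(gmat)[!is.na(gmat[, 1])])
  if (!all(genotyped %in% rownames(gmat)))
    ped_stop("member_mismatch", "kinship ids missing from replicate genotypes")
  prep <- mqls_prepare(km, genotyped, rep$affection, prevalence, struct = struct)
  G <- gmat[prep$N, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(ncol(G)), function(l)
    mqls_statistic(prep, unname(G[, l]),
                   locus = colnames(G)[l] %||% sprintf("L%03d", l))))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
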