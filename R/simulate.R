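#' Haldane map function
#'
#' Converts genetic distance in centimorgans to a recombination fraction:
#' \eqn{\theta = (1 - e^{-2d/100})/2}.
#'
#' @param d_cM non-negative genetic distance in cM.
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane_theta <- function(d_cM) {
  if (any(d_cM < 0)) ped_stop("bad_distance", "genetic distance must be >= 0")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Marker map
#'
#' An ordered set of SNP loci.  The default emulates a dense null panel:
#' 124 autosomal SNPs on one chromosome at uniform 0.062 cM spacing, with
#' the optional disease locus at the middle marker.
#'
#' @param n_loci number of loci.
#' @param spacing_cM uniform inter-marker spacing in cM.
#' @param chromosome chromosome label.
#' @param disease_locus_index index of the disease SNP (default: middle
#'   marker), used by disease models; `NA` for a pure null map.
#' @return An object of class `"marker_map"` with fields `chromosome`,
#'   `name`, `position_cM`, `theta` (adjacent recombination fractions) and
#'   `disease_locus_index`.
#' @export
marker_map <- function(n_loci = 124, spacing_cM = 0.062, chromosome = 1,
                       disease_locus_index = (n_loci + 1) %/% 2) {
  pos <- (seq_len(n_loci) - 1) * spacing_cM
  structure(list(chromosome = rep(chromosome, n_loci),
                 name = sprintf("SNP%03d", seq_len(n_loci)),
                 position_cM = pos,
                 theta = haldane_theta(diff(pos)),
                 disease_locus_index = disease_locus_index,
                 n_loci = n_loci),
            class = "marker_map")
}

#' Disease model for gene-dropping simulation
#'
#' Per-genotype penetrances are calibrated so the Hardy-Weinberg-weighted
#' mean penetrance equals the population prevalence `K`, with per-genotype
#' odds scaled by the odds ratio `psi` according to the inheritance mode:
#' dominant multiplies the odds once for 1 or 2 risk alleles, recessive only
#' for 2, additive multiplies per allele (`psi^g`).  `mode = "null"` carries
#' no genotype effect and copies template affection labels verbatim.
#'
#' @param mode one of `"null"`, `"dominant"`, `"recessive"`, `"additive"`.
#' @param odds_ratio genotype relative odds `psi` (> 0); ignored for null.
#' @param maf risk (minor) allele frequency of the disease SNP.
#' @param prevalence population prevalence `K`.
#' @return An object of class `"disease_model"` with the calibrated
#'   penetrance triple `f` (risk for 0/1/2 copies of the risk allele).
#' @export
disease_model <- function(mode = c("null", "dominant", "recessive", "additive"),
                          odds_ratio = 1, maf = 0.2, prevalence = 106 / 798) {
  mode <- match.arg(mode)
  f <- if (mode == "null") rep(prevalence, 3)
       else calibrate_penetrance(mode, odds_ratio, maf, prevalence)
  structure(list(mode = mode, odds_ratio = odds_ratio, maf = maf,
                 prevalence = prevalence, f = f),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("Disease model: %s, OR %.2f, MAF %.3f, prevalence %.4f\n",
              x$mode, x$odds_ratio, x$maf, x$prevalence))
  cat(sprintf("  penetrances (0/1/2 risk alleles): %.5f / %.5f / %.5f\n",
              x$f[1], x$f[2], x$f[3]))
  invisible(x)
}

#' Calibrate penetrances to a prevalence
#'
#' Solves for `(f0, f1, f2)` with `odds(f_g) = psi^{m(g)} * odds(f0)`
#' (`m` per mode: dominant 0,1,1; recessive 0,0,1; additive 0,1,2) subject to
#' the Hardy-Weinberg-weighted mean penetrance equalling `K`, by a monotone
#' scalar root solve in `f0`.
#'
#' @param mode `"dominant"`, `"recessive"` or `"additive"`.
#' @param psi odds ratio (> 0).
#' @param p risk allele frequency.
#' @param K target prevalence.
#' @return numeric penetrance triple.
#' @export
calibrate_penetrance <- function(mode, psi, p, K) {
  stopifnot(psi > 0, p > 0, p < 1, K > 0, K < 1)
  m <- switch(mode,
              dominant = c(0, 1, 1),
              recessive = c(0, 0, 1),
              additive = c(0, 1, 2),
              ped_stop("bad_mode", "unknown inheritance mode '%s'", mode))
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  mean_pen <- function(f0) {
    odds <- f0 / (1 - f0) * psi^m
    sum(hwe * odds / (1 + odds))
  }
  # mean penetrance is increasing in f0, from 0 to 1
  root <- uniroot(function(f0) mean_pen(f0) - K, interval = c(1e-14, 1 - 1e-14),
                  tol = 1e-14)
  if (abs(mean_pen(root$root) - K) > 1e-10)
    ped_stop("no_root", "penetrance calibration did not converge")
  f0 <- root$root
  odds <- f0 / (1 - f0) * psi^m
  odds / (1 + odds)
}

#' Draw founder haplotypes
#'
#' Two haplotypes per founder; each allele an independent Bernoulli draw
#' with risk-allele probability `p` at every locus (loci simulated in
#' linkage equilibrium at a fixed minor allele frequency).
#'
#' @param n_founders number of founders.
#' @param map a [marker_map()].
#' @param p risk allele frequency.
#' @param seed optional RNG seed for a self-contained draw.
#' @return list of two 0/1 integer matrices `pat`, `mat`
#'   (`n_founders x n_loci`; 1 = risk allele).
#' @export
draw_founder_haplotypes <- function(n_founders, map, p, seed = NULL) {
  draw <- function() {
    list(pat = matrix(rbinom(n_founders * map$n_loci, 1L, p), n_founders),
         mat = matrix(rbinom(n_founders * map$n_loci, 1L, p), n_founders))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Gene-drop a marker panel through a pedigree
#'
#' Founders carry the supplied haplotypes; every non-founder receives one
#' recombinant gamete per parent: the transmitted haplotype starts from a
#' random parental strand and switches strand between adjacent loci with
#' probability `haldane_theta(spacing)`.  All members receive genotypes at
#' all loci (masking to the genotyped subset happens later).
#'
#' @param ped a [pedigree()].
#' @param founder_haps haplotypes from [draw_founder_haplotypes()] whose rows
#'   correspond to the founders in lexicographic id order.
#' @param map a [marker_map()].
#' @param seed optional RNG seed.
#' @return members x loci integer dosage matrix (row-named by id) counting
#'   risk alleles; attribute `"haplotypes"` holds the phased `pat`/`mat`
#'   matrices.
#' @export
gene_drop <- function(ped, founder_haps, map, seed = NULL) {
  topo <- ped_topology(ped)
  n <- length(topo$ids)
  L <- map$n_loci
  founder_rows <- which(topo$father == 0L)
  if (nrow(founder_haps$pat) != length(founder_rows))
    ped_stop("unassigned_founder",
             "founder haplotypes (%d) do not match founder count (%d)",
             nrow(founder_haps$pat), length(founder_rows))
  hp <- hm <- matrix(0L, n, L)
  hp[founder_rows, ] <- founder_haps$pat
  hm[founder_rows, ] <- founder_haps$mat
  run <- function() .gene_drop_cpp(topo$father, topo$mother, hp, hm, map$theta)
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  dos <- res$pat + res$mat
  rownames(dos) <- topo$ids
  dos <- dos[ped$id, , drop = FALSE]
  colnames(dos) <- map$name
  attr(dos, "haplotypes") <- list(pat = res$pat, mat = res$mat, ids = topo$ids)
  dos
}

#' Assign affection status from genotypes
#'
#' Under the null the template affection labels are copied verbatim (the
#' replicate keeps the template's sampling frame).  Under a disease model,
#' each template-phenotyped member is affected with probability
#' `f[g + 1]` given its dosage `g` at the disease locus, unaffected
#' otherwise; template-unphenotyped members stay unknown.
#'
#' @param genotypes full (unmasked) dosage matrix from [gene_drop()].
#' @param model a [disease_model()].
#' @param template the template [pedigree()].
#' @param map a [marker_map()] providing `disease_locus_index`.
#' @param seed optional RNG seed.
#' @return integer affection vector (0/1/2) aligned with `template$id`.
#' @export
assign_affection <- function(genotypes, model, template, map, seed = NULL) {
  if (model$mode == "null") return(template$affection)
  if (is.na(map$disease_locus_index))
    ped_stop("no_disease_locus", "disease_locus_index unset for a non-null model")
  g <- genotypes[template$id, map$disease_locus_index]
  aff <- rep(0L, nrow(template))
  ph <- template$phenotyped
  draw <- function() runif(sum(ph)) < model$f[g[ph] + 1]
  hit <- if (is.null(seed)) draw() else with_seed(seed, draw())
  aff[ph] <- ifelse(hit, 2L, 1L)
  aff
}

#' Simulate one replicate on a template pedigree
#'
#' One gene-dropped genotype matrix plus a phenotype vector, with genotypes
#' masked to the template's genotyped subset and phenotypes to the
#' phenotyped subset.  The replicate seed is derived deterministically from
#' `(master_seed, index)` so any replicate can be regenerated in isolation.
#'
#' @param template template [pedigree()].
#' @param map a [marker_map()].
#' @param model a [disease_model()].
#' @param index replicate index (1-based).
#' @param master_seed master seed of the replicate stream.
#' @return An object of class `"replicate_sim"`: list with `genotypes`
#'   (genotyped members x loci dosage, `NA`-masked elsewhere), `affection`
#'   (0/1/2 over all members, named), `index`, `seed`.
#' @export
simulate_replicate <- function(template, map, model, index, master_seed) {
  seed <- derive_seed(master_seed, "replicate", index)
  n_founders <- sum(founder_mask(template))
  fh <- draw_founder_haplotypes(n_founders, map, model$maf,
                                seed = derive_seed(seed, "founders"))
  dos <- gene_drop(template, fh, map, seed = derive_seed(seed, "drop"))
  aff <- assign_affection(dos, model, template, map,
                          seed = derive_seed(seed, "affection"))
  names(aff) <- template$id
  masked <- dos
  masked[!template$genotyped, ] <- NA_integer_
  structure(list(genotypes = masked, affection = aff,
                 index = as.integer(index), seed = seed),
            class = "replicate_sim")
}

#' Generate a stream of replicates
#'
#' @inheritParams simulate_replicate
#' @param n_reps number of replicates.
#' @return list of [simulate_replicate()] results (possibly empty).
#' @export
generate_replicates <- function(template, map, model, n_reps, master_seed) {
  lapply(seq_len(n_reps), function(i)
    simulate_replicate(template, map, model, i, master_seed))
}

# phenotype vector of a replicate restricted to a pedigree (template or
# subpedigree): affection for members of `ped`, in ped id order
replicate_phenotype <- function(rep, ped) rep$affection[ped$id]
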