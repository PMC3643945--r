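# Independent oracles, implemented from first principles and sharing no code
# paths with the package internals they check.

# --- gene-dropping IBD estimator of kinship --------------------------------
# Drops uniquely labelled founder alleles down the pedigree (single locus)
# and estimates phi_ij as the probability that a randomly chosen allele from
# i is identical by descent to one from j.  Vectorized across drops.
oracle_ibd_kinship <- function(ped, ids, ndrops = 5e4) {
  gen <- attr(ped, "generation")
  ord <- order(gen, ped$id)
  ids_o <- ped$id[ord]
  fid <- match(ped$father[ord], ids_o)
  mid <- match(ped$mother[ord], ids_o)
  n <- nrow(ped)
  P <- M <- matrix(0L, n, ndrops)
  for (i in seq_len(n)) {
    if (is.na(fid[i])) {
      P[i, ] <- 2L * i - 1L
      M[i, ] <- 2L * i
    } else {
      pick <- runif(ndrops) < 0.5
      P[i, ] <- ifelse(pick, P[fid[i], ], M[fid[i], ])
      pick <- runif(ndrops) < 0.5
      M[i, ] <- ifelse(pick, P[mid[i], ], M[mid[i], ])
    }
  }
  rows <- match(ids, ids_o)
  est <- function(i, j) {
    v <- ((P[i, ] == P[j, ]) + (P[i, ] == M[j, ]) +
          (M[i, ] == P[j, ]) + (M[i, ] == M[j, ])) / 4
    c(mean(v), stats::sd(v) / sqrt(ndrops))
  }
  list(est = function(id_i, id_j) est(rows[match(id_i, ids)],
                                      rows[match(id_j, ids)]))
}

# --- brute-force pedigree likelihood ---------------------------------------
# Enumerates every configuration of ordered two-locus genotypes (16 states
# per member; or 4 states single-locus) and sums the probability of the
# observed data.  Its transmission/prior/penetrance terms are written out
# independently of the package's factor machinery.
oracle_brute_likelihood <- function(ped, dosage, marker_freq, pen, q, theta,
                                    locus = c("joint", "trait", "marker"),
                                    affection = NULL, affecteds_only = TRUE) {
  locus <- match.arg(locus)
  if (is.null(affection)) affection <- setNames(ped$affection, ped$id)
  n <- nrow(ped)
  ns <- if (locus == "joint") 16L else 4L
  stopifnot(ns^n <= 2^24)  # keep the enumeration honest and bounded
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  aff <- affection[ped$id]
  dos <- if (is.null(dosage)) rep(NA, n) else dosage[ped$id]

  # state decoding
  if (locus == "joint") {
    hapd <- function(h) h %/% 2L; hapm <- function(h) h %% 2L
    pat <- function(s) s %/% 4L; mat <- function(s) s %% 4L
    hap_freq <- function(h) (ifelse(hapd(h) == 1, q, 1 - q) *
                             ifelse(hapm(h) == 1, marker_freq, 1 - marker_freq))
    gam_prob <- function(g, s) {
      h1 <- pat(s); h2 <- mat(s)
      0.5 * (hapd(g) == hapd(h1)) *
        ((1 - theta) * (hapm(g) == hapm(h1)) + theta * (hapm(g) == hapm(h2))) +
      0.5 * (hapd(g) == hapd(h2)) *
        ((1 - theta) * (hapm(g) == hapm(h2)) + theta * (hapm(g) == hapm(h1)))
    }
    nD <- function(s) hapd(pat(s)) + hapd(mat(s))
    nM <- function(s) hapm(pat(s)) + hapm(mat(s))
  } else {
    pfreq <- if (locus == "trait") q else marker_freq
    pat <- function(s) s %/% 2L; mat <- function(s) s %% 2L
    hap_freq <- function(h) ifelse(h == 1, pfreq, 1 - pfreq)
    gam_prob <- function(g, s) 0.5 * ((g == pat(s)) + (g == mat(s)))
    nD <- function(s) pat(s) + mat(s)
    nM <- nD
  }
  states <- 0:(ns - 1)
  grid <- as.matrix(do.call(expand.grid, rep(list(states), n)))
  pr <- rep(1, nrow(grid))
  for (i in seq_len(n)) {
    s <- grid[, i]
    if (is.na(fi[i])) {
      pr <- pr * hap_freq(pat(s)) * hap_freq(mat(s))
    } else {
      pr <- pr * gam_prob(pat(s), grid[, fi[i]]) * gam_prob(mat(s), grid[, mi[i]])
    }
    if (locus != "marker") {
      a <- aff[i]
      if (!is.na(a) && a == 2L) pr <- pr * pen[nD(s) + 1]
      if (!is.na(a) && a == 1L && !affecteds_only) pr <- pr * (1 - pen[nD(s) + 1])
    }
    if (locus != "trait" && !is.na(dos[i])) pr <- pr * (nM(s) == dos[i])
  }
  log10(sum(pr))
}

# --- direct quadratic-form evaluation of the score statistic ---------------
# Plain matrix arithmetic with solve(); no Cholesky reuse, no package code.
oracle_mqls_W <- function(K_NN, Y2, A_N, k, K_NM = NULL, K_MM = NULL,
                          A_M = NULL) {
  Y <- Y2 / 2
  Atil <- A_N
  if (!is.null(K_NM)) Atil <- A_N + as.vector(K_NM %*% solve(K_MM, A_M))
  one <- rep(1, length(Y))
  Ki <- solve(K_NN)
  mu <- as.numeric(t(one) %*% Ki %*% Y) / as.numeric(t(one) %*% Ki %*% one)
  sig2 <- mu * (1 - mu) / 2
  num <- as.numeric(t(Atil) %*% (Y - mu * one))
  den <- sig2 * (as.numeric(t(Atil) %*% K_NN %*% Atil) -
                   as.numeric(t(Atil) %*% one)^2 /
                   as.numeric(t(one) %*% Ki %*% one))
  num^2 / den
}

# --- small random pedigrees for property tests -----------------------------
make_random_pedigree <- function(seed, n_generations = 5, target = 120,
                                 n_genotyped = 30, n_affected = 8,
                                 n_unaffected = 14, consang = 0.2) {
  generate_template(template_params(
    n_generations = n_generations, n_founder_couples = 3,
    target_members = target, n_genotyped = n_genotyped,
    n_affected = n_affected, n_unaffected = n_unaffected,
    consanguinity_rate = consang, seed = seed))
}

# tiny literal pedigrees used across tests
trio_pedigree <- function(aff_child = 2L)
  pedigree(c("c1", "f1", "m1"), c("f1", NA, NA), c("m1", NA, NA),
           c(1, 1, 2), c(aff_child, 1, 1))

# small literal pedigrees (<= 5 members) with random topology, sexes and
# affection, for brute-force enumeration oracles
small_random_pedigree <- function(seed) {
  set.seed(seed)
  topo <- sample(c("trio", "quartet", "sibship3", "threegen"), 1)
  aff <- function(n) sample(0:2, n, replace = TRUE)
  switch(topo,
    trio = pedigree(c("f", "m", "k1"), c(NA, NA, "f"), c(NA, NA, "m"),
                    c(1, 2, sample(1:2, 1)), aff(3)),
    quartet = pedigree(c("f", "m", "k1", "k2"),
                       c(NA, NA, "f", "f"), c(NA, NA, "m", "m"),
                       c(1, 2, sample(1:2, 2, replace = TRUE)), aff(4)),
    sibship3 = pedigree(c("f", "m", "k1", "k2", "k3"),
                        c(NA, NA, "f", "f", "f"), c(NA, NA, "m", "m", "m"),
                        c(1, 2, sample(1:2, 3, replace = TRUE)), aff(5)),
    threegen = pedigree(c("gf", "gm", "p1", "s1", "k1"),
                        c(NA, NA, "gf", NA, "p1"), c(NA, NA, "gm", NA, "s1"),
                        c(1, 2, 1, 2, sample(1:2, 1)), aff(5)))
}

# phase-known fully-penetrant family: grandfather affected with marker 2/2,
# grandmother unaffected 1/1, their affected child P marries an unaffected
# 1/1 spouse; every non-recombinant offspring adds log10(2) to the LOD
phase_known_family <- function(m_children, recomb = 0) {
  naff <- ceiling(m_children / 2)
  kid_aff <- c(rep(2L, naff), rep(1L, m_children - naff))
  ids <- c("gf", "gm", "p0", "s0", sprintf("k%02d", seq_len(m_children)))
  ped <- pedigree(ids,
                  c(NA, NA, "gf", NA, rep("p0", m_children)),
                  c(NA, NA, "gm", NA, rep("s0", m_children)),
                  c(1, 2, 1, 2, rep(1, m_children)),
                  c(2, 1, 2, 1, kid_aff))
  dos <- setNames(c(2L, 0L, 1L, 0L, ifelse(kid_aff == 2L, 1L, 0L)), ids)
  if (recomb > 0) dos[4 + seq_len(recomb)] <- 0L  # affected recombinants
  list(ped = ped, dos = dos)
}

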