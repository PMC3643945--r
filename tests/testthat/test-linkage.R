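# wrap a single pedigree as a subpedigree set for the scan API
as_set <- function(ped) list(subpedigrees = list(ped))

# named dosage + replicate-like object for a literal pedigree
make_rep <- function(ped, dosage) {
  g <- matrix(dosage, ncol = 1, dimnames = list(ped$id, "M1"))
  list(genotypes = g, affection = setNames(ped$affection, ped$id))
}

test_that("peeling equals brute-force enumeration (joint, trait and marker)", {
  n_cases <- 0
  for (seed in 1:40) {
    p <- small_random_pedigree(seed)
    n_cases <- n_cases + 1
    mod <- linkage_model(sample(c("dominant", "recessive"), 1),
                         q = runif(1, 0.005, 0.3))
    pm <- runif(1, 0.1, 0.6)
    theta <- sample(c(0, 0.1, 0.5), 1)
    dos <- setNames(sample(c(0:2, NA), nrow(p), replace = TRUE), p$id)
    l_pkg <- pedigree_likelihood(p, dos, pm, mod, theta)
    l_orc <- oracle_brute_likelihood(p, dos, pm, mod$penetrance, mod$q, theta)
    if (is.finite(l_orc)) {
      expect_equal(l_pkg, l_orc, tolerance = 1e-10)
    } else {
      expect_true(identical(l_pkg, -Inf))
    }
  }
  expect_gt(n_cases, 15)
})

test_that("single-locus peeling matches enumeration on 8-member pedigrees", {
  # the 4-state marker-only model checks the elimination engine at a size
  # where the joint grid would be unenumerable
  set.seed(2718)
  for (rep_i in 1:20) {
    ids <- c("f1", "m1", "f2", "m2", "c1", "c2", "g1", "g2")
    p <- pedigree(ids,
                  c(NA, NA, NA, NA, "f1", "f1", "f2", "f2"),
                  c(NA, NA, NA, NA, "m1", "m1", "m2", "m2"),
                  c(1, 2, 1, 2, 2, 2, 1, 1),
                  sample(0:2, 8, replace = TRUE))
    pm <- runif(1, 0.1, 0.7)
    dos <- setNames(sample(c(0:2, NA), 8, replace = TRUE), ids)
    mod <- linkage_model("dominant")
    eng <- pedpower:::twopoint_engine(p, mod, pm, theta = 0)
    l_pkg <- pedpower:::engine_loglik(eng, "marker",
                                      setNames(p$affection, p$id), dos)
    l_orc <- oracle_brute_likelihood(p, dos, pm, mod$penetrance, mod$q, 0,
                                     locus = "marker") * log(10)
    if (is.finite(l_orc)) expect_equal(l_pkg, l_orc, tolerance = 1e-9)
    else expect_true(identical(l_pkg, -Inf))
  }
})

test_that("missing marker data makes the likelihood independent of theta", {
  p <- small_random_pedigree(8)
  mod <- linkage_model("dominant")
  dos <- setNames(rep(NA_integer_, nrow(p)), p$id)
  ls <- vapply(c(0, 0.1, 0.3, 0.5), function(th)
    pedigree_likelihood(p, dos, 0.2, mod, th), 1)
  expect_true(all(abs(ls - ls[1]) < 1e-10))
})

test_that("at theta one-half the joint likelihood factorizes", {
  for (seed in c(104, 112, 131)) {
    p <- small_random_pedigree(seed)
    mod <- linkage_model("recessive")
    set.seed(seed)
    dos <- setNames(sample(c(0:2, NA), nrow(p), replace = TRUE), p$id)
    lj <- pedigree_likelihood(p, dos, 0.3, mod, 0.5)
    lt <- oracle_brute_likelihood(p, NULL, 0.3, mod$penetrance, mod$q, 0.5,
                                  locus = "trait")
    lm <- oracle_brute_likelihood(p, dos, 0.3, mod$penetrance, mod$q, 0.5,
                                  locus = "marker")
    expect_equal(lj, lt + lm, tolerance = 1e-9)
  }
})

test_that("Mendelian-inconsistent marker data give an exact zero likelihood", {
  p <- trio_pedigree()
  dos <- setNames(c(2L, 0L, 0L), c("c1", "f1", "m1"))  # child 2 from 0 x 0
  expect_identical(pedigree_likelihood(p, dos, 0.2, linkage_model("dominant"),
                                       0), -Inf)
})

test_that("a phase-known fully-penetrant family scores m * log10(2)", {
  mod <- linkage_model("dominant", q = 0.01, penetrance = c(0, 1, 1),
                       affecteds_only = FALSE)
  for (m in c(2, 4, 6)) {
    fam <- phase_known_family(m)
    z <- pedigree_likelihood(fam$ped, fam$dos, 0.2, mod, 0) -
      pedigree_likelihood(fam$ped, fam$dos, 0.2, mod, 0.5)
    expect_equal(z, m * log10(2), tolerance = 1e-9)
  }
  # an extra non-recombinant meiosis never lowers the LOD at theta = 0
  z4 <- with(phase_known_family(4), pedigree_likelihood(ped, dos, 0.2, mod, 0) -
               pedigree_likelihood(ped, dos, 0.2, mod, 0.5))
  z5 <- with(phase_known_family(5), pedigree_likelihood(ped, dos, 0.2, mod, 0) -
               pedigree_likelihood(ped, dos, 0.2, mod, 0.5))
  expect_gte(z5, z4)
  # one recombinant at theta = 0 kills the linked likelihood entirely
  fam_r <- phase_known_family(4, recomb = 1)
  expect_identical(pedigree_likelihood(fam_r$ped, fam_r$dos, 0.2, mod, 0),
                   -Inf)
})

test_that("HLOD bounds, alpha limits and dense-grid agreement hold", {
  set.seed(1234)
  for (i in 1:50) {
    z <- rnorm(sample(3:12, 1), sd = runif(1, 0.2, 1.5))
    h <- hlod(z)
    expect_gte(h$hlod, 0)
    expect_gte(h$hlod + 1e-12, max(0, sum(z)))
    dense <- max(vapply(seq(0, 1, by = 1e-4), function(a)
      sum(log10(a * 10^z + 1 - a)), 1))
    expect_lt(abs(h$hlod - dense), 1e-6)
  }
  # alpha = 1 recovers the total LOD for an all-positive Z vector
  h <- hlod(c(0.5, 0.8))
  expect_equal(h$alpha, 1, tolerance = 1e-6)
  expect_equal(h$hlod, 1.3, tolerance = 1e-6)
})

test_that("uninformative subpedigrees contribute zero and HLOD dominates mixtures", {
  # no affected members and no genotypes -> Z = 0 for every subpedigree
  p <- pedigree(c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
                c(1, 2, 1), c(1, 1, 1), genotyped = FALSE,
                phenotyped = c(TRUE, TRUE, TRUE))
  r <- make_rep(p, rep(NA_integer_, 3))
  res <- twopoint_lod(as_set(p), r, 1, linkage_model("dominant"))
  expect_equal(res$LOD, 0)
  expect_equal(res$HLOD, 0)
  # mixed-sign Z: admixture bound
  h <- hlod(c(1.2, -2))
  expect_gte(h$hlod, 0)
  expect_gte(h$hlod, sum(c(1.2, -2)))
  expect_lte(h$alpha, 1)
})

test_that("compiled marker scans agree with the direct evaluation path", {
  tm <- make_random_pedigree(55, target = 160, n_genotyped = 45,
                             n_affected = 10, n_unaffected = 18)
  set <- split_pedigree(tm, bit_limit = 16)
  map <- marker_map(6)
  r <- simulate_replicate(tm, map, disease_model("null"), 1, 66)
  mod <- linkage_model("recessive")
  sc <- twopoint_scan(set, r, mod)
  engines <- twopoint_engines(set, mod, 0.2, affection = r$affection)
  for (mk in c(1, 4, 6)) {
    direct <- twopoint_lod(set, r, mk, mod, engines = engines)
    expect_equal(sc$LOD[mk], direct$LOD, tolerance = 1e-9)
    expect_equal(sc$HLOD[mk], direct$HLOD, tolerance = 1e-9)
  }
})
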