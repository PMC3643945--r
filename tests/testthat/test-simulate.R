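small_template <- function()
  generate_template(template_params(
    n_generations = 6, n_founder_couples = 4, target_members = 300,
    n_genotyped = 80, n_affected = 15, n_unaffected = 55, seed = 7))

test_that("the Haldane map function has the right limits and closed form", {
  expect_equal(haldane_theta(0), 0)
  expect_equal(haldane_theta(1e9), 0.5)
  expect_equal(haldane_theta(0.062), 0.5 * (1 - exp(-0.00124)))
  expect_error(haldane_theta(-1), class = "pedpower_bad_distance")
})

test_that("founder haplotype pools hit the target allele frequency", {
  map <- marker_map(124)
  fh <- draw_founder_haplotypes(1000, map, 0.2, seed = 5)
  freq <- (colSums(fh$pat) + colSums(fh$mat)) / 2000
  se <- sqrt(0.2 * 0.8 / 2000)
  expect_true(all(abs(freq - 0.2) < 4 * se))
  expect_true(all(draw_founder_haplotypes(10, map, 0, seed = 1)$pat == 0))
  expect_true(all(draw_founder_haplotypes(10, map, 1, seed = 1)$mat == 1))
})

test_that("gene dropping is Mendelian and transmits each strand half the time", {
  tm <- small_template()
  map <- marker_map(20)
  fh <- draw_founder_haplotypes(sum(is.na(tm$father)), map, 0.2, seed = 3)
  dos <- gene_drop(tm, fh, map, seed = 4)
  fi <- match(tm$father, tm$id); mi <- match(tm$mother, tm$id)
  kid <- which(!is.na(fi))
  for (l in seq_len(ncol(dos))) {
    d <- dos[, l]
    # child dosage must lie within what the parents can transmit
    lo <- (d[fi[kid]] == 2) + (d[mi[kid]] == 2)
    hi <- 2 - ((d[fi[kid]] == 0) + (d[mi[kid]] == 0))
    expect_true(all(d[kid] >= lo & d[kid] <= hi))
  }
  # heterozygous parent transmits the risk allele half the time: one
  # sibship of n children is n independent meioses at a single locus
  n <- 1e5
  ids <- c("f", "m", sprintf("k%06d", seq_len(n)))
  big <- pedigree(ids, c(NA, NA, rep("f", n)), c(NA, NA, rep("m", n)),
                  c(1, 2, rep(1, n)), rep(0, n + 2))
  map1 <- marker_map(1)
  fh <- list(pat = matrix(c(1L, 0L), 2, 1), mat = matrix(c(0L, 0L), 2, 1))
  dos <- gene_drop(big, fh, map1, seed = 12)
  hits <- dos[startsWith(rownames(dos), "k"), 1]
  expect_lt(abs(mean(hits) - 0.5), 4 * 0.5 / sqrt(n))
})

test_that("zero recombination transmits whole parental haplotypes", {
  tm <- small_template()
  map <- marker_map(12, spacing_cM = 1)
  map$theta[] <- 0
  fh <- draw_founder_haplotypes(sum(is.na(tm$father)), map, 0.5, seed = 8)
  dos <- gene_drop(tm, fh, map, seed = 9)
  hp <- attr(dos, "haplotypes")
  fa <- match(tm$father, tm$id)
  ids <- hp$ids
  for (i in which(!is.na(fa))[1:25]) {
    row <- match(tm$id[i], ids); prow <- match(tm$father[i], ids)
    child_pat <- hp$pat[row, ]
    expect_true(identical(child_pat, hp$pat[prow, ]) ||
                  identical(child_pat, hp$mat[prow, ]))
  }
})

test_that("penetrance calibration satisfies the odds and prevalence constraints", {
  modes <- list(dominant = c(0, 1, 1), recessive = c(0, 0, 1),
                additive = c(0, 1, 2))
  hwe <- c(0.64, 0.32, 0.04)
  for (mode in names(modes)) {
    f <- calibrate_penetrance(mode, 5, 0.2, 0.133)
    odds <- f / (1 - f)
    expect_equal(odds / odds[1], 5^modes[[mode]], tolerance = 1e-9)
    expect_lt(abs(sum(hwe * f) - 0.133), 1e-10)
  }
  expect_equal(disease_model("dominant", 1, prevalence = 0.2)$f, rep(0.2, 3))
  f <- calibrate_penetrance("recessive", 5, 0.2, 0.133)
  expect_equal(f[1], f[2])
  expect_lt(f[1], f[3])
})

test_that("affection assignment respects the template sampling frame", {
  tm <- small_template()
  map <- marker_map(9)
  m0 <- disease_model("null")
  r <- simulate_replicate(tm, map, m0, 1, 123)
  expect_identical(unname(r$affection[tm$id]), tm$affection)
  expect_equal(sum(r$affection == 2L), 15)
  # certain penetrance affects every phenotyped member
  m1 <- disease_model("dominant", 5)
  m1$f <- c(1, 1, 1)
  fh <- draw_founder_haplotypes(sum(is.na(tm$father)), map, 0.2, seed = 1)
  dos <- gene_drop(tm, fh, map, seed = 2)
  aff <- assign_affection(dos, m1, tm, map, seed = 3)
  expect_true(all(aff[tm$phenotyped] == 2L))
  expect_true(all(aff[!tm$phenotyped] == 0L))
  # a non-null model needs a disease locus
  map_nodl <- marker_map(9, disease_locus_index = NA)
  expect_error(assign_affection(dos, disease_model("dominant", 2), tm, map_nodl),
               class = "pedpower_no_disease_locus")
})

test_that("replicate streams are deterministic and masked to the template flags", {
  tm <- small_template()
  map <- marker_map(6)
  m <- disease_model("additive", 2)
  r1 <- generate_replicates(tm, map, m, 3, 2024)
  r2 <- generate_replicates(tm, map, m, 3, 2024)
  expect_identical(r1, r2)
  expect_length(generate_replicates(tm, map, m, 0, 1), 0)
  expect_true(all(is.na(r1[[1]]$genotypes[!tm$genotyped, ])))
  expect_true(all(!is.na(r1[[1]]$genotypes[tm$genotyped, ])))
  # a replicate can be regenerated in isolation from (master seed, index)
  expect_identical(r1[[3]], simulate_replicate(tm, map, m, 3, 2024))
})

test_that("null phenotypes are independent of genotypes; risk models enrich cases", {
  tm <- small_template()
  map <- marker_map(3, disease_locus_index = 2)
  geno <- tm$id[tm$genotyped]
  aff_ids <- tm$id[tm$affection == 2L]
  ctl_ids <- tm$id[tm$affection == 1L & tm$genotyped]
  nullcor <- vapply(1:60, function(i) {
    r <- simulate_replicate(tm, map, disease_model("null"), i, 31)
    cor(r$genotypes[geno, 2], r$affection[geno] == 2L)
  }, 1)
  expect_lt(abs(mean(nullcor)), 4 * sd(nullcor) / sqrt(length(nullcor)))
  freq_gap <- function(psi) {
    m <- disease_model("additive", psi)
    mean(vapply(1:40, function(i) {
      r <- simulate_replicate(tm, map, m, i, 77)
      ca <- names(r$affection)[r$affection == 2L & !is.na(r$genotypes[, 2])]
      co <- names(r$affection)[r$affection == 1L & !is.na(r$genotypes[, 2])]
      mean(r$genotypes[ca, 2]) / 2 - mean(r$genotypes[co, 2]) / 2
    }, 1))
  }
  gaps <- vapply(c(1.1, 5), freq_gap, 1)
  expect_true(all(gaps > 0))          # cases carry more risk alleles
  expect_gt(gaps[2], gaps[1])         # and more so for a stronger effect
})
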