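test_that("trio parses, validates and has bit size zero", {
  p <- trio_pedigree()
  expect_s3_class(p, "pedigree")
  expect_equal(sum(is.na(p$father)), 2)   # two founders
  expect_equal(sum(!is.na(p$father)), 1)  # one non-founder
  expect_equal(bit_size(p), 0L)
})

test_that("structural violations raise distinct identifiable errors", {
  expect_error(pedigree(c("a", "a"), c(NA, NA), c(NA, NA), c(1, 2), c(0, 0)),
               class = "pedpower_duplicate_id")
  expect_error(pedigree("c", "f", NA, 1, 0),
               class = "pedpower_single_parent")
  expect_error(pedigree(c("c", "f", "m"), c("f", NA, NA), c("x", NA, NA),
                        c(1, 1, 2), c(0, 0, 0)),
               class = "pedpower_parent_not_found")
  # mother reference pointing at a male
  expect_error(pedigree(c("c", "f", "m"), c("f", NA, NA), c("m", NA, NA),
                        c(1, 1, 1), c(0, 0, 0)),
               class = "pedpower_parent_sex")
  # two members each other's ancestors
  expect_error(pedigree(c("a", "b", "f", "m"), c("b", "a", NA, NA),
                        c("m", "m", NA, NA), c(1, 1, 1, 2), c(0, 0, 0, 0)),
               class = "pedpower_cyclic_ancestry")
})

test_that("bit size follows 2*nonfounders - founders and ignores ordering", {
  five <- pedigree(c("f", "m", "c1", "c2", "c3"),
                   c(NA, NA, "f", "f", "f"), c(NA, NA, "m", "m", "m"),
                   c(1, 2, 1, 2, 1), rep(0, 5))
  expect_equal(bit_size(five), 2L * 3L - 2L)
  shuffled <- pedigree(c("c3", "m", "c1", "f", "c2"),
                       c("f", NA, "f", NA, "f"), c("m", NA, "m", NA, "m"),
                       c(1, 2, 1, 1, 2), rep(0, 5))
  expect_equal(bit_size(shuffled), bit_size(five))
  p <- make_random_pedigree(3)
  fo <- sum(is.na(p$father))
  expect_equal(bit_size(p), 2L * (nrow(p) - fo) - fo)
})

test_that("ped file round trip preserves all fields and flags", {
  p <- make_random_pedigree(5, target = 100, n_genotyped = 25)
  ped_path <- tempfile(fileext = ".ped")
  flag_path <- tempfile(fileext = ".flags")
  write_pedfile(p, ped_path)
  write_flags(p, flag_path)
  q <- read_pedfile(ped_path, flag_path)
  expect_equal(as.data.frame(q), as.data.frame(p))
  expect_equal(attr(q, "generation"), attr(p, "generation"))
})

test_that("ped files with genotypes code alleles and missingness correctly", {
  p <- trio_pedigree()
  path <- tempfile(fileext = ".ped")
  write_pedfile(p, path)
  expect_equal(ncol(read.table(path)), 6)
  g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), 3, 2,
              dimnames = list(c("c1", "f1", "m1"), NULL))
  write_pedfile(p, path, genotypes = g)
  tab <- read.table(path, colClasses = "character")
  expect_equal(ncol(tab), 10)  # 6 + 2 markers x 2 alleles
  row_c1 <- unlist(tab[tab[[2]] == "c1", 7:10])
  expect_equal(unname(row_c1), c("1", "1", "0", "0"))  # dosage 0 then missing
  q <- read_pedfile(path)
  expect_equal(unname(attr(q, "genotypes")[c("c1", "f1", "m1"), ]), unname(g))
})

test_that("kinship recursion reproduces textbook coefficients", {
  # parent-offspring with unrelated founders
  p <- trio_pedigree()
  km <- kinship(p)
  expect_equal(km$phi["c1", "f1"], 0.25)
  expect_equal(km$phi["f1", "m1"], 0)
  # full sibs; offspring of full-sib mating
  p2 <- pedigree(c("a", "b", "s1", "s2", "x"),
                 c(NA, NA, "a", "a", "s1"), c(NA, NA, "b", "b", "s2"),
                 c(1, 2, 1, 2, 1), rep(0, 5))
  k2 <- kinship(p2)
  expect_equal(k2$phi["s1", "s2"], 0.25)
  expect_equal(unname(k2$h["x"]), 0.25)
  expect_equal(k2$phi["x", "x"], 0.625)
  # offspring of first cousins
  ids <- c("g1", "g2", "p1", "p2", "s1", "s2", "c1", "c2", "z")
  fat <- c(NA, NA, NA, NA, "g1", "g1", "p1", "p2", "c1")
  mot <- c(NA, NA, NA, NA, "g2", "g2", "s1", "s2", "c2")
  sex <- c(1, 2, 1, 1, 2, 2, 1, 2, 1)
  k3 <- kinship(pedigree(ids, fat, mot, sex, rep(0, 9)))
  expect_equal(unname(k3$h["z"]), 1 / 16)
  expect_equal(k3$phi["z", "z"], 0.53125)
})

test_that("kinship matrix is symmetric with PSD covariance form on looped pedigrees", {
  for (seed in c(2, 9)) {
    p <- make_random_pedigree(seed, consang = 0.3)
    km <- kinship(p)
    expect_equal(km$phi, t(km$phi))
    expect_true(all(km$h >= 0))
    expect_true(all(diag(km$phi) >= 0.5 & diag(km$phi) <= 1))
    K <- 2 * km$phi
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("kinship recursion agrees with a gene-dropping IBD estimator", {
  p <- make_random_pedigree(13, target = 200, n_genotyped = 40, consang = 0.3)
  km <- kinship(p)
  set.seed(99)
  orc <- oracle_ibd_kinship(p, p$id, ndrops = 4e4)
  set.seed(100)
  pairs <- cbind(sample(p$id, 30, replace = TRUE),
                 sample(p$id, 30, replace = TRUE))
  for (r in seq_len(nrow(pairs))) {
    e <- orc$est(pairs[r, 1], pairs[r, 2])
    expect_lt(abs(km$phi[pairs[r, 1], pairs[r, 2]] - e[1]),
              3 * e[2] + 1e-9)
  }
})
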