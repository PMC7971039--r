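AAs <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

test_that("aac_vector is the residue frequency vector", {
  v <- aac_vector("AAAA")
  expect_equal(unname(v["fA"]), 1)
  expect_equal(sum(v), 1)
  u <- aac_vector(paste(AAs, collapse = ""))
  expect_equal(unname(u), rep(0.05, 20))
  set.seed(2)
  for (s in random_protein(5, 37)) expect_equal(sum(aac_vector(s)), 1)
  expect_error(aac_vector("ABZ"), "invalid protein residue")
})

test_that("standardize_properties yields mean 0, population sd 1, all 24", {
  st <- standardize_properties(load_property_table())
  expect_equal(ncol(st$values), 24)
  for (p in colnames(st$values)) {
    v <- st$values[, p]
    expect_lt(abs(mean(v)), 1e-12)
    expect_lt(abs(sqrt(sum((v - mean(v))^2) / 20) - 1), 1e-12)
  }
})

test_that("standardization is affine-invariant and rejects constants", {
  pt <- load_property_table()
  shifted <- pt
  shifted$values[, "mass"] <- 3.7 * shifted$values[, "mass"] + 11
  expect_equal(standardize_properties(shifted)$values[, "mass"],
               standardize_properties(pt)$values[, "mass"])
  const <- pt
  const$values[, "polarity"] <- 5
  expect_error(standardize_properties(const), "'polarity' is constant")
})

test_that("theta_tier evaluates the squared-difference correlation", {
  gv <- matrix(0, 20, 3, dimnames = list(AAs, NULL))
  gv["C", ] <- c(1, -1, 2)
  # single A->C step: Theta = (1 + 1 + 4)/3 = 2
  expect_equal(theta_tier("AC", 1, gv), 2)
  expect_equal(theta_tier("CA", 1, gv), 2) # symmetric
  expect_equal(theta_tier("AAAAA", 3, gv), 0) # homopolymer
  expect_error(theta_tier("ACDE", 4, gv), "lag must satisfy")
})

test_that("pseaac_vector has the stated length, range and unit sum", {
  pt <- load_property_table()
  set.seed(4)
  for (s in random_protein(5, 80)) {
    v <- pseaac_vector(s, "A", lambda = 30, table = pt)
    expect_length(v, 50)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
  expect_error(pseaac_vector(random_protein(1, 25), "A", lambda = 30, id = "pX"),
               "pX.*L = 25.*lambda = 30")
})

test_that("pseaac omega->0 limit reproduces AAC; homopolymer collapses to one-hot", {
  s <- random_protein(1, 70)
  v <- pseaac_vector(s, "B", lambda = 20, omega = 1e-12)
  expect_equal(unname(v[1:20]), unname(aac_vector(s)), tolerance = 1e-9)
  homo <- strrep("L", 40)
  h <- pseaac_vector(homo, "A", lambda = 30)
  expect_equal(unname(h[1:20]), unname(aac_vector(homo)))
  expect_equal(unname(h[21:50]), rep(0, 30))
})

test_that("pseaac is invariant to affine rescaling of raw properties", {
  pt <- load_property_table()
  sc <- pt
  sc$values[, pt$groups$C] <- sweep(sc$values[, pt$groups$C], 2, c(2, 0.5, 10), "*") + 7
  s <- random_protein(1, 60)
  expect_equal(pseaac_vector(s, "C", table = pt), pseaac_vector(s, "C", table = sc))
})

test_that("build_feature_matrix reproduces the catalogued dimensions", {
  ds <- tiny_dataset(n_pairs = 4)
  all8 <- build_feature_matrix(ds, kmax = 3, mode = "plain")
  expect_equal(ncol(all8$x), 484) # 84 + 8 x 50
  expect_equal(nrow(all8$x), 4)
  a_only <- build_feature_matrix(ds, kmax = 3, groups = "A")
  expect_equal(ncol(a_only$x), 134)
  revc <- build_feature_matrix(ds, kmax = 3, mode = "revc")
  expect_equal(ncol(revc$x), 444) # 44 + 400
  # aptamer block first, then groups in A..H order
  expect_identical(colnames(all8$x)[1], "k1_A")
  expect_identical(colnames(all8$x)[85], "A_fA")
  expect_identical(colnames(all8$x)[484], "H_th30")
  expect_identical(all8$y, ds$pairs$label)
})

test_that("feature matrix CSV round-trips through the documented schema", {
  fm <- build_feature_matrix(tiny_dataset(3), kmax = 2, groups = "A")
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f)
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_identical(back$y, fm$y)
  expect_identical(back$pair_id, fm$pair_id)
})
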