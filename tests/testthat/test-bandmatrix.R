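test_that("packaged fixtures load with the documented shapes", {
  prot <- bg_protein()
  expect_equal(n_loci(prot), 17)
  expect_equal(n_genotypes(prot), 10)
  expect_equal(genotypes(prot), paste0("S", 1:10))
  pod <- bg_isozyme("pod")
  expect_equal(n_loci(pod), 5)
  expect_false(is.null(pod$intensity))
  expect_true(all(pod$intensity %in% 0:3))
})

test_that("constructor accepts a minimal 1x1 matrix and rejects bad input", {
  one <- band_matrix(matrix(1, 1, 1, dimnames = list("b1", "G1")))
  expect_equal(dim(one$presence), c(1L, 1L))

  m <- matrix(c(1, 2, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(band_matrix(m), "non-binary.*locus 'b'")
  m2 <- matrix(c(1, 0, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(band_matrix(m2), "all-zero")
  m3 <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(band_matrix(m3), "duplicate locus")
  m4 <- matrix(1, 1, 2, dimnames = list("a", c("x", "x")))
  expect_error(band_matrix(m4), "duplicate genotype")
  # intensity must coincide with presence
  p <- matrix(c(1L, 1L), 1, 2, dimnames = list("a", c("x", "y")))
  g <- matrix(c(2L, 0L), 1, 2, dimnames = list("a", c("x", "y")))
  expect_error(band_matrix(p, intensity = g), "coincide")
  # isozyme Rm outside [0,1]
  lo <- data.frame(locus_id = "a", assay = "isozyme", group = "POD",
                   size = 1.4)
  expect_error(band_matrix(matrix(1, 1, 1, dimnames = list("a", "x")),
                           loci = lo), "Rm")
})

test_that("write-then-read is the identity, with and without intensity", {
  for (bm in list(bg_protein(), bg_isozyme("ppo"))) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_band_matrix(bm, f)
    back <- read_band_matrix(f, intensity = !is.null(bm$intensity))
    expect_identical(back$presence, bm$presence)
    expect_identical(back$intensity, bm$intensity)
    expect_equal(back$loci, bm$loci)
  }
  # tab-separated dialect is auto-detected
  f <- withr::local_tempfile(fileext = ".tsv")
  write_band_matrix(bg_protein(), f, sep = "\t")
  expect_identical(read_band_matrix(f)$presence, bg_protein()$presence)
})

test_that("malformed files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("locus_id,assay,group,size,G1", "a,protein,P,10,maybe"), f)
  expect_error(read_band_matrix(f), "non-numeric.*G1")
  writeLines(c("id,assay,G1", "a,protein,1"), f)
  expect_error(read_band_matrix(f), "first four columns")
  expect_error(read_band_matrix("no/such/file.csv"), "not found")
})

test_that("collapse_intensity maps grades to presence and is idempotent", {
  pod <- bg_isozyme("pod")
  flat <- collapse_intensity(pod)
  expect_null(flat$intensity)
  expect_true(all(flat$presence %in% 0:1))
  # the Rm 0.6 band survives only in S1 and S2
  rm06 <- which(flat$loci$size == 0.6)
  expect_equal(genotypes(flat)[flat$presence[rm06, ] == 1], c("S1", "S2"))
  expect_identical(collapse_intensity(flat)$presence, flat$presence)
  # all-grade-3 grid collapses to all ones
  g <- matrix(3L, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  bm <- band_matrix((g > 0) * 1L, intensity = g)
  expect_true(all(collapse_intensity(bm)$presence == 1L))
})

test_that("pool_bands concatenates loci, aligns genotypes by label", {
  pooled <- pool_bands(bg_protein(), bg_isozyme("pod"), bg_isozyme("ppo"))
  expect_equal(n_loci(pooled), 27)
  expect_equal(genotypes(pooled), paste0("S", 1:10))
  expect_equal(table(pooled$loci$assay),
               table(c(rep("protein", 17), rep("isozyme", 10))))

  # identity on a single matrix
  same <- pool_bands(list(bg_protein()))
  expect_identical(same$presence, bg_protein()$presence)

  # label alignment: permuting a matrix's columns changes nothing
  pod <- collapse_intensity(bg_isozyme("pod"))
  perm <- band_matrix(pod$presence[, sample(10)], loci = pod$loci)
  a <- pool_bands(bg_protein(), pod)
  b <- pool_bands(bg_protein(), perm)
  expect_identical(a$presence, b$presence)

  # conflicting genotype sets are rejected, naming the mismatch
  other <- band_matrix(matrix(1, 1, 2, dimnames = list("z", c("S1", "SX"))))
  expect_error(pool_bands(bg_protein(), other), "genotype sets differ")
})

test_that("pool_bands is associative over the locus multiset", {
  a <- bg_protein(); b <- bg_isozyme("pod"); c <- bg_isozyme("ppo")
  left <- pool_bands(pool_bands(a, b), c)
  right <- pool_bands(a, pool_bands(b, c))
  expect_identical(left$presence, right$presence)
  expect_equal(left$loci, right$loci)
})
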