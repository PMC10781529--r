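test_that("locus_stats classifies the protein bands as published", {
  ls <- locus_stats(bg_protein())
  # 126 kDa band: present in all but S8
  b126 <- ls[ls$size == 126, ]
  expect_equal(b126$p, 0.9)
  expect_equal(b126$klass, "unique_negative")
  # 12 kDa band: absent in two genotypes -> polymorphic, not unique
  expect_equal(ls$klass[ls$size == 12], "polymorphic")
  expect_equal(sum(ls$klass == "monomorphic"), 12)
  expect_equal(sum(ls$klass != "monomorphic"), 5)
  expect_equal(ls$pic_locus, 2 * ls$p * (1 - ls$p))
})

test_that("locus_stats handles degenerate frequencies", {
  m <- rbind(all1 = rep(1L, 10), only1 = c(1L, rep(0L, 9)))
  colnames(m) <- paste0("G", 1:10)
  ls <- locus_stats(band_matrix(m))
  expect_equal(ls$p, c(1, 0.1))
  expect_equal(ls$klass, c("monomorphic", "unique_positive"))
})

test_that("locus_stats agrees with exhaustive per-column counting", {
  set.seed(11)
  for (trial in 1:25) {
    bm <- rand_band_matrix(sample(2:8, 1), sample(2:8, 1), runif(1, .3, .9))
    ls <- locus_stats(bm)
    n <- n_genotypes(bm)
    for (i in seq_len(n_loci(bm))) {
      cnt <- sum(bm$presence[i, ] == 1L)
      expect_equal(ls$p[i], cnt / n)
      expected <- if (cnt == n) "monomorphic" else
        if (cnt == 1) "unique_positive" else
        if (cnt == n - 1) "unique_negative" else "polymorphic"
      expect_equal(ls$klass[i], expected)
    }
  }
})

test_that("polymorphism_percent matches the published protein and isozyme values", {
  expect_equal(polymorphism_percent(bg_protein()), 29.41)
  iso <- pool_bands(bg_isozyme("pod"), bg_isozyme("ppo"))
  expect_equal(polymorphism_percent(iso, by_group = TRUE),
               c(POD = 20, PPO = 20))
  mono <- band_matrix(matrix(1, 3, 4, dimnames = list(letters[1:3],
                                                      LETTERS[1:4])))
  expect_equal(polymorphism_percent(mono), 0)
})

test_that("polymorphism_percent is invariant under row/column reordering", {
  set.seed(7)
  bm <- rand_band_matrix(12, 6, 0.6)
  ref <- polymorphism_percent(bm)
  perm <- band_matrix(bm$presence[sample(12), sample(6)])
  expect_equal(polymorphism_percent(perm), ref)
})

test_that("genotype_specific_markers recovers the published protein M- markers", {
  mk <- genotype_specific_markers(bg_protein())
  expect_equal(nrow(mk), 4)
  expect_true(all(mk$polarity == "negative"))
  expect_setequal(paste0(mk$genotype, "@", mk$size),
                  c("S8@126", "S8@100", "S6@23", "S2@11"))
})

test_that("genotype_specific_markers handles identity-like and monomorphic input", {
  m <- diag(1L, 4)
  dimnames(m) <- list(paste0("b", 1:4), paste0("G", 1:4))
  mk <- genotype_specific_markers(band_matrix(m))
  expect_equal(nrow(mk), 4)
  expect_true(all(mk$polarity == "positive"))
  expect_setequal(mk$genotype, paste0("G", 1:4))

  mono <- band_matrix(matrix(1, 2, 3, dimnames = list(c("a", "b"),
                                                      c("x", "y", "z"))))
  expect_equal(nrow(genotype_specific_markers(mono)), 0)
})

test_that("pic_group, emr_group and rp_group evaluate the standard formulas", {
  expect_equal(pic_group(c(1, 1, 1)), 0)
  expect_equal(pic_group(0.5), 0.5)
  expect_equal(pic_group(c(0.9, 0.1)), 0.18)
  expect_error(pic_group(numeric(0)), "empty")
  expect_error(pic_group(1.2), "\\[0, 1\\]")

  expect_equal(emr_group(5, 5), 5)
  expect_equal(emr_group(3, 0), 0)
  expect_equal(emr_group(11, 7), 7 * 7 / 11)
  expect_error(emr_group(0, 0), "positive")
  expect_error(emr_group(3, 4), "pbn")

  expect_equal(rp_group(c(1, 1, 1)), 0)
  expect_equal(rp_group(0.5), 1)
  expect_equal(rp_group(c(0.8, 0.5)), 1.4)
  expect_error(rp_group(numeric(0)), "empty")
})

test_that("primer_summary aggregates per group with exact identities", {
  # one group of 3 bands all fixed -> fully monomorphic primer
  m <- matrix(1L, 3, 10, dimnames = list(paste0("b", 1:3), paste0("G", 1:10)))
  ps <- primer_summary(band_matrix(m))
  expect_equal(ps[, c("tbn", "mbn", "pbn", "p_pct", "pic", "emr", "mi", "rp")],
               data.frame(tbn = 3, mbn = 3, pbn = 0, p_pct = 0, pic = 0,
                          emr = 0, mi = 0, rp = 0))

  # bands at p = {0.5, 1.0} -> pic is the mean of 2p(1-p): (0.5 + 0)/2
  m2 <- rbind(h = c(1L, 1L, 0L, 0L), f = c(1L, 1L, 1L, 1L))
  colnames(m2) <- paste0("G", 1:4)
  ps2 <- primer_summary(band_matrix(m2))
  expect_equal(ps2$pic, 0.25)

  # totals and averages rows
  pooled <- pool_bands(bg_protein(), bg_isozyme("pod"), bg_isozyme("ppo"))
  pt <- primer_summary(pooled, totals = TRUE)
  body <- pt[!pt$group %in% c("Total", "Average"), ]
  expect_equal(pt$tbn[pt$group == "Total"], sum(body$tbn))
  expect_equal(pt$pic[pt$group == "Average"], mean(body$pic))
  expect_equal(body$tbn, body$mbn + body$pbn)
})

test_that("mi = pic * emr and pic bounds hold on random matrices", {
  set.seed(23)
  for (trial in 1:20) {
    bm <- generate_bands(synth_spec(8, c(A = 6, B = 5, C = 4),
                                    freq = c(0.1, 0.9), seed = trial))
    ps <- primer_summary(bm)
    expect_equal(ps$mi, ps$pic * ps$emr)
    expect_true(all(ps$pic >= 0 & ps$pic <= 0.5))
    expect_true(all(ps$rp >= 0))
    # pic is permutation invariant
    s <- locus_stats(bm)
    expect_equal(pic_group(sample(s$p)), pic_group(s$p))
  }
})
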