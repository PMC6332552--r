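test_that("unrelated cohorts draw two pool haplotypes per individual", {
  pool <- test_pool()
  expect_equal(length(with_seed(1, generate_unrelated(pool, 0))$individuals),
               0L)
  pool2 <- test_pool(seed = 98)
  co <- with_seed(2, generate_unrelated(pool2, 600))
  expect_equal(length(co$individuals), 600L)
  expect_equal(pool_batches(pool2), 2L)   # 1200 haplotypes = second batch
  # founder origin ids are all distinct
  ids <- unlist(lapply(co$individuals,
                       function(i) c(i$track1$src, i$track2$src)))
  expect_equal(anyDuplicated(ids), 0L)
  # cohort allele frequencies match the model within binomial noise
  co2 <- with_seed(3, generate_unrelated(test_pool(seed = 97), 5000))
  G <- cohort_dosages(co2)
  p_hat <- colMeans(G) / 2
  p <- test_pool(seed = 97)$model$p
  se <- sqrt(p * (1 - p) / (2 * 5000))
  expect_true(all(abs(p_hat - p) <= 4 * se))
})

test_that("pedigree gene-dropping is Mendelian-consistent at every site", {
  pool <- test_pool()
  ped <- validate_pedigree(data.frame(
    fam = "f1", id = c("dad", "mum", "kid"),
    father = c("0", "0", "dad"), mother = c("0", "0", "mum"),
    sex = c(1, 2, 1)))
  co <- with_seed(4, simulate_pedigree(ped, pool))
  expect_equal(length(co$individuals), 3L)
  dad <- co$individuals[[1]]; mum <- co$individuals[[2]]
  kid <- co$individuals[[3]]
  # paternal gamete allele must exist in the father, maternal in the mother
  expect_true(all(
    (kid$gamete1 == dad$gamete1) | (kid$gamete1 == dad$gamete2)))
  expect_true(all(
    (kid$gamete2 == mum$gamete1) | (kid$gamete2 == mum$gamete2)))
})

test_that("IBD identities hold exactly for canonical relationships", {
  pool <- test_pool()
  ped <- validate_pedigree(data.frame(
    fam = "f1", id = c("dad", "mum", "c1", "c2"),
    father = c("0", "0", "dad", "dad"), mother = c("0", "0", "mum", "mum"),
    sex = c(1, 2, 1, 2)))
  for (s in c(11, 12, 13)) {
    co <- with_seed(s, simulate_pedigree(ped, pool,
                                         recomb_params("no_interference")))
    dad <- co$individuals[[1]]; mum <- co$individuals[[2]]
    kid <- co$individuals[[3]]
    po <- compute_pair_ibd12(dad, kid)
    expect_equal(po$ibd1, 1)            # parent-offspring: IBD1 everywhere
    expect_equal(po$ibd2, 0)
    expect_equal(compute_pair_ibd12(dad, mum)$ibd0, 1)   # two founders
    # self comparison (monozygotic duplicate): IBD2 everywhere
    expect_equal(compute_pair_ibd12(kid, kid)$ibd2, 1)
    sib <- compute_pair_ibd12(kid, co$individuals[[4]])
    expect_equal(sib$ibd0 + sib$ibd1 + sib$ibd2, 1, tolerance = 1e-12)
    expect_equal(sib$mean_ibd, sib$ibd2 + sib$ibd1 / 2)
  }
})

test_that("sibling IBD matches Mendelian expectations on average", {
  pool <- test_pool()
  ped <- validate_pedigree(data.frame(
    fam = "f1", id = c("p1", "p2", "c1", "c2"),
    father = c("0", "0", "p1", "p1"), mother = c("0", "0", "p2", "p2"),
    sex = c(1, 2, 1, 2)))
  set.seed(31)
  res <- replicate(400, {
    co <- simulate_pedigree(ped, pool)
    ib <- compute_pair_ibd12(co$individuals[[3]], co$individuals[[4]])
    c(ib$ibd1, ib$ibd2, ib$mean_ibd)
  })
  for (i in 1:3) {
    tgt <- c(0.5, 0.25, 0.5)[i]
    expect_lt(abs(mean(res[i, ]) - tgt), 3 * sd(res[i, ]) / sqrt(400))
  }
})

test_that("grandparent-grandchild mean IBD is 0.25 on average", {
  pool <- test_pool()
  set.seed(32)
  fams <- sim_three_gen_families(pool, 150)
  vals <- vapply(seq_len(150), function(f) {
    d <- fams$data[fams$data$family == f, ]
    B <- fams$B_list[[as.character(f)]]
    mean(B[which(d$generation == 1), which(d$generation == 3)])
  }, 0)  # family-level means: independent across families
  expect_lt(abs(mean(vals) - 0.25), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("three-generation families have 4 to 8 members across generations", {
  pool <- test_pool()
  set.seed(33)
  fams <- sim_three_gen_families(pool, 40)
  sizes <- table(fams$data$family)
  expect_true(all(sizes >= 4 & sizes <= 8))
  for (f in unique(fams$data$family)) {
    d <- fams$data[fams$data$family == f, ]
    expect_equal(sum(d$generation == 1), 2L)
    expect_true(sum(d$generation == 2) %in% 1:2)
    expect_true(sum(d$generation == 3) >= sum(d$generation == 2))
    B <- fams$B_list[[as.character(f)]]
    expect_true(all(B >= 0 & B <= 1))
    expect_equal(diag(B), rep(1, nrow(B)))
  }
  expect_equal(nrow(fams$G), nrow(fams$data))
})

test_that("cohorts export to dosages, IBD tables and back to VCF", {
  pool <- test_pool()
  ped <- validate_pedigree(data.frame(
    fam = "f1", id = c("a", "b", "k"), father = c("0", "0", "a"),
    mother = c("0", "0", "b"), sex = c(1, 2, 2)))
  co <- with_seed(5, simulate_pedigree(ped, pool))
  G <- cohort_dosages(co)
  expect_equal(dim(G), c(3L, 30L))
  expect_true(all(G %in% 0:2))
  tab <- compute_cohort_ibd(co)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$ibd1[tab$id1 == "f1:a" & tab$id2 == "f1:k"], 1)
  p <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(cohort_to_haplotypes(co), p)
  back <- read_phased_vcf(p)
  expect_equal(back$alleles[5, ], co$individuals[[3]]$gamete1)
  expect_equal(back$alleles[6, ], co$individuals[[3]]$gamete2)
})
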