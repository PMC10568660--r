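test_that("Hudson per-site components match hand values and the oracle", {
  # fixed difference: maximal differentiation
  comp <- hudson_fst_components(cbind(ref = 0L, alt = 10L),
                                cbind(ref = 10L, alt = 0L))
  expect_equal(comp$N, 1)
  expect_equal(comp$D, 1)
  expect_equal(comp$fst, 1)

  # hand-derived example: A = (8 ref, 2 alt), B = (3 ref, 7 alt)
  comp <- hudson_fst_components(cbind(8L, 2L), cbind(3L, 7L))
  expect_equal(comp$N, 0.25 - 0.2 * 0.8 / 9 - 0.7 * 0.3 / 9)
  expect_equal(comp$N, 0.208889, tolerance = 1e-5)
  expect_equal(comp$D, 0.62)
  expect_equal(comp$fst, 0.33692, tolerance = 1e-4)

  # identical monomorphic counts: D = 0, ratio masked
  comp <- hudson_fst_components(cbind(10L, 0L), cbind(10L, 0L))
  expect_lte(comp$N, 0)
  expect_equal(comp$D, 0)
  expect_true(is.na(comp$fst))

  # oracle equivalence on random small fixtures
  set.seed(42)
  for (rep in 1:20) {
    a <- cbind(sample(0:9, 15, TRUE) + 2L, sample(0:9, 15, TRUE))
    b <- cbind(sample(0:9, 15, TRUE) + 2L, sample(0:9, 15, TRUE))
    comp <- hudson_fst_components(a, b)
    for (s in 1:15) {
      o <- oracle_hudson_site(a[s, 1], a[s, 2], b[s, 1], b[s, 2])
      expect_equal(comp$N[s], unname(o["N"]), tolerance = 1e-12)
      expect_equal(comp$D[s], unname(o["D"]), tolerance = 1e-12)
    }
  }

  expect_error(hudson_fst_components(cbind(1L, 0L), cbind(5L, 5L)),
               "insufficient haplotypes")
})

test_that("windowed F_ST is a ratio of averages over contained sites", {
  comp <- hudson_fst_components(rbind(c(8L, 2L), c(0L, 10L)),
                                rbind(c(3L, 7L), c(10L, 0L)))
  # both sites in one window: (0.208889 + 1) / (0.62 + 1)
  w <- windowed_fst(comp, rep("2L", 2), c(100, 200), window_size = 1000)
  expect_equal(nrow(w), 1)
  expect_equal(w$value, 1.208889 / 1.62, tolerance = 1e-5)
  expect_equal(w$value, 0.74623, tolerance = 1e-4)
  expect_equal(w$n_variants, 2L)

  # single fixed-difference site alone in its window
  w1 <- windowed_fst(comp[2, ], "2L", 200, window_size = 1000)
  expect_equal(w1$value, 1)

  # empty window reported missing
  w2 <- windowed_fst(comp, rep("2L", 2), c(100, 2500), window_size = 1000)
  expect_true(is.na(w2$value[2]))
  expect_equal(w2$n_variants[2], 0L)
  expect_equal(w2$start, c(1, 1001, 2001))   # tiling, nonoverlapping
  expect_equal(w2$end, c(1000, 2000, 3000))
})

test_that("PBS matches hand evaluation, clips fixation, keeps symmetry", {
  expect_equal(pbs(0, 0, 0)$pbs, 0)

  res <- pbs(0.2, 0.3, 0.1)
  expect_equal(res$T_ab, -log(0.8))
  expect_equal(res$pbs, (0.223144 + 0.356675 - 0.105361) / 2,
               tolerance = 1e-5)
  expect_equal(res$pbs, 0.237229, tolerance = 1e-5)

  clipped <- pbs(1, 0.3, 0.1, eps = 1e-6)
  expect_true(is.finite(clipped$pbs))
  expect_true(clipped$clipped)

  # swapping the two non-focal groups leaves focal PBS unchanged:
  # (AB, AC, BC) -> (AC, AB, CB) with F symmetric
  set.seed(7)
  f_ab <- runif(20, 0, 0.6); f_ac <- runif(20, 0, 0.6)
  f_bc <- runif(20, 0, 0.6)
  expect_equal(pbs(f_ab, f_ac, f_bc)$pbs, pbs(f_ac, f_ab, f_bc)$pbs)

  w <- data.frame(chrom = "2L", start = 1, end = 10, value = 0.1)
  w2 <- data.frame(chrom = "2L", start = 11, end = 20, value = 0.1)
  expect_error(pbs(w, w2, w2), "not aligned")
})

test_that("pi and theta match hand formulas and brute force", {
  # one SNP, counts (5,5), n = 10, 1000-bp window
  sheet <- read_sample_sheet(write_sheet(
    data.frame(sampleID = paste0("s", 1:5), treatment = "g")))
  v <- cv_build("2L", 500, "A", "T", 50,
                list(c("0/1", "0/1", "0/1", "0/1", "0/1")),
                paste0("s", 1:5))
  d <- diversity(v, sheet, "g", window_size = 1000, n_boot = 10, seed = 1)
  expect_equal(d$windows$pi, (25 / 45) / 1000)
  expect_equal(d$windows$pi, 5.5556e-4, tolerance = 1e-4)
  expect_equal(d$windows$pi, oracle_pi(cbind(5, 5), 1000))

  # 5 segregating sites, n = 10, 1000-bp window
  geno <- rep(list(c("0/1", "0/1", "0/0", "0/0", "0/0")), 5)
  v5 <- cv_build("2L", seq(100, 500, 100), "A", "T", 50, geno,
                 paste0("s", 1:5))
  d5 <- diversity(v5, sheet, "g", window_size = 1000, n_boot = 10, seed = 1)
  expect_equal(d5$windows$S, 5)
  a9 <- sum(1 / (1:9))
  expect_equal(a9, 2.8289683, tolerance = 1e-7)
  expect_equal(d5$windows$theta_w, 5 / (a9 * 1000))
  expect_equal(d5$windows$theta_w, 1.7674e-3, tolerance = 1e-4)

  # monomorphic window
  vm <- cv_build("2L", 1, "A", "T", 50,
                 list(rep("0/0", 5)), paste0("s", 1:5))
  dm <- diversity(vm, sheet, "g", window_size = 1000, n_boot = 10, seed = 1)
  expect_equal(dm$windows$pi, 0)
  expect_equal(dm$windows$theta_w, 0)

  # brute-force oracle on random multiallelic fixtures
  set.seed(13)
  for (rep in 1:5) {
    cm <- matrix(sample(0:4, 8 * 3, TRUE), 8, 3)
    cm[, 1] <- cm[, 1] + 2L
    pi_pkg <- sum(apply(cm, 1, popscan:::site_pi), na.rm = TRUE) / 500
    expect_equal(pi_pkg, oracle_pi(cm, 500), tolerance = 1e-12)
  }
})

test_that("pi is invariant to relabeling samples within a group", {
  sim <- simulate_populations(sim_config(n_sites = 300, n_samples = 6,
                                         seed = 21))
  sheet <- sim$sheet
  d1 <- diversity(sim$variants, sheet, "pop1", n_boot = 10, seed = 2)
  perm <- sheet[c(sample(1:6), 7:12), ]
  class(perm) <- class(sheet)
  d2 <- diversity(sim$variants, perm, "pop1", n_boot = 10, seed = 2)
  expect_equal(d1$windows$pi, d2$windows$pi)
  expect_equal(d1$windows$theta_w, d2$windows$theta_w)
})

test_that("inbreeding coefficient hits its anchors and HW simulation", {
  sheet4 <- read_sample_sheet(write_sheet(
    data.frame(sampleID = paste0("s", 1:4), treatment = "g")))
  # everyone heterozygous, p = 0.5: H_obs = 1, H_exp = 0.5 -> F_IS = -1
  v <- cv_build("2L", 1, "A", "T", 50, list(rep("0/1", 4)), paste0("s", 1:4))
  expect_equal(inbreeding_coefficient(v, sheet4)$f_is, -1)

  # all homozygous alternate at a polymorphic-between-samples pair of sites
  v2 <- cv_build("2L", c(1, 2), "A", "T", 50,
                 list(c("1/1", "1/1", "0/0", "0/0"),
                      c("1/1", "1/1", "1/1", "0/0")),
                 paste0("s", 1:4))
  expect_equal(inbreeding_coefficient(v2, sheet4)$f_is, 1)

  # Hardy-Weinberg simulation: 1000 diploids at p = 0.3 -> F_IS ~ 0
  set.seed(99)
  n <- 1000L; L <- 60L
  gt <- array(NA_integer_, c(L, n, 2))
  gt[, , 1] <- rbinom(L * n, 1, 0.3)
  gt[, , 2] <- rbinom(L * n, 1, 0.3)
  sites <- data.frame(chrom = "2L", pos = 1:L, ref = "A", qual = 50)
  sites$alt <- as.list(rep("T", L))
  vhw <- called_variants(sites, gt, paste0("s", 1:n))
  shw <- read_sample_sheet(write_sheet(
    data.frame(sampleID = paste0("s", 1:n), treatment = "g")))
  expect_equal(inbreeding_coefficient(vhw, shw)$f_is, 0, tolerance = 0.05)

  vmono <- cv_build("2L", 1, "A", "T", 50, list(rep("0/0", 4)),
                    paste0("s", 1:4))
  expect_warning(res <- inbreeding_coefficient(vmono, sheet4), "monomorphic")
  expect_true(is.na(res$f_is))
})

test_that("per-gene F_ST averages, ranks and flags the top percentile", {
  genes1 <- data.frame(gene_id = "g1", chrom = "2L", start = 150, end = 250)
  comp <- hudson_fst_components(cbind(0L, 10L), cbind(10L, 0L))
  gs <- per_gene_fst(comp, "2L", 200, genes1)
  expect_equal(gs$fst, 1)
  expect_equal(gs$percentile, 100)
  expect_true(gs$top_flag)

  # 100 genes with distinct constructed values: exactly 5 flagged at 5%
  n <- 100
  set.seed(3)
  comp100 <- structure(
    data.frame(N = sample(seq(0.005, 0.5, length.out = n)), D = 1,
               fst = NA, masked = FALSE),
    class = c("hudson_components", "data.frame"))
  comp100$fst <- comp100$N / comp100$D
  genes <- data.frame(gene_id = paste0("g", 1:n), chrom = "2L",
                      start = (1:n) * 1000, end = (1:n) * 1000 + 500)
  gs100 <- per_gene_fst(comp100, rep("2L", n), (1:n) * 1000 + 100, genes)
  expect_equal(length(unique(gs100$fst)), n)   # distinct by construction
  expect_equal(sum(gs100$top_flag), 5)
  expect_true(all(gs100$percentile >= 0 & gs100$percentile <= 100))
  expect_setequal(which(gs100$top_flag), order(gs100$fst, decreasing = TRUE)[1:5])

  # a gene with no variants gets NA and no flag
  genes_nv <- rbind(genes1, data.frame(gene_id = "g2", chrom = "2L",
                                       start = 5000, end = 6000))
  gs2 <- per_gene_fst(comp, "2L", 200, genes_nv)
  expect_true(is.na(gs2$fst[2]))
  expect_false(gs2$top_flag[2])
  expect_true(is.na(gs2$percentile[2]))
})

test_that("Balding-Nichols F is recovered and F_ST is monotone in F", {
  # moderate-size check (the full acceptance grid runs in test-acceptance)
  med <- sapply(c(0.02, 0.1, 0.25), function(f) {
    sim <- simulate_populations(sim_config(n_sites = 4000, n_samples = 20,
                                           f_target = f, seed = 17))
    gac <- group_allele_counts(sim$variants, sim$sheet)
    bac <- biallelic_counts(gac)
    comp <- hudson_fst_components(bac$pop1, bac$pop2)
    gw <- sum(comp$N, na.rm = TRUE) / sum(comp$D, na.rm = TRUE)
    w <- windowed_fst(comp, sim$variants$sites$chrom, sim$variants$sites$pos)
    c(gw = gw, med = median(w$value, na.rm = TRUE), f = f)
  })
  expect_true(all(abs(med["gw", ] - c(0.02, 0.1, 0.25)) < 0.02))
  expect_true(all(diff(med["med", ]) > 0))   # strictly increasing medians
})
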