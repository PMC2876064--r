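# enumeration oracle for the two-sided Fisher test on a 2x2 table
o_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  sum(probs[probs <= stats::dhyper(a, c1, n - c1, r1) * (1 + 1e-7)])
}

test_that("pathway frequency is the fraction of taxa possessing the pathway", {
  taxa <- list(t1 = list(P1 = "m", P2 = "m"), t2 = list(P1 = "m"),
               t3 = list(P1 = "m"), t4 = list(P3 = "m"))
  expect_equal(pathway_frequency(taxa, "P1"), 0.75)
  expect_equal(pathway_frequency(taxa, "P9"), 0)
  expect_equal(pathway_frequency(taxa[1:3], "P1"), 1)
  expect_error(pathway_frequency(list(), "P1"), "empty")
  # NIP graphs work too
  nips <- list(a = k4_nip(), b = k4_nip())
  expect_equal(pathway_frequency(nips, "P1"), 1)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  for (seed in 1:12) {
    set.seed(seed)
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact(tab), o_fisher(tab), tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)),
               o_fisher(matrix(c(10, 0, 0, 10), 2)), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("Mann-Whitney agrees with rank enumeration and a permutation oracle", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 1 / 3, tolerance = 1e-12)

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-6)

  # permutation oracle, moderate n
  set.seed(30)
  x <- stats::rnorm(15); y <- stats::rnorm(15, 0.8)
  obs <- mann_whitney(x, y)
  pool <- c(x, y)
  nperm <- 20000
  ustat <- function(a, b) sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b),
                                     numeric(1)))
  u_obs <- ustat(x, y)
  mid <- length(x) * length(y) / 2
  count <- 0
  for (i in seq_len(nperm)) {
    idx <- sample(30, 15)
    u <- ustat(pool[idx], pool[-idx])
    if (abs(u - mid) >= abs(u_obs - mid) - 1e-9) count <- count + 1
  }
  p_perm <- count / nperm
  expect_lt(abs(obs$p_value - p_perm), 4 * sqrt(p_perm * (1 - p_perm) / nperm) + 0.005)
})

test_that("Kruskal-Wallis matches the hand rank formula and handles ties", {
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1))),
               list(H = 0, p_value = 1))
  # no ties: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  samples <- list(c(1, 2), c(3, 4), c(5, 6))
  rbar <- c(1.5, 3.5, 5.5)
  H <- 12 / (6 * 7) * sum(2 * (rbar - 3.5)^2)
  kw <- kruskal_wallis(samples)
  expect_equal(kw$H, H, tolerance = 1e-12)
  expect_equal(kw$p_value, stats::pchisq(H, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1)), "2 non-empty")
})

test_that("multiple-testing corrections follow their definitions", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  for (seed in 1:5) {
    set.seed(seed)
    p <- stats::runif(20)
    bh <- adjust_pvalues(p, "bh")
    bf <- adjust_pvalues(p, "bonferroni")
    expect_true(all(bh >= p - 1e-12))
    expect_true(all(bf >= p - 1e-12))
    expect_true(all(bh <= bf + 1e-12))
    expect_true(all(bh <= 1) && all(bf <= 1))
    # BH step-up by hand on the sorted vector
    ps <- sort(p)
    hand <- rev(cummin(rev(ps * 20 / seq_len(20))))
    expect_equal(sort(bh), pmin(1, hand), tolerance = 1e-12)
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

planted_groups <- function(seed = 101, n_per_group = 15, boost = 5) {
  # group B lipid pathways gain `boost` extra shared metabolites
  set.seed(seed)
  cats <- c(P1 = "lipid", P2 = "lipid", P3 = "other", P4 = "other",
            P5 = "other", P6 = "other")
  base <- function(extra_lipid) {
    hubs <- sprintf("h%d", 1:4)
    pw <- list(
      P1 = c("a1", hubs[1], if (extra_lipid) sprintf("x%d", 1:boost)),
      P2 = c("a2", hubs[1], hubs[2], if (extra_lipid) sprintf("x%d", 1:boost)),
      P3 = c("a3", hubs[2], hubs[3]),
      P4 = c("a4", hubs[3]),
      P5 = c("a5", hubs[4], hubs[1]),
      P6 = c("a6", hubs[4]))
    pw
  }
  make_group <- function(extra) {
    lapply(seq_len(n_per_group), function(i) {
      pw <- base(extra)
      # jitter: drop one random non-lipid pathway sometimes
      if (stats::runif(1) < 0.5) pw[[sample(3:6, 1)]] <- NULL
      # per-taxon private metabolite keeps scores non-identical
      pw[[sample(seq_along(pw), 1)]] <-
        c(pw[[sample(seq_along(pw), 1)]], sprintf("p%d", i))
      build_nip(pw, categories = cats)
    })
  }
  a <- make_group(FALSE); b <- make_group(TRUE)
  names(a) <- sprintf("a%02d", seq_along(a))
  names(b) <- sprintf("b%02d", seq_along(b))
  list(a = a, b = b, cats = cats)
}

test_that("planted lipid strength shift is flagged with the right direction", {
  pg <- planted_groups()
  res <- compare_pathways(pg$a, pg$b, categories = pg$cats,
                          group_a = "ctl", group_b = "boosted")
  lipid <- res$categories[res$categories$category == "lipid" &
                            res$categories$score_name == "strength", ]
  expect_equal(lipid$direction, "increase")
  expect_lt(lipid$median_fdr, 0.05)
  expect_true(all(res$comparisons$fdr >= res$comparisons$p_value - 1e-12))
})

test_that("identical groups show no pathway shifts", {
  pg <- planted_groups()
  res <- suppressMessages(compare_pathways(pg$a, pg$a, categories = pg$cats))
  expect_true(all(res$comparisons$fdr >= 0.9))
  expect_true(all(res$comparisons$amplitude == 0))
  expect_true(all(res$categories$direction == "none"))
})

test_that("swapping groups negates amplitudes and keeps p-values", {
  pg <- planted_groups()
  r1 <- compare_pathways(pg$a, pg$b, categories = pg$cats)
  r2 <- compare_pathways(pg$b, pg$a, categories = pg$cats)
  m1 <- r1$comparisons[order(r1$comparisons$pathway_id,
                             r1$comparisons$score_name), ]
  m2 <- r2$comparisons[order(r2$comparisons$pathway_id,
                             r2$comparisons$score_name), ]
  expect_equal(m1$amplitude, -m2$amplitude, tolerance = 1e-12)
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-12)
})

test_that("descriptor-level group tests flag a planted shift only", {
  set.seed(77)
  n <- 40
  desc <- data.frame(taxon_id = sprintf("t%02d", 1:n),
                     matrix(stats::rnorm(n * 6), n, 6), check.names = FALSE)
  names(desc)[-1] <- sprintf("D%d", 1:6)
  g <- rep(c("x", "y"), each = n / 2)
  desc$D3 <- desc$D3 + 5 * (g == "y")
  out <- compare_descriptors(desc, g)
  expect_lt(out$p_bonferroni[out$descriptor_id == "D3"], 0.01)
  expect_gte(out[["mean_y"]][out$descriptor_id == "D3"],
             out[["mean_x"]][out$descriptor_id == "D3"] + 4)
  # identical copied groups: all tests at p = 1
  desc2 <- rbind(desc[1:20, ], desc[1:20, ])
  out2 <- compare_descriptors(desc2, rep(c("x", "y"), each = 20))
  expect_true(all(out2$p_value > 0.99))
  expect_error(compare_descriptors(desc, rep("x", n)), "2 groups")
})
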