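test_that("rank curves filter at the cutoff and sort ascending deterministically", {
  recs <- binding_df(c(200, 30, 99))
  s <- rank_ic50_curve(recs, 100)
  expect_equal(s$rank, 1:2)
  expect_equal(s$ic50_nM, c(30, 99))
  expect_equal(nrow(rank_ic50_curve(binding_df(c(150, 5000)), 100)), 0L)
  # large simulated series: sort oracle and contiguous ranks
  set.seed(71)
  big <- binding_df(10^runif(1000, 0, 3))
  s2 <- rank_ic50_curve(big, 100)
  keep <- big$ic50_nM[big$ic50_nM <= 100]
  expect_equal(s2$ic50_nM, keep[order(keep)])
  expect_equal(s2$rank, seq_along(keep))
  # ties broken by (peptide, allele): reordering the input changes nothing
  tied <- binding_df(rep(50, 6), peptide = c("C", "A", "B", "F", "E", "D"))
  expect_equal(rank_ic50_curve(tied, 100),
               rank_ic50_curve(tied[sample(6), ], 100))
})

test_that("quadratic fits recover generating polynomials", {
  const <- data.frame(rank = 1:10, ic50_nM = 7)
  f <- fit_quadratic(const)
  expect_equal(unname(f$coefficients), c(0, 0, 7))
  expect_equal(f$rmse, 0)
  x <- 1:50
  gen <- data.frame(rank = x, ic50_nM = 0.02 * x^2 + 0.5 * x + 3)
  f2 <- fit_quadratic(gen)
  expect_equal(unname(f2$coefficients), c(0.02, 0.5, 3), tolerance = 1e-8)
  expect_lt(f2$rmse, 1e-8)
  lin <- data.frame(rank = x, ic50_nM = 2 * x)
  f3 <- fit_quadratic(lin)
  expect_equal(unname(f3$coefficients), c(0, 2, 0), tolerance = 1e-8)
  expect_error(fit_quadratic(const[1:2, ]), "at least 3")
})

test_that("closed-form integration matches the hand antiderivative", {
  expect_equal(integrate_curve(0, 0, 3, 1, 11), 30)
  # the worked definite integral of 0.02x^2 + 0.5x + 3 over [1, 50]
  hand <- 0.02 * (50^3 - 1) / 3 + 0.5 * (50^2 - 1) / 2 + 3 * 49
  expect_equal(integrate_curve(0.02, 0.5, 3, 1, 50), hand)
  expect_equal(round(hand, 2), 1605.08)
  expect_equal(integrate_curve(1, 2, 3, 4, 4), 0)
  expect_error(integrate_curve(0, 0, 1, 5, 4), "a <= b")
})

test_that("alloreactivity potential composes rank, fit and integral", {
  # empty and degenerate inputs
  empty <- compute_alloreactivity_potential(binding_df(numeric(0)))
  expect_equal(empty$auc, 0)
  expect_equal(empty$n_points, 0L)
  expect_true(empty$fallback)
  # constant series: AUC = c * (N - 1), exactly the trapezoid area
  const <- compute_alloreactivity_potential(binding_df(rep(50, 10)))
  expect_equal(const$auc, 50 * 9)
  expect_false(const$fallback)
  two <- compute_alloreactivity_potential(binding_df(c(10, 20)))
  expect_true(two$fallback)
  expect_equal(two$auc, 15)  # trapezoid over two points
  # records sampled from a known quadratic rank curve recover its integral
  x <- 1:80
  gen_ic50 <- 0.012 * x^2 + 0.1 * x + 2   # max ~ 87 < 100 cutoff keeps all
  res <- compute_alloreactivity_potential(binding_df(sample(gen_ic50)))
  analytic <- integrate_curve(0.012, 0.1, 2, 1, 80)
  expect_lt(abs(res$auc - analytic) / analytic, 0.01)
  # AUC equals the closed-form evaluation of its own coefficients
  cf <- res$coefficients
  expect_equal(res$auc,
               integrate_curve(cf[["c2"]], cf[["c1"]], cf[["c0"]], res$a, res$b))
  # quadratic-fit AUC stays within the sanity band of the trapezoid area
  set.seed(81)
  noisy <- binding_df(sort(gen_ic50 + rnorm(80, 0, 1)))
  rn <- compute_alloreactivity_potential(noisy)
  s <- rank_ic50_curve(noisy, 100)
  trap <- sum(diff(s$rank) * (head(s$ic50_nM, -1) + tail(s$ic50_nM, -1)) / 2)
  expect_lt(abs(rn$auc - trap), 3 * rn$fit_rmse * (rn$b - rn$a) + 1e-9)
})

test_that("expression weighting sums Re/IC50 with unmapped genes contributing zero", {
  expr <- structure(data.frame(gene = c("G1", "G2"), liver = c(10, 0),
                               lung = c(2, 5), stringsAsFactors = FALSE),
                    class = c("expression_table", "data.frame"))
  one <- binding_df(100, gene = "G1")
  expect_equal(weighted_potential(one, expr, "liver")$value, 0.1)
  zero <- binding_df(c(10, 20), gene = "G2")
  expect_equal(weighted_potential(zero, expr, "liver")$value, 0)
  expect_error(weighted_potential(one, expr, "muscle"), "liver")
  # 20-record fixture vs spreadsheet-style manual accumulation
  set.seed(91)
  recs <- binding_df(10^runif(20, 0, 3), gene = sample(c("G1", "G2", "G9"), 20, TRUE))
  wp <- weighted_potential(recs, expr, "lung")
  manual <- 0
  for (i in 1:20) {
    re <- c(G1 = 2, G2 = 5)[recs$gene[i]]
    manual <- manual + ifelse(is.na(re), 0, re) / recs$ic50_nM[i]
  }
  expect_equal(wp$value, unname(manual))
  expect_equal(wp$n_unmapped, sum(recs$gene == "G9"))
})

test_that("power-law fits recover generating exponents", {
  # noise-free: 1/ic50 = C * rank^-1.5
  r <- 1:200
  ic50 <- 1 / (0.5 * r^(-1.5))
  f <- fit_power_law(ic50)
  expect_equal(f$exponent, -1.5, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # constant affinity: exponent 0
  expect_equal(fit_power_law(rep(100, 10))$exponent, 0)
  expect_error(fit_power_law(c(1, 2)), "at least 3")
  # multiplicative lognormal noise, sigma = 0.1 in log10, n = 500
  set.seed(101)
  r2 <- 1:500
  noisy <- 1 / (0.2 * r2^(-1.5) * 10^rnorm(500, 0, 0.1))
  f2 <- fit_power_law(noisy)
  expect_lt(abs(f2$exponent - (-1.5)), 0.1)
  # scale covariance: scaling all ic50 by k shifts only the intercept
  f3 <- fit_power_law(noisy * 100)
  expect_equal(f3$exponent, f2$exponent, tolerance = 1e-9)
  expect_equal(f3$intercept, f2$intercept - 2, tolerance = 1e-9)
})

test_that("the exact Mann-Whitney U test matches complete enumeration", {
  # complete separation at sizes 4 vs 5: U = 20, p = 2/126
  a <- c(10, 11, 12, 13); b <- c(1, 2, 3, 4, 5)
  mw <- exact_mann_whitney(a, b)
  expect_equal(mw$u_statistic, 20)
  expect_equal(mw$p_two_sided, 2 / 126)
  expect_equal(mw$method, "exact")
  expect_equal(round(mw$p_two_sided, 3), 0.016)
  # U = 18 at sizes 4 vs 5: p = 2 * 4/126
  a18 <- c(3.5, 11, 12, 13)  # one a-value below two b-values
  b18 <- c(1, 2, 3, 4, 5)
  mw18 <- exact_mann_whitney(a18, b18)
  expect_equal(mw18$u_statistic, 18)
  expect_equal(mw18$p_two_sided, 8 / 126)
  # identical tied groups: no separation, tie-corrected path, p = 1
  mwt <- exact_mann_whitney(c(1, 2), c(1, 2))
  expect_equal(mwt$method, "normal_approx")
  expect_equal(mwt$u_statistic, 2)
  expect_equal(mwt$p_two_sided, 1.0)
  expect_error(exact_mann_whitney(numeric(0), 1), "non-empty")
})

test_that("the enumerated U null distribution is a symmetric probability law", {
  set.seed(111)
  for (sizes in list(c(3, 4), c(4, 5), c(5, 5))) {
    x <- sample(1000, sum(sizes))  # distinct values, no ties
    mw <- exact_mann_whitney(x[seq_len(sizes[1])], x[-seq_len(sizes[1])])
    nd <- mw$null_distribution
    expect_equal(sum(nd$p), 1)
    expect_true(all(nd$u >= 0 & nd$u <= prod(sizes)))
    # symmetry about nA*nB/2
    expect_equal(nd$p, rev(nd$p))
    # cross-check against the independent reference implementation
    wt <- suppressWarnings(stats::wilcox.test(x[seq_len(sizes[1])],
                                              x[-seq_len(sizes[1])],
                                              exact = TRUE))
    expect_equal(mw$u_statistic, unname(wt$statistic))
    expect_equal(mw$p_two_sided, wt$p.value)
  }
})

test_that("large or tied samples use the tie-corrected normal approximation", {
  set.seed(121)
  a <- rnorm(30); b <- rnorm(25, 0.8)
  mw <- exact_mann_whitney(a, b)
  expect_equal(mw$method, "normal_approx")
  wt <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE, exact = FALSE))
  expect_equal(mw$u_statistic, unname(wt$statistic))
  expect_equal(mw$p_two_sided, wt$p.value, tolerance = 1e-10)
})

test_that("cohort summaries reproduce medians, ranges and order invariance", {
  tab <- reference_pair_counts()
  s <- summarize_counts(tab)
  med <- function(stat) s$aggregates$median[s$aggregates$statistic == stat]
  expect_equal(med("smm_presented"), 18396)
  expect_equal(med("smm_strong"), 2254)
  expect_equal(med("pan_presented"), 3962)
  expect_equal(med("pan_strong"), 989)
  expect_equal(med("shared_presented"), 2065)
  rng <- s$aggregates[s$aggregates$statistic == "smm_presented", ]
  expect_equal(c(rng$min, rng$max), c(1926, 72294))
  # medians equal an explicit sort-and-index oracle
  for (cc in c("smm_presented", "pan_strong", "shared_presented")) {
    v <- sort(tab[[cc]])
    expect_equal(med(cc), v[(length(v) + 1) / 2])
  }
  # row order invariance
  s2 <- summarize_counts(tab[sample(nrow(tab)), ])
  expect_equal(s2$aggregates[order(s2$aggregates$statistic), ],
               s$aggregates[order(s$aggregates$statistic), ],
               ignore_attr = TRUE)
  # single pair: degenerate range
  s1 <- summarize_counts(tab[1, ])
  expect_equal(s1$aggregates$min, s1$aggregates$max)
  # strongly presented never exceeds presented in any row
  expect_true(all(tab$smm_strong <= tab$smm_presented))
  expect_true(all(tab$pan_strong <= tab$pan_presented))
})

test_that("record-level summaries agree with direct counting and locus tallies", {
  set.seed(131)
  mk <- function(n, seedoff) {
    peps <- random_peptides(n)
    alleles <- sample(c("HLA-A*01:01", "HLA-B*08:01", "HLA-C*07:01"), n, TRUE)
    data.frame(peptide = peps, allele = alleles,
               ic50_nM = 10^runif(n, 0, 4), gene = "G1",
               stringsAsFactors = FALSE)
  }
  pairs <- list(p1 = list(smm = mk(60), pan = mk(50), n_nssnp = 10),
                p2 = list(smm = mk(40), pan = mk(45), n_nssnp = 12))
  s <- summarize_counts(pairs, donor_types = c(p1 = "MRD", p2 = "URD"))
  for (i in 1:2) {
    p <- pairs[[i]]; row <- s$rows[i, ]
    dd <- deduplicate_complexes(p$smm)
    expect_equal(row$smm_presented, sum(dd$ic50_nM < 500))
    expect_equal(row$smm_strong, sum(dd$ic50_nM < 50))
    expect_gte(row$smm_presented, row$smm_strong)
    expect_equal(row$shared_presented, nrow(shared_complexes(p$smm, p$pan)))
  }
  expect_equal(sum(s$per_locus$n_presented),
               sum(s$rows$smm_presented) + sum(s$rows$pan_presented))
})
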