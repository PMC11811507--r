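test_that("Mann-Whitney exact branch matches hand-enumerated cases", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)           # 2 * 1/20 over all C(6,3) assignments
  expect_equal(r$method, "exact")

  r <- mann_whitney(c(1, 4), c(2, 3))
  expect_equal(r$U, 2)             # centre of the U distribution
  expect_equal(r$p, 1)
  expect_false(r$degenerate)
})

test_that("degenerate pooled samples are flagged with p = 1", {
  r <- mann_whitney(c(2, 2, 2), c(2, 2))
  expect_equal(r$p, 1)
  expect_true(r$degenerate)
  k <- ks_two_sample(c(2, 2, 2), c(2, 2))
  expect_equal(k$D, 0)
  expect_equal(k$p, 1)
  expect_true(k$degenerate)
})

test_that("ties and large samples fall back to the corrected approximation", {
  r <- mann_whitney(c(1, 2, 2, 3), c(2, 4, 5))
  expect_equal(r$method, "normal_approx")
  r <- mann_whitney(rnorm(13), rnorm(13))
  expect_equal(r$method, "normal_approx")
  k <- ks_two_sample(rnorm(5), rnorm(13))
  expect_equal(k$method, "asymptotic")
})

test_that("KS statistic equals the ECDF supremum distance", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  r <- ks_two_sample(c(1, 3, 5), c(2, 4, 6))
  expect_equal(r$D, 1 / 3)
  expect_equal(r$p, perm_ks_pvalue(c(1, 3, 5), c(2, 4, 6)))
})

test_that("exact MW and KS p-values equal permutation enumeration (n <= 6)", {
  set.seed(101)
  for (rep in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(runif(n1), 6); y <- round(runif(n2), 6)
    if (anyDuplicated(c(x, y))) next
    expect_equal(mann_whitney(x, y)$p, perm_mw_pvalue(x, y),
                 tolerance = 1e-12)
    expect_equal(ks_two_sample(x, y)$p, perm_ks_pvalue(x, y),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up formula and its properties", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0, 0, 0)), c(0, 0, 0))
  expect_error(bh_adjust(c(0.1, 1.2)), "position 2")
  expect_error(bh_adjust(c(0.1, NA)), "position 2")

  set.seed(7)
  for (rep in 1:20) {
    p <- runif(sample(3:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # permutation invariance
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o]), adj[o], tolerance = 1e-14)
  }
})

test_that("screening classifies planted metabolites as specific and shared", {
  cfg <- panel_sim_config(effect_metabolites_A = c("Ala", "Pro"),
                          effect_metabolites_B = c("Pro", "Val"),
                          log_fold_shift = 2, cv = 0.3, seed = 20)
  res <- screen_panel(simulate_panel(cfg))
  cl <- res$classification
  expect_equal(cl$category[cl$metabolite == "Ala"], "diseaseA_specific")
  expect_equal(cl$category[cl$metabolite == "Val"], "diseaseB_specific")
  expect_equal(cl$category[cl$metabolite == "Pro"], "shared")
  # classification partitions the panel
  expect_equal(nrow(cl), 44L)
  expect_true(all(cl$category %in% c("diseaseA_specific", "diseaseB_specific",
                                     "shared", "none")))
  # flags and classification agree
  sig <- significant_metabolites(res)
  expect_setequal(cl$metabolite[cl$category == "shared"], sig$shared)
})

test_that("screening output table is internally consistent", {
  res <- screen_panel(simulate_study_panel(seed = 2))
  tab <- res$table
  expect_equal(nrow(tab), 88L)  # 44 metabolites x 2 contrasts
  expect_true(all(tab$p_mw >= 0 & tab$p_mw <= 1))
  expect_true(all(tab$q_mw >= tab$p_mw - 1e-15))
  expect_true(all(tab$q_ks >= tab$p_ks - 1e-15))
  expect_true(all(tab$D >= 0 & tab$D <= 1))
  expect_true(all(tab$n_case == 9 & tab$n_control == 17))
  expect_true(all(tab$mw_method == "exact"))      # n = 9 <= 12, no ties
  expect_true(all(tab$ks_method == "asymptotic")) # control n = 17 > 12
})

test_that("combination rules nest as expected", {
  p <- simulate_study_panel(seed = 3)
  n_sig <- function(rule)
    sum(screen_panel(p, rule = rule)$table$significant)
  expect_lte(n_sig("both"), n_sig("mw_only"))
  expect_lte(n_sig("both"), n_sig("ks_only"))
  expect_lte(n_sig("mw_only"), n_sig("either"))
  expect_lte(n_sig("ks_only"), n_sig("either"))
})

test_that("screening requires a control group", {
  mat <- matrix(runif(20, 1, 2), 5,
                dimnames = list(paste0("s", 1:5), c("Ala", "Pro", "C2", "C4")))
  expect_error(metabolite_profiles(mat, rep("diseaseA", 5)), "control")
})

test_that("missing values are excluded pairwise per metabolite", {
  cfg <- panel_sim_config(seed = 31)
  p <- simulate_panel(cfg)
  p$concentrations[1, "Ala"] <- NA  # sample 1 is diseaseA
  res <- screen_panel(p)
  tab <- res$table
  expect_equal(tab$n_case[tab$metabolite == "Ala" & tab$disease == "diseaseA"], 8L)
  expect_equal(tab$n_case[tab$metabolite == "Pro" & tab$disease == "diseaseA"], 9L)
})
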