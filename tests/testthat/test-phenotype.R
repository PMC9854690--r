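test_that("final model reproduces the hand-derived least-squares fit", {
  # points (bc, y) = (2,1),(3,1),(4,2),(5,2): Sxy = 2, Sxx = 5
  ph <- pheno_table(bc = c(2, 3, 4, 5), fec = c(1, 1, 2, 2))
  fit <- fit_final_model(ph)
  expect_equal(fit$beta1, 0.4, tolerance = 1e-12)
  expect_equal(fit$beta0, 0.1, tolerance = 1e-12)
  # fitted: 0.9, 1.3, 1.7, 2.1 -> rounded 1,1,2,2 -> accuracy 1
  expect_identical(fit$accuracy, 1)
  expect_equal(unname(coef(fit)), c(0.1, 0.4), tolerance = 1e-12)
})

test_that("constant body condition falls back to an intercept-only model", {
  ph <- pheno_table(bc = rep(3, 5), fec = c(1, 1, 2, 1, 0))
  expect_warning(fit <- fit_final_model(ph), "constant")
  expect_equal(fit$beta0, mean(ph$fecundity))
  expect_identical(fit$beta1, 0)
})

test_that("model accuracy approaches 1 as liability noise vanishes", {
  # targets must be reachable by a deterministic step function of body
  # condition at noise 0: low bc {1,2} -> all singles (mean 1.0); high bc
  # {4,5} with probs (0.6, 0.4) -> twins iff bc = 5 (mean 1.4)
  cfg <- small_sim_config(seed = 23, noise_sd = 1e-4,
                          pheno_means = c(high = 1.4, low = 1.0))
  ph <- simulate_population(cfg)$phenotypes
  fit <- fit_final_model(ph)
  expect_gte(fit$accuracy, 0.95)
})

test_that("final-model residuals are orthogonal to the design", {
  ph <- pheno_table(bc = c(1, 2, 2, 3, 4, 5, 5), fec = c(0, 1, 1, 1, 2, 2, 1))
  fit <- fit_final_model(ph)
  r <- residuals(fit)
  expect_lt(abs(sum(r)), 1e-8)
  expect_lt(abs(sum(r * ph$body_condition)), 1e-8)
})

test_that("Wald screen flags the true covariate and matches the normal-tail identity", {
  set.seed(31)
  n <- 200
  ph <- data.frame(id = sprintf("E%03d", 1:n),
                   year = sample(2019:2021, n, TRUE),
                   age = rnorm(n, 4.5, 1.3),
                   body_condition = sample(1:5, n, TRUE),
                   hours_estrus = rnorm(n, 30, 6),
                   n_births = rpois(n, 3),
                   stringsAsFactors = FALSE)
  ph$fecundity <- pmin(2, pmax(0, round(0.2 + 0.3 * ph$body_condition +
                                          rnorm(n, 0, 0.3))))
  sc <- screen_covariates(ph)
  expect_true("body_condition" %in% sc$retained)
  # Wald p on 1 df == two-sided normal tail of the z statistic
  z <- sc$coefficients$estimate / sc$coefficients$se
  expect_equal(sc$coefficients$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("screening retains the true covariate always, null covariates near 5%", {
  retained_bc <- 0
  null_hits <- c(year = 0, age = 0, hours_estrus = 0, n_births = 0)
  n_seed <- 100
  for (s in seq_len(n_seed)) {
    set.seed(1000 + s)
    n <- 200
    ph <- data.frame(id = sprintf("E%03d", 1:n),
                     year = sample(2019:2021, n, TRUE),
                     age = rnorm(n, 4.5, 1.3),
                     body_condition = sample(1:5, n, TRUE),
                     hours_estrus = rnorm(n, 30, 6),
                     n_births = rpois(n, 3),
                     stringsAsFactors = FALSE)
    ph$fecundity <- pmin(2, pmax(0, round(0.2 + 0.3 * ph$body_condition +
                                            rnorm(n, 0, 0.3))))
    sc <- screen_covariates(ph)
    retained_bc <- retained_bc + ("body_condition" %in% sc$retained)
    for (v in names(null_hits))
      null_hits[v] <- null_hits[v] + (v %in% sc$retained)
  }
  expect_identical(retained_bc, n_seed)
  expect_true(all(null_hits / n_seed < 0.15))
})

test_that("constant and collinear covariates are dropped with warnings", {
  ph <- pheno_table(bc = c(1, 2, 3, 4, 5, 3), fec = c(0, 1, 1, 2, 2, 1))
  ph$age <- 4  # constant
  expect_warning(sc <- screen_covariates(ph, covariates = c("body_condition", "age")),
                 "constant")
  expect_false("age" %in% sc$coefficients$term)
  ph2 <- pheno_table(bc = c(1, 2, 3, 4, 5, 3), fec = c(0, 1, 1, 2, 2, 1))
  ph2$age <- ph2$body_condition * 2  # aliased
  expect_warning(sc2 <- screen_covariates(ph2, covariates = c("body_condition", "age")),
                 "aliased|collinear")
})

test_that("Welch t-test matches hand computation and the reference implementation", {
  # A = {1,1,2}, B = {1,1,1}: varB = 0, t = (4/3 - 1)/sqrt((1/3)/3) = 1
  w <- welch_t_test(c(1, 1, 2), c(1, 1, 1))
  expect_equal(w$t, 1, tolerance = 1e-12)
  expect_equal(w$df, 2, tolerance = 1e-12)

  ident <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_identical(ident$t, 0)
  expect_identical(ident$p, 1)

  set.seed(12)
  for (i in 1:100) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    ref <- t.test(a, b)
    w <- welch_t_test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("clustering separates well-separated adjusted values and orients labels", {
  adj <- setNames(c(1.0, 1.0, 2.0, 2.0), c("a", "b", "c", "d"))
  gr <- assign_groups(adj)
  expect_identical(gr$assignments$label, c("low", "low", "high", "high"))
  expect_identical(unname(gr$means["high"]), 2)
  expect_error(assign_groups(setNames(rep(1, 4), letters[1:4])), "identical")
  expect_match(gr$newick, "^\\(")
})

test_that("cluster labels are invariant to input ordering", {
  set.seed(41)
  adj <- setNames(c(rnorm(10, 1.0, 0.05), rnorm(10, 1.4, 0.05)),
                  sprintf("E%02d", 1:20))
  g1 <- assign_groups(adj)
  perm <- sample(20)
  g2 <- assign_groups(adj[perm])
  m <- match(g1$assignments$id, g2$assignments$id)
  expect_identical(g1$assignments$label, g2$assignments$label[m])
})

test_that("group assignment recovers the generator's true groups", {
  sim <- simulate_population(small_sim_config(seed = 27))
  fit <- fit_final_model(aggregate_phenotypes(sim$phenotypes))
  gr <- assign_groups(fit$fitted)
  truth <- sim$truth$group[gr$assignments$id]
  agree <- mean(gr$assignments$label == truth)
  expect_gte(max(agree, 1 - agree), 0.9)  # best label permutation
})

test_that("group means hit the configured targets and the Welch test has power", {
  # phenotype-only replicates at the default study size (n = 48)
  n_rep <- 500
  reject <- 0
  ok_means <- 0
  cfg <- sim_config(n_chrom = 1, snps_per_chrom = 20, n_low_maf_snps = 0,
                    n_hwe_violating_snps = 0, n_low_call_snps = 0,
                    planted_roh = data.frame(),
                    planted_diff_snps = data.frame())
  for (s in seq_len(n_rep)) {
    set.seed(5000 + s)
    ph <- simulate_phenotypes(cfg)
    fit <- fit_final_model(ph)
    gr <- suppressWarnings(assign_groups(fit$fitted))
    reject <- reject + (!is.null(gr$welch) && gr$welch$p < 0.05)
    m <- tapply(ph$fecundity, gr$assignments$label[match(ph$id, gr$assignments$id)], mean)
    se_h <- 0.5 / sqrt(sum(ph$group == "high"))
    se_l <- 0.4 / sqrt(sum(ph$group == "low"))
    ok_means <- ok_means +
      (abs(m["high"] - 1.3) < 3 * se_h && abs(m["low"] - 1.1) < 3 * se_l)
  }
  expect_gte(reject / n_rep, 0.8)     # power of the group-difference test
  expect_gte(ok_means / n_rep, 0.9)   # means within 3 SE of the targets
})

test_that("aggregation averages fecundity and keeps the latest covariates", {
  ph <- data.frame(id = c("a", "a", "b"), year = c(2019, 2021, 2020),
                   age = c(3, 5, 4), body_condition = c(2, 4, 3),
                   hours_estrus = 30, n_births = c(1, 3, 2),
                   fecundity = c(1, 2, 1), stringsAsFactors = FALSE)
  agg <- aggregate_phenotypes(ph)
  expect_identical(nrow(agg), 2L)
  expect_equal(agg$fecundity[agg$id == "a"], 1.5)
  expect_identical(agg$body_condition[agg$id == "a"], 4)
})
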