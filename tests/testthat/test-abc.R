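# Reference tables, rejection, scenario choice, parameter adjustment and
# the posterior utilities.

small_table <- function(n = 120, scenarios = 1:2, seed = 61) {
  set.seed(seed)
  build_reference_table(scenarios, n_per_scenario = n, n_loci = 5,
                        sample_sizes = c(6, 6, 6))
}

test_that("reference tables have the right shape and are seed-reproducible", {
  set.seed(62)
  tab <- build_reference_table(1:4, n_per_scenario = 25, n_loci = 5,
                               sample_sizes = c(6, 6, 6))
  expect_equal(nrow(tab), 100)
  expect_equal(length(attr(tab, "stat_names")), 21)
  expect_true(all(attr(tab, "stat_names") %in% names(tab)))
  expect_equal(sort(unique(tab$scenario)), 1:4)
  # parameters a scenario does not use are NA in its rows
  expect_true(all(is.na(tab$db[tab$scenario == 1])))
  expect_true(all(!is.na(tab$db[tab$scenario == 2])))
  set.seed(63)
  a <- build_reference_table(2, n_per_scenario = 10, n_loci = 3,
                             sample_sizes = c(4, 4, 4))
  set.seed(63)
  b <- build_reference_table(2, n_per_scenario = 10, n_loci = 3,
                             sample_sizes = c(4, 4, 4))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("bottleneck scenarios show lower diversity than their no-bottleneck twins", {
  set.seed(64)
  pr <- default_priors(overrides = list(
    N1 = c(200, 500), N2 = c(200, 500), N3 = c(200, 500),
    N1b = c(15000, 25000), N2b = c(15000, 25000), N3b = c(15000, 25000),
    db = c(2000, 4000), t1 = c(4500, 9000)
  ))
  tab <- build_reference_table(1:2, priors = pr, n_per_scenario = 60,
                               n_loci = 8, sample_sizes = c(8, 8, 8))
  div <- rowMeans(tab[, c("P1_div", "P2_div", "P3_div")])
  expect_lt(mean(div[tab$scenario == 2]), mean(div[tab$scenario == 1]))
})

test_that("reference tables round-trip through CSV", {
  tab <- small_table(n = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_table(tab, path)
  back <- read_reference_table(path)
  expect_equal(attr(back, "stat_names"), attr(tab, "stat_names"))
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})

test_that("rejection retains the exact row for an in-table observation", {
  tab <- small_table(n = 60)
  sn <- attr(tab, "stat_names")
  obs <- setNames(as.numeric(tab[17, sn]), sn)
  ret <- select_closest(tab, obs, fraction = 1 / nrow(tab))
  expect_equal(nrow(ret), 1)
  expect_equal(ret$distance, 0)
  expect_equal(as.numeric(ret[1, sn]), unname(obs))
  # fraction = 1 keeps everything
  ret_all <- select_closest(tab, obs, fraction = 1)
  expect_equal(nrow(ret_all), nrow(tab))
})

test_that("zero-MAD statistics are dropped with a warning", {
  tab <- small_table(n = 30)
  sn <- attr(tab, "stat_names")
  tab$P1_nal <- 1 # constant column
  obs <- setNames(as.numeric(tab[3, sn]), sn)
  expect_warning(select_closest(tab, obs, 0.2), "zero-MAD")
})

test_that("model choice handles degenerate compositions sensibly", {
  tab <- small_table(n = 100, scenarios = 1:2)
  sn <- attr(tab, "stat_names")
  # an observation sitting on a scenario-2 row: that row is retained
  obs <- setNames(as.numeric(tab[150, sn]), sn)
  mc <- suppressWarnings(model_choice(tab, obs, fraction = 0.05))
  expect_equal(sum(mc$prob_direct), 1, tolerance = 1e-9)
  expect_equal(sum(mc$prob_logistic), 1, tolerance = 1e-9)
  expect_error(model_choice(tab[tab$scenario == 1, ], obs),
               "at least two")
})

test_that("duplicated scenarios split the posterior probability evenly", {
  set.seed(65)
  tab <- small_table(n = 80, scenarios = 1)
  tab2 <- tab
  tab2$scenario <- 2L
  both <- dplyr::bind_rows(tab, tab2)
  both <- msatabc:::as_reftable(both, tab)
  sn <- attr(tab, "stat_names")
  obs <- setNames(colMeans(tab[, sn]), sn)
  # fraction 1 so the tie between byte-identical rows cannot bias retention
  mc <- model_choice(both, obs, fraction = 1)
  expect_equal(mc$prob_direct, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(mc$prob_logistic, c(0.5, 0.5), tolerance = 0.1)
})

test_that("posterior adjustment honours point masses and no-signal cases", {
  tab <- small_table(n = 400, scenarios = 2)
  sn <- attr(tab, "stat_names")
  obs <- setNames(colMeans(tab[, sn]), sn)
  # all retained rows share one parameter value -> point mass
  tab_pt <- tab
  tab_pt$Nanc <- 1234
  post <- estimate_posteriors(tab_pt, obs, scenario = 2, fraction = 0.3)
  s <- post$summary[post$summary$parameter == "Nanc", ]
  expect_equal(s$median, 1234, tolerance = 1e-6)
  expect_equal(s$q050, s$q950, tolerance = 1e-6)
  # a parameter with no relation to the statistics keeps its sample
  # (slopes ~ 0): inject pure noise as a fake parameter
  set.seed(66)
  tab_ns <- tab
  tab_ns$sni_mic <- runif(nrow(tab_ns), 1e-8, 1e-5)
  post2 <- estimate_posteriors(tab_ns, obs, scenario = 2, fraction = 0.3)
  ret <- select_closest(tab_ns, obs, 0.3)
  raw <- sort(ret$sni_mic)
  adj <- sort(post2$samples$sni_mic)
  expect_gt(cor(raw, adj), 0.98)
})

test_that("adjusted samples never leave the prior support", {
  set.seed(67)
  tab <- small_table(n = 150, scenarios = 2)
  sn <- attr(tab, "stat_names")
  pr <- default_priors()
  for (rep in 1:5) {
    obs <- setNames(as.numeric(tab[sample(nrow(tab), 1), sn]), sn)
    post <- estimate_posteriors(tab, obs, scenario = 2, fraction = 0.2)
    for (nm in setdiff(names(post$samples), c("weight", "distance"))) {
      b <- pr[pr$name == nm, ]
      expect_true(all(post$samples[[nm]] >= b$low - 1e-9))
      expect_true(all(post$samples[[nm]] <= b$high + 1e-9))
    }
    expect_true(all(post$summary$q050 <= post$summary$median + 1e-12))
    expect_true(all(post$summary$median <= post$summary$q950 + 1e-12))
  }
})

test_that("fraction 1 with zero slopes reproduces the prior", {
  set.seed(68)
  tab <- build_reference_table(1, n_per_scenario = 600, n_loci = 3,
                               sample_sizes = c(4, 4, 4))
  sn <- attr(tab, "stat_names")
  obs <- setNames(colMeans(tab[, sn]), sn)
  post <- estimate_posteriors(tab, obs, scenario = 1, fraction = 1,
                              zero_slopes = TRUE)
  pr <- default_priors()
  for (nm in c("N1", "Nanc", "t1")) {
    b <- pr[pr$name == nm, ]
    ks <- suppressWarnings(
      stats::ks.test(post$samples[[nm]], "punif", b$low, b$high)
    )
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("time conversions and bottleneck ratios match the published arithmetic", {
  expect_equal(convert_to_years(6830), 20490)
  expect_equal(convert_to_years(5010), 15030)
  expect_equal(convert_to_years(0), 0)
  expect_equal(convert_to_years(100, generation_time = 2), 200)
  expect_error(convert_to_years(10, generation_time = 0))
  expect_equal(bottleneck_ratio(6400, 3380), 1.9)
  expect_equal(bottleneck_ratio(14400, 3240), 4.4)
  expect_equal(bottleneck_ratio(16500, 5480), 3.0)
  expect_equal(bottleneck_ratio(500, 500), 1.0)
  expect_error(bottleneck_ratio(100, 0))
})

test_that("tidy and glance expose the fitted objects as tibbles", {
  tab <- small_table(n = 100, scenarios = 1:2)
  sn <- attr(tab, "stat_names")
  obs <- setNames(colMeans(tab[, sn]), sn)
  mc <- suppressWarnings(model_choice(tab, obs, fraction = 0.1))
  expect_s3_class(tidy(mc), "tbl_df")
  expect_equal(nrow(glance(mc)), 1)
  post <- estimate_posteriors(tab, obs, scenario = 2, fraction = 0.3)
  expect_s3_class(tidy(post), "tbl_df")
  expect_true(all(c("median", "q050", "q950") %in% names(tidy(post))))
  expect_equal(glance(post)$scenario, 2)
})

test_that("PCA pre-evaluation projects the observed point consistently", {
  set.seed(69)
  tab <- small_table(n = 150, scenarios = 1:2)
  sn <- attr(tab, "stat_names")
  obs <- setNames(as.numeric(tab[42, sn]), sn)
  p <- pca_preevaluation(tab, obs, n_points = 1e5)
  # observed equals a table row: identical coordinates to that row's score
  row_score <- p$scores[42, ]
  expect_equal(unname(unlist(row_score[c("PC1", "PC2")])),
               unname(unlist(p$observed)), tolerance = 1e-8)
  # unit-scaled PCA: component variances sum to the statistic count
  used <- sum(apply(tab[, sn], 2, stats::sd) > 0)
  expect_equal(sum(p$prcomp$sdev^2), used, tolerance = 1e-8)
})

test_that("autoplot methods return ggplot objects", {
  tab <- small_table(n = 100, scenarios = 1:2)
  sn <- attr(tab, "stat_names")
  obs <- setNames(colMeans(tab[, sn]), sn)
  mc <- suppressWarnings(model_choice(tab, obs, fraction = 0.1))
  post <- estimate_posteriors(tab, obs, scenario = 2, fraction = 0.3)
  p <- pca_preevaluation(tab, obs)
  expect_s3_class(autoplot(mc), "ggplot")
  expect_s3_class(autoplot(post), "ggplot")
  expect_s3_class(autoplot(p), "ggplot")
})
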