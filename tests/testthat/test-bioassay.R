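test_that("mortality classification partitions [0, 100] per WHO/CDC rules", {
  expect_equal(classify_mortality(87.2), "resistant")     # Ponce malathion x1
  expect_equal(classify_mortality(100), "susceptible")
  expect_equal(classify_mortality(98), "susceptible")
  expect_equal(classify_mortality(97.99), "possible_resistance")
  expect_equal(classify_mortality(90), "possible_resistance")
  expect_equal(classify_mortality(89.99), "resistant")
  expect_equal(classify_mortality(0), "resistant")
  # every value maps to exactly one of the three classes
  grid <- seq(0, 100, by = 0.1)
  cls <- classify_mortality(grid)
  expect_true(all(cls %in% c("susceptible", "possible_resistance",
                             "resistant")))
  expect_error(classify_mortality(101), "0, 100")
  expect_error(classify_mortality(-1), "0, 100")
})

test_that("death reconstruction inverts the printed percentages", {
  expect_equal(reconstruct_deaths(22.7, 97)$deaths, 22L)
  expect_equal(reconstruct_deaths(0, 91)$deaths, 0L)
  expect_equal(reconstruct_deaths(100, 45)$deaths, 45L)

  # exhaustive check over the bundled table: every cell round-trips within
  # 0.05 points except the starred San Juan malathion control-colony cell
  tab <- bioassay_table()
  rec <- reconstruct_deaths(tab$pct, tab$n)
  bad <- which(!rec$consistent)
  expect_equal(length(bad), 1L)
  expect_equal(tab$site[bad], "SanJuan")
  expect_equal(tab$insecticide[bad], "malathion")
  expect_equal(tab$treatment[bad], "rock")
  expect_equal(rec$deaths[bad], 50L)   # still reproduces the pooled total
})

test_that("pooled mortality reproduces the printed totals", {
  tab <- bioassay_table()
  rec <- reconstruct_deaths(tab$pct, tab$n)
  tab$deaths <- rec$deaths
  pick <- function(ins, tr) tab[tab$insecticide == ins & tab$treatment == tr, ]
  expect_equal(pooled_mortality(pick("deltamethrin", "x1")), 22.0)
  expect_equal(pooled_mortality(pick("deltamethrin", "x5")), 48.8)
  expect_equal(pooled_mortality(pick("deltamethrin", "x10")), 89.8)
  expect_equal(pooled_mortality(pick("malathion", "x1")), 39.8)
  expect_equal(pooled_mortality(pick("malathion", "x2")), 62.3)
  expect_equal(pooled_mortality(pick("malathion", "x3")), 76.7)
  # single record pools to its own percentage
  one <- data.frame(deaths = 19L, n = 47L)
  expect_equal(pooled_mortality(one), round_half_up(100 * 19 / 47, 1))
})

test_that("IRLS matches closed forms, glm, and the score equations", {
  # intercept-only single cell: coefficient = log(deaths / n)
  one <- data.frame(site = "A", insecticide = "deltamethrin",
                    dose_multiplier = 1, dose_ug = 0.75, n = 50L,
                    deaths = 20L)
  f0 <- fit_poisson_loglinear(one, formula_terms = character(0))
  expect_equal(unname(f0$coefficients), log(20 / 50), tolerance = 1e-10)

  # random design: agree with stats::glm to high precision
  set.seed(5)
  rec <- expand.grid(site = c("Bayamon", "Dorado", "Ponce"),
                     insecticide = c("deltamethrin", "malathion"),
                     dose_multiplier = c(1, 5, 10),
                     stringsAsFactors = FALSE)
  rec$dose_ug <- rec$dose_multiplier * ifelse(rec$insecticide == "malathion",
                                              400, 0.75)
  rec$n <- sample(40:100, nrow(rec), replace = TRUE)
  rec$deaths <- rbinom(nrow(rec), rec$n, 0.3)
  fit <- fit_poisson_loglinear(rec)
  g <- stats::glm(deaths ~ site + insecticide + dose_multiplier,
                  family = stats::poisson(),
                  offset = log(n),
                  data = transform(rec,
                                   site = factor(site),
                                   insecticide = factor(insecticide)))
  expect_equal(unname(fit$coefficients[c("(Intercept)", "siteDorado",
                                         "sitePonce")]),
               unname(stats::coef(g)[c("(Intercept)", "siteDorado",
                                       "sitePonce")]), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["concentration"]),
               unname(stats::coef(g)["dose_multiplier"]), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-8)

  # score equations X'(y - mu) = 0 within 1e-6
  X <- stats::model.matrix(~ site + insecticide + concentration,
                           transform(rec, concentration = dose_multiplier,
                                     site = factor(site,
                                                   c("Bayamon", "Dorado",
                                                     "Ponce")),
                                     insecticide = factor(insecticide)))
  expect_lt(max(abs(crossprod(X, rec$deaths - fit$fitted))), 1e-6)

  # saturated model reproduces the observed counts
  rec$cell <- factor(seq_len(nrow(rec)))
  Xs <- stats::model.matrix(~ cell, rec)
  sat <- fit_poisson_loglinear(transform(rec, site = cell),
                               formula_terms = "site",
                               ref_site = levels(rec$cell)[1])
  expect_equal(unname(sat$fitted), as.numeric(rec$deaths), tolerance = 1e-6)
})

test_that("coefficients are recovered from simulated counts", {
  set.seed(6)
  des <- expand.grid(site = c("Bayamon", "Dorado", "Ponce", "SanJuan"),
                     insecticide = c("deltamethrin", "malathion"),
                     dose_multiplier = c(1, 2, 3),
                     stringsAsFactors = FALSE)
  des$dose_ug <- des$dose_multiplier
  des$n <- 10000L
  beta <- c(`(Intercept)` = -2.5, siteDorado = -0.3, sitePonce = 0.35,
            siteSanJuan = 0.1, insecticidemalathion = 0.43,
            concentration = 0.25)
  X <- stats::model.matrix(~ site + insecticide + concentration,
                           transform(des, concentration = dose_multiplier,
                                     site = factor(site),
                                     insecticide = factor(insecticide)))
  mu <- des$n * exp(as.vector(X %*% beta))
  des$deaths <- rpois(nrow(des), mu)
  fit <- fit_poisson_loglinear(des)
  expect_true(all(abs(fit$coefficients[names(beta)] - beta) < 0.02))
})

test_that("likelihood-ratio test matches directly evaluated likelihoods", {
  tab <- bioassay_regression_cells()
  full <- fit_poisson_loglinear(tab)
  red <- fit_poisson_loglinear(tab, formula_terms = c("site", "insecticide"))
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  z <- likelihood_ratio_test(full, red)
  # direct likelihood oracle from the returned coefficients
  ll <- function(fit, terms) {
    d <- transform(tab, concentration = dose_multiplier,
                   site = factor(site, c("Bayamon", "Dorado", "Ponce",
                                         "SanJuan")),
                   insecticide = factor(insecticide,
                                        c("deltamethrin", "malathion")))
    X <- stats::model.matrix(stats::reformulate(terms), d)
    sum(stats::dpois(d$deaths,
                     exp(log(d$n) + as.vector(X %*% fit$coefficients)),
                     log = TRUE))
  }
  expect_equal(z$statistic,
               2 * (ll(full, c("site", "insecticide", "concentration")) -
                      ll(red, c("site", "insecticide"))),
               tolerance = 1e-8)
  expect_equal(z$df, 1L)

  # non-nested rejection
  other <- fit_poisson_loglinear(tab, formula_terms = "concentration")
  expect_error(likelihood_ratio_test(other, red), "not nested")
})

test_that("LRT type-I error is nominal under the null", {
  set.seed(8)
  n_rep <- 1000L
  reject <- 0L
  des <- expand.grid(site = c("A", "B"),
                     insecticide = c("deltamethrin", "malathion"),
                     dose_multiplier = 1, stringsAsFactors = FALSE)
  des$dose_ug <- 1; des$n <- 200L
  rate <- c(A = 0.2, B = 0.35)
  for (r in seq_len(n_rep)) {
    des$deaths <- rpois(nrow(des), des$n * rate[des$site])
    des$deaths <- pmin(des$deaths, des$n)
    full <- fit_poisson_loglinear(des, formula_terms = c("site",
                                                         "insecticide"),
                                  ref_site = "A")
    red <- fit_poisson_loglinear(des, formula_terms = "site", ref_site = "A")
    if (likelihood_ratio_test(full, red)$p < 0.05) reject <- reject + 1L
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(reject / n_rep - 0.05), 3 * se)
})

test_that("the reconstructed mortality table gives the published directions", {
  tab <- bioassay_regression_cells()
  expect_equal(nrow(tab), 24L)
  fit <- fit_poisson_loglinear(tab)
  expect_gt(fit$coefficients[["insecticidemalathion"]], 0)
  expect_gt(fit$coefficients[["sitePonce"]], 0)
  # concentration and insecticide are significant covariates
  for (tm in c("concentration", "insecticide")) {
    red <- fit_poisson_loglinear(tab,
                                 formula_terms = setdiff(fit$terms, tm))
    expect_lt(likelihood_ratio_test(fit, red)$p, 0.001)
  }
})
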