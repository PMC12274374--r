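## CDC bottle-bioassay mortality analysis: WHO/CDC classification, death
## reconstruction from printed percentages, pooled rates, and an offset
## Poisson log-linear model fitted by iteratively reweighted least squares
## (Fisher scoring) with likelihood-ratio tests.

#' Classify mortality per WHO/CDC criteria
#'
#' 98-100% susceptibility, 90-97% possible resistance, below 90% resistance.
#'
#' @param pct mortality percentage(s) in \[0, 100\]
#' @return character vector: `"susceptible"`, `"possible_resistance"` or
#'   `"resistant"`
#' @export
classify_mortality <- function(pct) {
  if (any(is.na(pct)) || any(pct < 0 | pct > 100))
    stop("mortality percentage must be in [0, 100]")
  ifelse(pct >= 98, "susceptible",
         ifelse(pct >= 90, "possible_resistance", "resistant"))
}

#' Reconstruct integer death counts from printed percentages
#'
#' deaths = round(pct * n / 100) to the nearest integer; a cell is flagged
#' inconsistent when no integer death count reproduces the printed
#' percentage within `tol` points.
#'
#' @param pct printed mortality percentage(s)
#' @param n number(s) of mosquitoes
#' @param tol round-trip tolerance in percentage points (default 0.05)
#' @return data frame with `deaths`, `roundtrip_pct` and `consistent`
#' @export
reconstruct_deaths <- function(pct, n, tol = 0.05) {
  stopifnot(all(pct >= 0 & pct <= 100), all(n > 0))
  deaths <- as.integer(round_half_up(pct * n / 100))
  rt <- 100 * deaths / n
  data.frame(deaths = deaths, roundtrip_pct = rt,
             consistent = abs(rt - pct) < tol)
}

#' Pooled mortality across records
#'
#' 100 * total deaths / total n, rounded half-up to one decimal.
#'
#' @param records data frame with `deaths` and `n`
#' @param digits decimal places (default 1, the printed-table precision)
#' @return pooled mortality percentage
#' @export
pooled_mortality <- function(records, digits = 1) {
  stopifnot(nrow(records) >= 1)
  N <- sum(records$n)
  if (N == 0) return(NA_real_)
  round_half_up(100 * sum(records$deaths) / N, digits)
}

#' Offset Poisson log-linear mortality model
#'
#' Fits log E(deaths) = log(n) + X beta by Fisher scoring, with site and
#' insecticide factors (reference levels Bayamon and deltamethrin) and a
#' concentration covariate coded either as the numeric dose multiplier or
#' as log dose in ug/bottle.
#'
#' @param records data frame with `site`, `insecticide`,
#'   `dose_multiplier`, `dose_ug`, `n`, `deaths`
#' @param concentration_coding `"multiplier"` or `"log_dose"`
#' @param formula_terms character vector of design terms (any of `"site"`,
#'   `"insecticide"`, `"concentration"`; empty for intercept-only)
#' @param ref_site,ref_insecticide reference factor levels
#' @param max_iter,tol IRLS iteration cap and score-norm convergence
#'   tolerance
#' @return object of class `poisson_fit`: `coefficients`, `se`,
#'   `loglik`, `df`, `fitted`, `converged`, plus the design kept for
#'   nesting checks
#' @export
fit_poisson_loglinear <- function(records,
                                  concentration_coding = c("multiplier",
                                                           "log_dose"),
                                  formula_terms = c("site", "insecticide",
                                                    "concentration"),
                                  ref_site = "Bayamon",
                                  ref_insecticide = "deltamethrin",
                                  max_iter = 100L, tol = 1e-8) {
  concentration_coding <- match.arg(concentration_coding)
  stopifnot(all(records$deaths >= 0), all(records$n > 0),
            all(records$deaths <= records$n))
  df <- records
  df$concentration <- switch(concentration_coding,
                             multiplier = df$dose_multiplier,
                             log_dose = log(df$dose_ug))
  terms <- intersect(c("site", "insecticide", "concentration"), formula_terms)
  for (f in intersect(c("site", "insecticide"), terms)) {
    lev <- unique(df[[f]])
    ref <- if (f == "site") ref_site else ref_insecticide
    if (ref %in% lev) lev <- c(ref, setdiff(lev, ref))
    df[[f]] <- factor(df[[f]], levels = lev)
  }
  fml <- if (length(terms)) stats::reformulate(terms) else ~ 1
  X <- model.matrix(fml, df)
  y <- df$deaths
  offset <- log(df$n)

  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- offset + as.vector(X %*% beta)
    mu <- exp(eta)
    score <- crossprod(X, y - mu)
    W <- mu
    fisher <- crossprod(X, X * W)
    step <- tryCatch(solve(fisher, score),
                     error = function(e) stop("singular design (separation?)"))
    beta <- beta + as.vector(step)
    if (max(abs(score)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    eta <- offset + as.vector(X %*% beta)
    mu <- exp(eta)
    if (max(abs(crossprod(X, y - mu))) >= tol)
      stop("IRLS failed to converge in ", max_iter, " iterations")
    converged <- TRUE
  }
  eta <- offset + as.vector(X %*% beta)
  mu <- exp(eta)
  se <- sqrt(diag(solve(crossprod(X, X * mu))))
  ll <- sum(dpois(y, mu, log = TRUE))
  structure(list(coefficients = setNames(as.vector(beta), colnames(X)),
                 se = setNames(se, colnames(X)),
                 loglik = ll, df = ncol(X), fitted = mu,
                 converged = converged, terms = terms,
                 coding = concentration_coding, n_obs = nrow(X)),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat("Offset Poisson log-linear model (", x$coding, " coding)\n", sep = "")
  z <- x$coefficients / x$se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  print(data.frame(estimate = round(x$coefficients, 4),
                   se = round(x$se, 4), z = round(z, 2),
                   p = signif(p, 3)))
  cat(sprintf("logLik %.3f on %d parameters (%d cells)\n",
              x$loglik, x$df, x$n_obs))
  invisible(x)
}

#' Likelihood-ratio test of nested Poisson models
#'
#' @param full,reduced `poisson_fit` objects; the reduced model's terms
#'   must be a subset of the full model's, both fitted to the same cells
#' @return list with `statistic`, `df`, `p`
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "poisson_fit"), inherits(reduced, "poisson_fit"))
  if (!all(reduced$terms %in% full$terms) || reduced$df > full$df ||
      full$n_obs != reduced$n_obs)
    stop("models are not nested")
  stat <- 2 * (full$loglik - reduced$loglik)
  df <- full$df - reduced$df
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = max(stat, 0), df = df, p = p)
}

#' Prepare the exposed-cell analysis table from a printed bioassay table
#'
#' Reconstructs integer deaths for every cell and keeps the field-exposed
#' cells (treatments x1 and above; unexposed controls and the ROCK
#' reference colony are excluded from the regression).
#'
#' @param tab a bioassay table as from [bioassay_table()]
#' @return the table with `deaths` and `consistent` columns, filtered to
#'   exposed cells
#' @export
bioassay_regression_cells <- function(tab = bioassay_table()) {
  rec <- reconstruct_deaths(tab$pct, tab$n)
  tab$deaths <- rec$deaths
  tab$consistent <- rec$consistent
  tab[!(tab$treatment %in% c("control", "rock")), , drop = FALSE]
}
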