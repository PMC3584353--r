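#' Fit a one-phase exponential decay or association curve
#'
#' Least-squares fit of `Y(x) = plateau + (Y0 - plateau) * exp(-k * x)` with
#' `k >= 0`. The decay and association forms describe the same curve
#' `a + b*exp(-k x)` (association is the conventional label when the
#' response rises toward the plateau, `b < 0`); the `form` argument controls
#' only how the fit is reported. The rate `k` is profiled over a log-spaced
#' grid of `n_starts` values in `[0, k_max]` — the intercept and amplitude
#' are solved exactly by linear least squares at each `k` — and the best
#' grid point is refined by golden-section search, so the returned residual
#' sum of squares never exceeds that of the constant model.
#'
#' @param x,y paired observations; at least 4 distinct `x` required.
#' @param form `"decay"` (response falls toward the plateau, e.g. density
#'   vs. age) or `"association"` (response rises, e.g. similarity vs. age).
#' @param k_max upper box bound for the rate, per unit of `x` (default 1,
#'   ample for rates measured per day over ages of 100-3000 days).
#' @param n_starts number of log-spaced grid values of `k`.
#' @return An object of class `decay_fit`: list with `form`, `Y0` (response
#'   at x = 0), `plateau`, `k`, `r_squared` (`1 - SSres/SStot`), `ss_res`,
#'   `n`, and flags `k_at_bound` and `k_unidentifiable` (constant response).
#' @examples
#' x <- seq(0, 3000, by = 100)
#' y <- 50 + 450 * exp(-0.01 * x)
#' fit_one_phase(x, y)
#' @export
fit_one_phase <- function(x, y, form = c("decay", "association"),
                          k_max = 1, n_starts = 20L) {
  form <- match.arg(form)
  keep <- is.finite(x) & is.finite(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (length(unique(x)) < 4L) {
    stop("need at least 4 distinct x values", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    return(structure(list(form = form, Y0 = mean(y), plateau = mean(y), k = 0,
                          r_squared = 0, ss_res = 0, n = n,
                          k_at_bound = FALSE, k_unidentifiable = TRUE),
                     class = "decay_fit"))
  }

  # profile SS over k: (a, b) in a + b*exp(-k x) solved by linear LS
  prof <- function(k) {
    z <- exp(-k * x)
    if (max(z) - min(z) < 1e-12) {            # k ~ 0: amplitude unidentifiable
      return(list(ss = ss_tot, a = mean(y), b = 0))
    }
    cf <- unname(qr.coef(qr(cbind(1, z)), y))
    if (any(!is.finite(cf))) return(list(ss = ss_tot, a = mean(y), b = 0))
    r <- y - (cf[1] + cf[2] * z)
    list(ss = sum(r^2), a = cf[1], b = cf[2])
  }
  k_grid <- c(0, 10^seq(log10(1e-5), log10(k_max), length.out = n_starts))
  ss_grid <- vapply(k_grid, function(k) prof(k)$ss, numeric(1))
  i <- which.min(ss_grid)
  lo <- k_grid[max(1L, i - 1L)]
  hi <- k_grid[min(length(k_grid), i + 1L)]
  if (lo == hi) hi <- lo + 1e-5
  opt <- optimize(function(k) prof(k)$ss, interval = c(lo, hi), tol = 1e-12)
  k <- if (opt$objective < ss_grid[i]) opt$minimum else k_grid[i]
  sol <- prof(k)
  structure(list(form = form, Y0 = sol$a + sol$b, plateau = sol$a, k = k,
                 r_squared = 1 - sol$ss / ss_tot, ss_res = sol$ss, n = n,
                 k_at_bound = (k_max - k) < 1e-8 * k_max,
                 k_unidentifiable = abs(sol$b) < 1e-12),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("One-phase %s fit: Y0 = %.4g, plateau = %.4g, k = %.4g, R2 = %.4f (n = %d)\n",
              x$form, x$Y0, x$plateau, x$k, x$r_squared, x$n))
  if (x$k_unidentifiable) cat("  note: constant response, k unidentifiable\n")
  if (x$k_at_bound) cat("  note: k at the box bound\n")
  invisible(x)
}

#' Predicted values from a one-phase fit
#' @param object a `decay_fit`.
#' @param x values at which to evaluate the curve.
#' @param ... ignored.
#' @export
predict.decay_fit <- function(object, x, ...) {
  one_phase_curve(x, object$Y0, object$plateau, object$k)
}

#' Ordinary least-squares regression with F-test
#'
#' Thin wrapper around [stats::lm()] returning the slope, intercept,
#' coefficient of determination and the p-value of the F-test of zero slope.
#'
#' @param x,y paired observations; `n >= 3` and `var(x) > 0` required.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @examples
#' linear_regression(1:10, 2 * (1:10) + 1)
#' @export
linear_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (var(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  p <- unname(pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                 lower.tail = FALSE))
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = sm$r.squared, p_value = p, n = length(x))
}

#' One-way analysis of variance
#'
#' Standard (unbalanced) one-way fixed-effects ANOVA via [stats::aov()].
#'
#' @param groups a named list of numeric vectors, one per group, each with
#'   at least 2 observations.
#' @return List with `F`, `p_value`, `df` (between, within), `means`,
#'   and the underlying `aov` fit.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  list(F = tab[1L, "F value"], p_value = tab[1L, "Pr(>F)"],
       df = c(between = tab[1L, "Df"], within = tab[2L, "Df"]),
       means = vapply(groups, mean, numeric(1)), fit = fit)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be named", call. = FALSE)
  }
  if (any(lengths(groups) < 2L)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  invisible(groups)
}

#' Tukey HSD post-hoc comparison with compact letter display
#'
#' Runs Tukey's honestly-significant-difference test after a one-way ANOVA
#' and assigns letters to groups so that any two groups sharing a letter are
#' not significantly different: groups are sorted by mean and maximal
#' windows of mutually non-significant groups each receive one letter
#' (the usual "letters above columns" display).
#'
#' @param groups a named list of numeric vectors (as [one_way_anova()]).
#' @param alpha significance level for the pairwise comparisons.
#' @return List with `letters` (named character vector, one letter string
#'   per group), `p_matrix` (pairwise adjusted p-values) and `means`.
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8, 10))
#' tukey_letters(g)$letters
#' @export
tukey_letters <- function(groups, alpha = 0.05) {
  check_groups(groups)
  aovres <- one_way_anova(groups)
  tk <- TukeyHSD(aovres$fit)$group
  gn <- names(groups)
  pmat <- matrix(1, length(gn), length(gn), dimnames = list(gn, gn))
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1L]]
    pmat[pair[1L], pair[2L]] <- pmat[pair[2L], pair[1L]] <- tk[r, "p adj"]
  }
  ord <- order(aovres$means, decreasing = TRUE)
  sorted <- gn[ord]
  # maximal windows of mutually non-significant groups along the mean order
  windows <- list()
  for (i in seq_along(sorted)) {
    j <- i
    while (j < length(sorted) &&
           all(pmat[sorted[i:(j + 1L)], sorted[i:(j + 1L)]] > alpha)) {
      j <- j + 1L
    }
    windows[[length(windows) + 1L]] <- sorted[i:j]
  }
  keep <- !vapply(seq_along(windows), function(i) {
    any(vapply(seq_along(windows), function(j) {
      i != j && all(windows[[i]] %in% windows[[j]])
    }, logical(1)))
  }, logical(1))
  windows <- windows[keep]
  letters_out <- setNames(rep("", length(gn)), gn)
  for (w in seq_along(windows)) {
    lab <- letters[w]
    for (g in windows[[w]]) {
      letters_out[g] <- paste0(letters_out[g], lab)
    }
  }
  list(letters = letters_out, p_matrix = pmat, means = aovres$means)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact test by complete hypergeometric enumeration in log
#' space: with the observed margins fixed, the p-value is the sum of the
#' probabilities of all tables whose probability does not exceed the
#' observed table's (probability-mass ordering, the convention of standard
#' implementations, with the same relative tolerance of 1e-7 when
#' comparing probabilities). Agrees with [stats::fisher.test()], which
#' serves as an independent cross-check in the test suite, but runs an
#' order of magnitude faster.
#'
#' @param tab a 2x2 matrix of non-negative counts, rows = marker +/-
#'   (e.g. BrdU), columns = intensity class (intense/weak).
#' @return List with `p_value`, `odds_ratio` (sample `ad/bc`, `Inf` or `NaN`
#'   when cells are empty), and the table.
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2))$p_value  # 2 / choose(20, 10)
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  a <- tab[1, 1]
  m <- a + tab[1, 2]                 # row-1 margin
  n2 <- tab[2, 1] + tab[2, 2]        # row-2 margin
  k <- a + tab[2, 1]                 # column-1 margin
  if (m == 0 || n2 == 0 || k == 0 || k == m + n2) {
    p <- 1                           # a zero margin admits a single table
  } else {
    xs <- max(0, k - n2):min(k, m)
    logp <- lchoose(m, xs) + lchoose(n2, k - xs) - lchoose(m + n2, k)
    obs <- logp[xs == a]
    p <- min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
  }
  list(p_value = p,
       odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
       table = tab)
}
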