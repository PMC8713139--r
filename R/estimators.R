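# Free-energy estimators: Crooks Gaussian Intersection and Bennett
# acceptance ratio, with bootstrap errors and overlap diagnostics.
#
# Convention: backward work sets store the work done along the backward
# (reduced -> oxidized) path; estimators negate them into the forward frame
# (W~ = -W_B), consistent with the Crooks fluctuation theorem
# P_F(W) / P_B(-W) = exp(beta (W - dG)).

#' Fit a Gaussian to a work set
#'
#' Sample mean and unbiased (n-1) standard deviation. Work histograms from
#' well-behaved fast-switching protocols are close to Gaussian, which is
#' the premise of the CGI estimator.
#'
#' @param ws a [work_set()] (or bare numeric vector) with >= 2 values.
#' @return An object of class `gaussian_fit` with fields `mean`, `sd`, `n`
#'   and `degenerate` (`TRUE` when all values coincide, sd = 0).
#' @examples
#' fit_gaussian(work_set("b", "forward", c(1, 3)))
#' @export
fit_gaussian <- function(ws) {
  x <- if (inherits(ws, "work_set")) ws$works else as.numeric(ws)
  if (length(x) < 2L) stop("need at least 2 samples to fit a Gaussian")
  s <- sd(x)
  structure(
    list(mean = mean(x), sd = s, n = length(x), degenerate = (s == 0)),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mean = %.4f, sd = %.4f, n = %d%s\n",
              x$mean, x$sd, x$n, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# Common validation for paired forward/backward sets; returns the negated
# backward works (forward frame) and beta.
.check_pair <- function(forward, backward) {
  stopifnot(inherits(forward, "work_set"), inherits(backward, "work_set"))
  if (forward$direction != "forward" || backward$direction != "backward") {
    stop("expected one forward and one backward work set (in that order)")
  }
  if (length(forward$works) < 2L || length(backward$works) < 2L) {
    stop("need at least 2 work values per direction")
  }
  if (!isTRUE(all.equal(forward$temperature, backward$temperature))) {
    stop("forward and backward sets must share a temperature")
  }
  list(wf = forward$works, wr = -backward$works,
       beta = beta_from_temperature(forward$temperature))
}

.free_energy_estimate <- function(dG, method, forward, backward, beta,
                                  se = NA_real_, diagnostics = NULL) {
  structure(
    list(dG = dG, se = se, method = method,
         n_forward = length(forward$works),
         n_backward = length(backward$works),
         temperature = forward$temperature, beta = beta,
         diagnostics = diagnostics),
    class = "free_energy_estimate"
  )
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  se <- if (is.na(x$se)) "NA" else sprintf("%.3f", x$se)
  cat(sprintf("<free_energy_estimate> %s: dG = %.4f +/- %s kJ/mol (nF = %d, nB = %d, T = %g K)\n",
              x$method, x$dG, se, x$n_forward, x$n_backward, x$temperature))
  if (!is.null(x$diagnostics$cgi_warning) && isTRUE(x$diagnostics$cgi_warning)) {
    cat("  note: CGI intersection fell back to / was flagged near the midpoint\n")
  }
  invisible(x)
}

#' Crooks Gaussian Intersection estimate of the free energy
#'
#' Fits Gaussians to the forward works and to the negated backward works
#' and returns the intersection abscissa of the two fitted normal
#' densities. For equal variances this reduces to the midpoint of the two
#' means; under the Crooks fluctuation theorem the intersection point of
#' the forward and (negated) backward work densities is the free-energy
#' difference.
#'
#' The intersection solves the quadratic
#' \deqn{(1/\sigma_f^2 - 1/\sigma_r^2) x^2
#'       - 2 (\mu_f/\sigma_f^2 - \mu_r/\sigma_r^2) x
#'       + \mu_f^2/\sigma_f^2 - \mu_r^2/\sigma_r^2
#'       - 2 \ln(\sigma_r/\sigma_f) = 0.}
#' The real root lying between the two means is preferred; when both or
#' neither root falls in that interval (or the roots are complex) the root
#' nearest the midpoint (or the midpoint itself) is returned and
#' `diagnostics$cgi_warning` is set.
#'
#' @param forward,backward [work_set()] objects for the two directions
#'   (backward in its own frame; it is negated internally).
#' @return A `free_energy_estimate` (method `"CGI"`, `se = NA` until
#'   [bootstrap_se()] is run).
#' @examples
#' p <- sample_cft_works(cft_model(dG_true = 30, sigma = 4,
#'                                 n_per_direction = 200, seed = 1))
#' cgi_estimate(p$forward, p$backward)
#' @export
cgi_estimate <- function(forward, backward) {
  pr <- .check_pair(forward, backward)
  ff <- fit_gaussian(pr$wf)
  fr <- fit_gaussian(pr$wr)
  if (ff$degenerate || fr$degenerate) {
    stop("degenerate (zero-sd) work distribution; CGI undefined")
  }
  sol <- .cgi_intersection(ff$mean, ff$sd, fr$mean, fr$sd)
  diag <- overlap_diagnostics(forward, backward)
  diag$cgi_warning <- sol$warning
  .free_energy_estimate(sol$x, "CGI", forward, backward, pr$beta,
                        diagnostics = diag)
}

# Intersection abscissa of N(mu_f, sd_f^2) and N(mu_r, sd_r^2) densities,
# with the root-selection policy described in cgi_estimate().
.cgi_intersection <- function(mu_f, sd_f, mu_r, sd_r) {
  mid <- (mu_f + mu_r) / 2
  a <- 1 / sd_f^2 - 1 / sd_r^2
  b <- -2 * (mu_f / sd_f^2 - mu_r / sd_r^2)
  cc <- mu_f^2 / sd_f^2 - mu_r^2 / sd_r^2 - 2 * log(sd_r / sd_f)
  if (abs(a) < 1e-12 * max(1 / sd_f^2, 1 / sd_r^2)) {
    # equal-variance limit: linear equation, exact midpoint
    x <- if (b != 0) -cc / b else mid
    return(list(x = x, warning = FALSE))
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) {
    return(list(x = mid, warning = TRUE))
  }
  roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  lo <- min(mu_f, mu_r); hi <- max(mu_f, mu_r)
  inside <- roots >= lo & roots <= hi
  if (sum(inside) == 1L) {
    return(list(x = roots[inside], warning = FALSE))
  }
  # both inside or none inside: nearest to midpoint, flagged
  list(x = roots[which.min(abs(roots - mid))], warning = TRUE)
}

#' Bennett acceptance ratio objective function
#'
#' With `f(t) = 1/(1 + exp(t))`, `M = log(nF/nB)` and negated backward
#' works `W~`, the BAR maximum-likelihood condition is `g(dG) = 0` where
#' \deqn{g(\Delta G) = \sum_i f(M + \beta(W_{F,i} - \Delta G))
#'                   - \sum_j f(-M + \beta(\Delta G - \tilde W_j)).}
#' `g` is strictly monotone increasing in `dG` (from `-nB` to `+nF`), so
#' the root is unique. Exposed mainly for diagnostics and testing.
#'
#' @param dG trial free-energy value(s), kJ/mol (vectorized).
#' @param forward,backward [work_set()] objects.
#' @return `g(dG)`, same length as `dG`.
#' @export
bar_objective <- function(dG, forward, backward) {
  pr <- .check_pair(forward, backward)
  M <- log(length(pr$wf) / length(pr$wr))
  vapply(dG, function(x) {
    # f(t) = 1/(1+e^t) = plogis(-t), numerically stable in both tails
    sum(stats::plogis(-(M + pr$beta * (pr$wf - x)))) -
      sum(stats::plogis(-(-M + pr$beta * (x - pr$wr))))
  }, numeric(1))
}

#' Bennett acceptance ratio estimate of the free energy
#'
#' Solves the BAR self-consistency equation (see [bar_objective()]) by
#' bracketed root finding. The initial bracket spans the range of all
#' (forward and negated backward) works widened by 50 kJ/mol; the objective
#' is strictly monotone so any sign change brackets the unique root.
#'
#' @param forward,backward [work_set()] objects.
#' @param tol absolute tolerance on dG, kJ/mol (default 1e-8).
#' @return A `free_energy_estimate` (method `"BAR"`).
#' @examples
#' f <- work_set("b", "forward", c(9, 11))
#' b <- work_set("b", "backward", c(-9, -11))
#' bar_estimate(f, b)$dG   # 10 by symmetry
#' @export
bar_estimate <- function(forward, backward, tol = 1e-8) {
  pr <- .check_pair(forward, backward)
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")
  all_w <- c(pr$wf, pr$wr)
  lo <- min(all_w) - 50
  hi <- max(all_w) + 50
  g_lo <- bar_objective(lo, forward, backward)
  g_hi <- bar_objective(hi, forward, backward)
  if (!is.finite(g_lo) || !is.finite(g_hi) || g_lo * g_hi > 0) {
    stop("BAR estimation failed: no sign change on bracket; ",
         "forward/backward work distributions do not overlap")
  }
  root <- uniroot(function(x) bar_objective(x, forward, backward),
                  interval = c(lo, hi), tol = tol)$root
  diag <- tryCatch(overlap_diagnostics(forward, backward),
                   error = function(e) NULL)
  .free_energy_estimate(root, "BAR", forward, backward, pr$beta,
                        diagnostics = diag)
}

#' Bootstrap standard error of a free-energy estimate
#'
#' Paired nonparametric bootstrap: each direction is resampled with
#' replacement independently, the estimator is re-run, and the standard
#' deviation of the resampled estimates is returned. Deterministic given
#' `seed`.
#'
#' @param forward,backward [work_set()] objects.
#' @param estimator `"bar"` or `"cgi"`.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @return Standard error in kJ/mol.
#' @examples
#' p <- sample_cft_works(cft_model(dG_true = 30, sigma = 4,
#'                                 n_per_direction = 100, seed = 1))
#' bootstrap_se(p$forward, p$backward, "bar", n_boot = 100, seed = 2)
#' @export
bootstrap_se <- function(forward, backward, estimator = c("bar", "cgi"),
                         n_boot = 1000, seed = 1) {
  estimator <- match.arg(estimator)
  if (n_boot < 100) stop("'n_boot' must be at least 100")
  pr <- .check_pair(forward, backward)
  est_fun <- switch(estimator,
                    bar = function(f, b) bar_estimate(f, b)$dG,
                    cgi = function(f, b) cgi_estimate(f, b)$dG)
  nf <- length(forward$works)
  nb <- length(backward$works)
  vals <- with_seed(seed, {
    out <- rep(NA_real_, n_boot)
    for (k in seq_len(n_boot)) {
      fb <- work_set(forward$label, "forward",
                     forward$works[sample.int(nf, nf, replace = TRUE)],
                     forward$temperature)
      bb <- work_set(backward$label, "backward",
                     backward$works[sample.int(nb, nb, replace = TRUE)],
                     backward$temperature)
      out[k] <- tryCatch(est_fun(fb, bb), error = function(e) NA_real_)
    }
    out
  })
  n_fail <- sum(is.na(vals))
  if (n_fail > 0.10 * n_boot) {
    stop(sprintf("estimator failed in %d of %d bootstrap resamples", n_fail,
                 n_boot))
  }
  ok <- vals[!is.na(vals)]
  if (all(ok == ok[1L])) return(0)   # degenerate, e.g. zero dissipation
  sd(ok)
}

#' Bhattacharyya coefficient of two Gaussians
#'
#' Closed form:
#' `sqrt(2 s1 s2 / (s1^2 + s2^2)) * exp(-(m1 - m2)^2 / (4 (s1^2 + s2^2)))`.
#' Equals 1 for identical densities and decays to 0 as they separate.
#'
#' @param mean1,sd1,mean2,sd2 parameters of the two Gaussians (`sd > 0`).
#' @return Coefficient in \[0, 1\].
#' @export
bhattacharyya_coef <- function(mean1, sd1, mean2, sd2) {
  if (any(c(sd1, sd2) <= 0)) stop("standard deviations must be > 0")
  sqrt(2 * sd1 * sd2 / (sd1^2 + sd2^2)) *
    exp(-(mean1 - mean2)^2 / (4 * (sd1^2 + sd2^2)))
}

#' Work-distribution overlap and normality diagnostics
#'
#' The accuracy of both CGI and BAR hinges on overlap between the forward
#' and (negated) backward work distributions. Reports the Bhattacharyya
#' coefficient of the two fitted Gaussians, a one-sample
#' Kolmogorov-Smirnov normality p-value per direction against its fitted
#' Gaussian (approximate: the fitted parameters are plugged in), and the
#' gap between the fitted means.
#'
#' @param forward,backward [work_set()] objects with >= 2 values each.
#' @return An object of class `overlap_report` with fields
#'   `bhattacharyya`, `ks_p_forward`, `ks_p_backward`, `mean_gap`
#'   (`mu_f - mu_r`, kJ/mol).
#' @export
overlap_diagnostics <- function(forward, backward) {
  pr <- .check_pair(forward, backward)
  ff <- fit_gaussian(pr$wf)
  fr <- fit_gaussian(pr$wr)
  if (ff$degenerate || fr$degenerate) {
    stop("degenerate (zero-sd) work distribution; overlap undefined")
  }
  ks_p <- function(x, fit) {
    suppressWarnings(ks.test(x, "pnorm", mean = fit$mean, sd = fit$sd)$p.value)
  }
  structure(
    list(bhattacharyya = bhattacharyya_coef(ff$mean, ff$sd, fr$mean, fr$sd),
         ks_p_forward = ks_p(pr$wf, ff),
         ks_p_backward = ks_p(pr$wr, fr),
         mean_gap = ff$mean - fr$mean),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> Bhattacharyya = %.4f, mean gap = %.3f kJ/mol\n",
              x$bhattacharyya, x$mean_gap))
  cat(sprintf("  KS normality p: forward %.3g, backward %.3g\n",
              x$ks_p_forward, x$ks_p_backward))
  invisible(x)
}
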