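# Dose-response and enzyme-quantification analytics for the cell-based
# receptor-activation bioassay and fluorogenic enzyme standard curves.

#' Fit a four-parameter Hill dose-response curve
#'
#' Least-squares fit of `bottom + (top - bottom) / (1 + (EC50/c)^h)` to
#' replicate luminescence (or other response) readings.  The concentration
#' axis is handled on a log scale internally (EC50 is fitted as log10 EC50);
#' zero-concentration wells anchor the `bottom` asymptote but do not enter
#' the log grid.  The EC50 uncertainty defaults to the SD across
#' replicate-wise refits, mirroring how triplicate assay midpoints are
#' summarized; a covariance-based SE is available instead.
#'
#' @param data Data frame with columns `conc_nM`, `response` and optionally
#'   `replicate` (required for `se_method = "replicates"` with more than
#'   one replicate).
#' @param fix_hill Optional fixed Hill slope (e.g. 1); `NULL` (default)
#'   fits the slope freely.
#' @param se_method `"replicates"` (default) or `"covariance"`.
#' @return An object of class `"hill_fit"` with `coefficients`
#'   (bottom, top, ec50, hill), `se` (per-parameter; EC50 per
#'   `se_method`), `r.squared`, `fitted.values`, `residuals` and the data.
#' @export
#' @examples
#' tab <- generate_dose_response(assay_spec(ec50_true = 6.7, seed = 2))
#' fit <- fit_hill(tab)
#' coef(fit)["ec50"]
fit_hill <- function(data, fix_hill = NULL,
                     se_method = c("replicates", "covariance")) {
  se_method <- match.arg(se_method)
  stopifnot(is.data.frame(data), all(c("conc_nM", "response") %in% names(data)))
  conc <- data$conc_nM
  resp <- data$response
  if (any(conc < 0)) stop("concentrations must be >= 0")
  pos <- conc > 0
  if (length(unique(conc[pos])) < 4)
    stop("need at least 4 distinct nonzero concentrations")
  span <- log10(max(conc[pos]) / min(conc[pos]))
  if (span < 1)
    warning("concentrations span less than one order of magnitude; the fit may be poorly constrained")

  one_fit <- function(conc, resp) {
    # zero-concentration wells: pseudo log-concentration far below the grid
    # so their model response is effectively `bottom`
    lc <- ifelse(conc > 0, log10(conc), log10(min(conc[conc > 0])) - 6)
    mu <- tapply(resp, conc, mean)
    start <- list(bottom = unname(min(mu)), top = unname(max(mu)),
                  lec50 = stats::median(lc[conc > 0]))
    lower <- c(bottom = -Inf, top = -Inf, lec50 = min(lc) - 3)
    upper <- c(bottom = Inf, top = Inf, lec50 = max(lc) + 3)
    if (is.null(fix_hill)) {
      start$h <- 1
      lower <- c(lower, h = 0.1)
      upper <- c(upper, h = 10)
      form <- resp ~ bottom + (top - bottom) / (1 + 10^(h * (lec50 - lc)))
    } else {
      h_fixed <- fix_hill
      form <- resp ~ bottom + (top - bottom) /
        (1 + 10^(h_fixed * (lec50 - lc)))
    }
    df <- data.frame(resp = resp, lc = lc)
    # multistart over midpoint initials: nlsLM can stall on a singular
    # Jacobian or a local minimum from a single start, so fit from several
    # and keep the lowest-deviance converged solution
    lec50_starts <- unique(c(start$lec50, start$lec50 + c(-1, -0.5, 0.5, 1)))
    best <- NULL; last_err <- NULL
    for (l0 in lec50_starts) {
      st <- start
      st$lec50 <- min(max(l0, lower["lec50"]), upper["lec50"])
      fit <- tryCatch(
        minpack.lm::nlsLM(form, data = df, start = st, lower = lower,
                          upper = upper,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) e)
      if (inherits(fit, "error")) { last_err <- fit; next }
      if (is.null(best) || stats::deviance(fit) < stats::deviance(best))
        best <- fit
    }
    if (is.null(best)) stop(last_err)
    best
  }

  fit <- tryCatch(one_fit(conc, resp), error = function(e) e)
  if (inherits(fit, "error")) {
    out <- structure(list(converged = FALSE, message = conditionMessage(fit),
                          data = data),
                     class = "hill_fit")
    return(out)
  }
  cf <- stats::coef(fit)
  hill <- if (is.null(fix_hill)) unname(cf["h"]) else fix_hill
  est <- c(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
           ec50 = unname(10^cf["lec50"]), hill = hill)
  # enforce bottom <= top orientation
  if (est["bottom"] > est["top"]) {
    est[c("bottom", "top")] <- est[c("top", "bottom")]
    est["hill"] <- -est["hill"]
  }
  fitted <- .hill_response(conc, est["bottom"], est["top"], est["ec50"],
                           est["hill"])
  res <- resp - fitted
  sst <- sum((resp - mean(resp))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_

  se <- c(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
          hill = NA_real_)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(vc)) {
    sds <- sqrt(diag(vc))
    se["bottom"] <- sds["bottom"]; se["top"] <- sds["top"]
    # delta method for EC50 = 10^lec50
    se["ec50"] <- log(10) * est["ec50"] * sds["lec50"]
    if (is.null(fix_hill)) se["hill"] <- sds["h"]
  }
  rep_ec50 <- NULL
  if (se_method == "replicates" && "replicate" %in% names(data) &&
      length(unique(data$replicate)) > 1) {
    rep_ec50 <- vapply(split(data, data$replicate), function(d) {
      f <- tryCatch(one_fit(d$conc_nM, d$response), error = function(e) NULL)
      if (is.null(f)) NA_real_ else unname(10^stats::coef(f)["lec50"])
    }, numeric(1))
    if (sum(!is.na(rep_ec50)) >= 2)
      se["ec50"] <- stats::sd(rep_ec50, na.rm = TRUE)
  }
  structure(list(coefficients = est, se = se, r.squared = r2,
                 fitted.values = fitted, residuals = res,
                 replicate_ec50 = rep_ec50, converged = TRUE,
                 se_method = se_method, data = data, nls = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  if (!isTRUE(x$converged)) {
    cat("Hill fit: DID NOT CONVERGE (", x$message, ")\n", sep = "")
    return(invisible(x))
  }
  cat("Four-parameter Hill dose-response fit\n")
  cat(sprintf("  EC50 = %.4g nM (SD %.2g), Hill slope = %.3g\n",
              x$coefficients["ec50"], x$se["ec50"], x$coefficients["hill"]))
  cat(sprintf("  bottom = %.4g, top = %.4g, R^2 = %.4f\n",
              x$coefficients["bottom"], x$coefficients["top"], x$r.squared))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  object
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
fitted.hill_fit <- function(object, ...) object$fitted.values

#' Predicted response from a fitted Hill curve
#'
#' @param object A `"hill_fit"`.
#' @param conc Concentrations (nM) at which to evaluate; defaults to the
#'   fitted ones.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.hill_fit <- function(object, conc = NULL, ...) {
  if (is.null(conc)) conc <- object$data$conc_nM
  cf <- object$coefficients
  unname(.hill_response(conc, cf["bottom"], cf["top"], cf["ec50"],
                        cf["hill"]))
}

#' Plot a Hill fit over the replicate data
#'
#' @param x A `"hill_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data[x$data$conc_nM > 0, ]
  graphics::plot(d$conc_nM, d$response, log = "x",
                 xlab = "concentration (nM)", ylab = "response", ...)
  cg <- 10^seq(log10(min(d$conc_nM)), log10(max(d$conc_nM)),
               length.out = 200)
  graphics::lines(cg, predict(x, cg), col = "red", lwd = 2)
  invisible(x)
}

#' Fold change in potency between two dose-response fits
#'
#' The ratio of fitted EC50s (`before / after`); a value above 1 means the
#' second condition is more potent (lower EC50), as for a blocked probe
#' activated by enzymatic cleavage.  The uncertainty is propagated from
#' the per-fit EC50 SDs assuming independence.
#'
#' @param fit_before,fit_after `"hill_fit"` objects.
#' @return A list with `fold`, `se`, and the two EC50s.
#' @export
fold_activation <- function(fit_before, fit_after) {
  stopifnot(inherits(fit_before, "hill_fit"), inherits(fit_after, "hill_fit"),
            isTRUE(fit_before$converged), isTRUE(fit_after$converged))
  e1 <- unname(fit_before$coefficients["ec50"])
  e2 <- unname(fit_after$coefficients["ec50"])
  fold <- e1 / e2
  s1 <- unname(fit_before$se["ec50"]); s2 <- unname(fit_after$se["ec50"])
  se <- if (is.finite(s1) && is.finite(s2))
    fold * sqrt((s1 / e1)^2 + (s2 / e2)^2) else NA_real_
  list(fold = fold, se = se, ec50_before = e1, ec50_after = e2)
}

#' Convert an activity-equivalent enzyme concentration to a per-cell amount
#'
#' An assay reading activity equivalent to `activity_equiv` nM of soluble
#' enzyme in `reaction_volume` uL containing `cell_count` cells corresponds
#' to `activity_equiv * reaction_volume * 1e-3` pmol of enzyme, scaled to
#' a per-10^6-cells figure.
#'
#' @param activity_equiv Activity-equivalent enzyme concentration (nM).
#' @param reaction_volume Assay reaction volume (uL); default 100.
#' @param cell_count Cells in the reaction; default 1e5.
#' @return Enzyme amount in pmol per 10^6 cells.
#' @export
#' @examples
#' quantify_fap_per_cell(8.5, 100, 1e5)  # 8.5 pmol per 10^6 cells
quantify_fap_per_cell <- function(activity_equiv, reaction_volume = 100,
                                  cell_count = 1e5) {
  stopifnot(activity_equiv >= 0, reaction_volume > 0, cell_count > 0)
  pmol <- activity_equiv * reaction_volume * 1e-3  # nM * uL = 1e-3 pmol
  pmol * 1e6 / cell_count
}

#' Fit a monotone standard curve for enzyme quantification
#'
#' Interpolates the mean assay response at each known enzyme amount with a
#' monotone (Hyman-filtered) cubic spline; if the means are not monotone
#' they are first projected onto a monotone sequence by isotonic
#' regression.  The curve passes exactly through the (amount, mean
#' response) knots, so a response measured at a calibration knot maps back
#' to exactly its known amount.
#'
#' @param amounts Known enzyme amounts (any consistent unit), >= 2
#'   distinct values.
#' @param responses Assay responses; either one per amount or a matrix /
#'   longer vector of replicates grouped by `amounts`.
#' @return An object of class `"standard_curve"`.
#' @export
standard_curve <- function(amounts, responses) {
  stopifnot(is.numeric(amounts), is.numeric(responses),
            length(responses) %% length(amounts) == 0)
  nrep <- length(responses) / length(amounts)
  rmat <- matrix(responses, nrow = length(amounts))
  mu <- rowMeans(rmat)
  ord <- order(amounts)
  amounts <- amounts[ord]; mu <- mu[ord]; rmat <- rmat[ord, , drop = FALSE]
  if (length(unique(amounts)) < 2) stop("need at least 2 distinct amounts")
  increasing <- stats::cor(amounts, mu) >= 0
  mu_fit <- mu
  if (any(diff(if (increasing) mu else -mu) < 0)) {
    iso <- stats::isoreg(amounts, if (increasing) mu else -mu)
    mu_fit <- if (increasing) iso$yf else -iso$yf
  }
  resid_sd <- if (nrep > 1) stats::sd(as.vector(rmat - mu)) else
    stats::sd(mu - mu_fit)
  fwd <- stats::splinefun(amounts, mu_fit, method = "hyman")
  structure(list(amounts = amounts, responses = rmat, mean_response = mu_fit,
                 forward = fwd, increasing = increasing,
                 resid_sd = resid_sd),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: %d calibration points, %s response\n",
              length(x$amounts),
              if (x$increasing) "increasing" else "decreasing"))
  cat(sprintf("  amount range [%g, %g]; replicate residual SD %.3g\n",
              min(x$amounts), max(x$amounts), x$resid_sd))
  invisible(x)
}

#' Invert a standard curve at a measured response
#'
#' Inverse interpolation of the fitted monotone calibration.  Responses
#' outside the calibrated range are flagged as extrapolation and clipped
#' to the nearest endpoint amount.  The uncertainty is the replicate
#' residual SD mapped through the local slope of the curve.
#'
#' @param curve A [standard_curve()].
#' @param measured_response Measured assay response(s); vectorized.
#' @return A data frame with columns `amount`, `se`, `extrapolated`.
#' @export
interpolate_standard <- function(curve, measured_response) {
  stopifnot(inherits(curve, "standard_curve"), is.numeric(measured_response))
  rng_amt <- range(curve$amounts)
  rng_resp <- range(curve$mean_response)
  out <- vapply(measured_response, function(r) {
    if (r < rng_resp[1] || r > rng_resp[2]) {
      amt <- if ((r > rng_resp[2]) == curve$increasing) rng_amt[2] else rng_amt[1]
      return(c(amt, NA_real_, 1))
    }
    # knot hit: return the known amount exactly
    hit <- which(abs(curve$mean_response - r) <=
                   1e-12 * max(1, abs(r)))
    if (length(hit)) {
      amt <- curve$amounts[hit[1]]
    } else {
      f <- function(a) curve$forward(a) - r
      amt <- stats::uniroot(f, rng_amt, tol = 1e-12)$root
    }
    slope <- curve$forward(amt, deriv = 1)
    se <- if (is.finite(slope) && abs(slope) > 0)
      curve$resid_sd / abs(slope) else NA_real_
    c(amt, se, 0)
  }, numeric(3))
  if (any(out[3, ] == 1))
    warning("response outside calibrated range; estimate clipped to the curve endpoint")
  data.frame(amount = out[1, ], se = out[2, ],
             extrapolated = out[3, ] == 1)
}
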