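#' Simulate an isothermal dose-response table
#'
#' Forward model for the isothermal readout: soluble-fraction response at
#' one temperature versus drug concentration, following a four-parameter
#' logistic `r(c) = bottom + (top - bottom) c^h / (c^h + ec50^h)` plus
#' Gaussian noise.
#'
#' @param ec50 Half-maximal concentration (uM, > 0).
#' @param hill Hill slope.
#' @param top,bottom Asymptotic responses (high dose / zero dose).
#' @param doses Concentrations (uM, all > 0).
#' @param replicates Replicates per dose.
#' @param noise_sd Gaussian noise sd (response units).
#' @param seed Integer seed.
#' @return `data.frame`: dose, replicate, response.
#' @export
simulate_dose_response <- function(ec50, hill = 1, top = 1, bottom = 0,
                                   doses, replicates = 3, noise_sd = 0,
                                   seed = 1) {
  if (ec50 <= 0) .stopf("ec50 must be > 0")
  if (any(doses <= 0)) .stopf("invalid input: doses must be > 0")
  set.seed(seed)
  d <- rep(doses, each = replicates)
  mu <- bottom + (top - bottom) * d^hill / (d^hill + ec50^hill)
  data.frame(dose = d,
             replicate = rep(seq_len(replicates), times = length(doses)),
             response = mu + stats::rnorm(length(d), 0, noise_sd))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit with log-dose parameterization of EC50
#' (initialized at the median dose) and a positive Hill slope; the
#' direction of the response is absorbed by free top/bottom. An EC50 inside
#' the dosed range is flagged `interpolated`, outside `extrapolated`.
#'
#' @param doses Concentrations (uM, > 0), at least 5 distinct values.
#' @param responses Responses, same length.
#' @param direction `"auto"`, `"up"` (response rises with dose) or
#'   `"down"`; with `"up"`/`"down"` the fitted plateau order is checked and
#'   a non-converged result returned on contradiction.
#' @return List of class `"dose_response_fit"`: ec50, hill, top, bottom,
#'   r_squared, converged, ec50_position.
#' @export
fit_dose_response <- function(doses, responses,
                              direction = c("auto", "up", "down")) {
  direction <- match.arg(direction)
  if (any(doses <= 0)) .stopf("invalid input: doses must be > 0")
  if (length(doses) != length(responses))
    .stopf("doses and responses differ in length")
  if (length(unique(doses)) < 5L)
    .stopf("need >= 5 distinct doses, got %d", length(unique(doses)))
  no_fit <- structure(list(ec50 = NA_real_, hill = NA_real_, top = NA_real_,
                           bottom = NA_real_, r_squared = NA_real_,
                           converged = FALSE,
                           ec50_position = NA_character_),
                      class = "dose_response_fit")
  if (max(responses) - min(responses) < 1e-12 * max(1, abs(mean(responses))))
    return(no_fit)

  ld <- log(doses)
  # `top` is the high-dose asymptote in this parameterization, whatever the
  # direction; initialize both plateaus from the data ends.
  lo_r <- mean(responses[ld <= stats::quantile(ld, 0.25)])
  hi_r <- mean(responses[ld >= stats::quantile(ld, 0.75)])
  start <- list(top = hi_r, bottom = lo_r,
                lec50 = stats::median(ld), hill = 1)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      responses ~ bottom + (top - bottom) / (1 + exp(hill * (lec50 - ld))),
      data = data.frame(ld = ld, responses = responses),
      start = start,
      lower = c(top = -Inf, bottom = -Inf, lec50 = min(ld) - 5,
                hill = 0.1),
      upper = c(top = Inf, bottom = Inf, lec50 = max(ld) + 5, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(no_fit)
  cf <- stats::coef(fit)
  if (direction == "up" && cf["top"] < cf["bottom"]) return(no_fit)
  if (direction == "down" && cf["top"] > cf["bottom"]) return(no_fit)
  ec50 <- exp(unname(cf["lec50"]))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  structure(list(
    ec50 = ec50, hill = unname(cf["hill"]), top = unname(cf["top"]),
    bottom = unname(cf["bottom"]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    converged = ec50 > 0,
    ec50_position = if (ec50 >= min(doses) && ec50 <= max(doses))
      "interpolated" else "extrapolated"
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) { cat("dose-response fit: not converged\n"); return(invisible(x)) }
  cat(sprintf("4PL fit: EC50 = %.3g uM (%s), hill = %.2f, top = %.3g, bottom = %.3g, R^2 = %.3f\n",
              x$ec50, x$ec50_position, x$hill, x$top, x$bottom, x$r_squared))
  invisible(x)
}
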