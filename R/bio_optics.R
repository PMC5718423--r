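#' Bio-optical chlorophyll-to-Secchi-depth model
#'
#' A Morel-type log-polynomial conversion for Case 1 (open-ocean,
#' phytoplankton-dominated) waters:
#'
#'   log10(Zsd) = c0 + c1 X + c2 X^2 + ... + cd X^d,   X = log10(chl)
#'
#' with Zsd in meters and chl in mg m^-3. An admissible model must give a
#' finite, positive, strictly decreasing Zsd over its valid chlorophyll
#' range (transparency falls as chlorophyll rises); the constructor
#' verifies this on a dense scan and refuses models that violate it.
#'
#' @param coefficients numeric vector (c0 ... cd), lowest order first
#' @param valid_chl_range chlorophyll interval (mg m^-3) over which the
#'   model is trusted; conversions outside it are flagged extrapolated
#' @param provenance free-text origin of the coefficients
#' @param n_scan points in the admissibility scan
#' @param strict refuse non-decreasing models (default). `FALSE` admits
#'   degenerate models (e.g. a constant conversion) for closed-form
#'   checks and pedagogy; such models cannot be inverted reliably
#' @return an object of class `bio_optical_model`
#' @export
bio_optical_model <- function(coefficients,
                              valid_chl_range = c(0.01, 30),
                              provenance = "unspecified",
                              n_scan = 10000L,
                              strict = TRUE) {
  coefficients <- as.numeric(coefficients)
  stopifnot(length(coefficients) >= 2L, all(is.finite(coefficients)),
            length(valid_chl_range) == 2L,
            valid_chl_range[1] > 0,
            valid_chl_range[1] < valid_chl_range[2])
  m <- structure(
    list(coefficients = coefficients,
         degree = length(coefficients) - 1L,
         valid_chl_range = as.numeric(valid_chl_range),
         provenance = provenance),
    class = "bio_optical_model"
  )
  xs <- seq(log10(valid_chl_range[1]), log10(valid_chl_range[2]),
            length.out = n_scan)
  ly <- eval_log_poly(m, xs)
  if (any(!is.finite(ly))) stop("model gives non-finite Zsd on the valid range")
  if (strict && any(diff(ly) >= 0)) {
    stop("model is not strictly decreasing in chlorophyll over ",
         "valid_chl_range [", valid_chl_range[1], ", ",
         valid_chl_range[2], "] mg m^-3")
  }
  m
}

# polynomial in X = log10(chl), returning log10(Zsd)
eval_log_poly <- function(model, x) {
  out <- 0
  for (k in rev(seq_along(model$coefficients))) {
    out <- out * x + model$coefficients[k]   # Horner
  }
  out
}

#' @export
print.bio_optical_model <- function(x, ...) {
  cat(sprintf("<bio_optical_model> degree %d, chl in [%g, %g] mg m^-3\n",
              x$degree, x$valid_chl_range[1], x$valid_chl_range[2]))
  cat("  log10(Zsd) =", paste(sprintf("%+.6g X^%d", x$coefficients,
                                      seq_along(x$coefficients) - 1L),
                              collapse = " "), "\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Package default bio-optical model
#'
#' The published conversion is a fitted closed form whose adjusted
#' coefficients are not printed in the validation study; this default is
#' a synthetic stand-in with realistic open-ocean behaviour (10 m at
#' 1 mg m^-3, ~26 m at 0.1 mg m^-3, ~3 m at 10 mg m^-3) intended for
#' simulation and for seeding [calibrate_model()]. Its provenance string
#' says so; analyses of real matchups should replace or recalibrate it.
#'
#' @return a `bio_optical_model`
#' @export
default_bio_optical_model <- function() {
  bio_optical_model(c(1.0, -0.47, -0.05, 0),
                    provenance = "package default (synthetic placeholder, not published coefficients)")
}

#' Convert chlorophyll to estimated Secchi depth
#'
#' @param chl chlorophyll-a, mg m^-3, strictly positive
#' @param model a [bio_optical_model()]
#' @return Secchi depth(s) in meters, with a logical attribute
#'   `extrapolated` marking values outside the model's valid range
#' @export
chl_to_zsd <- function(chl, model) {
  stopifnot(inherits(model, "bio_optical_model"))
  if (any(!is.finite(chl) | chl <= 0)) {
    stop("chlorophyll must be positive and finite")
  }
  zsd <- 10^eval_log_poly(model, log10(chl))
  attr(zsd, "extrapolated") <- chl < model$valid_chl_range[1] |
    chl > model$valid_chl_range[2]
  zsd
}

#' Invert the bio-optical model
#'
#' Finds the unique chlorophyll concentration mapped to a given Secchi
#' depth by bracketed root search in X = log10(chl); the model's strict
#' monotonicity over the valid range guarantees uniqueness.
#'
#' @param zsd Secchi depth(s), m; must lie in the model's attainable
#'   range over `valid_chl_range`
#' @param model a [bio_optical_model()]
#' @return chlorophyll in mg m^-3
#' @export
zsd_to_chl <- function(zsd, model) {
  stopifnot(inherits(model, "bio_optical_model"))
  lo <- log10(model$valid_chl_range[1])
  hi <- log10(model$valid_chl_range[2])
  zmax <- 10^eval_log_poly(model, lo)   # clearest: lowest chl
  zmin <- 10^eval_log_poly(model, hi)
  vapply(zsd, function(z) {
    if (!is.finite(z) || z < zmin || z > zmax) {
      stop(sprintf(
        "Secchi depth %g m outside the attainable interval [%g, %g] m",
        z, zmin, zmax))
    }
    f <- function(x) eval_log_poly(model, x) - log10(z)
    x <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    10^x
  }, numeric(1))
}

#' Recalibrate the bio-optical model against matchup data
#'
#' Least-squares refit of the log-polynomial against (chlorophyll,
#' observed Secchi depth) pairs, in log10 space. `mode = "refit"` fits all
#' coefficients; `mode = "scale"` keeps the shape and refits only the
#' intercept c0, i.e. a single multiplicative adjustment of Zsd. A fit
#' whose curve is not strictly decreasing over the data's chlorophyll
#' range is refused with a diagnostic rather than returned.
#'
#' @param model0 starting [bio_optical_model()]; fixes the degree and the
#'   valid range
#' @param chl,zsd_obs paired positive vectors, length >= degree + 2
#' @param mode "refit" or "scale"
#' @return a recalibrated `bio_optical_model` with a `fit` element
#'   holding the coefficient table (estimate, std. error), residual sd
#'   of log10(Zsd), and n
#' @export
calibrate_model <- function(model0, chl, zsd_obs,
                            mode = c("refit", "scale")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model0, "bio_optical_model"),
            length(chl) == length(zsd_obs))
  keep <- is.finite(chl) & is.finite(zsd_obs) & chl > 0 & zsd_obs > 0
  chl <- chl[keep]; zsd_obs <- zsd_obs[keep]
  d <- model0$degree
  if (length(chl) < d + 2L) {
    stop("calibration needs at least degree + 2 = ", d + 2L,
         " positive pairs, got ", length(chl))
  }
  x <- log10(chl)
  y <- log10(zsd_obs)
  if (mode == "refit") {
    X <- outer(x, 0:d, `^`)
    colnames(X) <- paste0("c", 0:d)
    if (qr(X)$rank < ncol(X)) {
      stop("rank-deficient calibration design (chlorophyll values do not ",
           "span enough of the range)")
    }
    fit <- stats::lm.fit(X, y)
    coefs <- fit$coefficients
    dof <- length(y) - length(coefs)
    sigma <- sqrt(sum(fit$residuals^2) / dof)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sigma * sqrt(diag(XtXinv))
  } else {
    shape <- eval_log_poly(model0, x) - model0$coefficients[1]
    r <- y - shape
    coefs <- model0$coefficients
    coefs[1] <- mean(r)
    dof <- length(y) - 1L
    sigma <- sqrt(sum((r - coefs[1])^2) / dof)
    se <- c(sigma / sqrt(length(y)), rep(NA_real_, d))
  }
  # admissibility over the data's chlorophyll range; the calibrated
  # model's valid range is clipped to where the data constrained it
  xs <- seq(min(x), max(x), length.out = 10000L)
  cand <- structure(list(coefficients = as.numeric(coefs), degree = d),
                    class = "bio_optical_model")
  if (any(diff(eval_log_poly(cand, xs)) >= 0)) {
    stop("calibrated fit is not strictly decreasing over the data's ",
         "chlorophyll range [", signif(10^min(x), 4), ", ",
         signif(10^max(x), 4), "] mg m^-3; fit refused")
  }
  out <- bio_optical_model(
    as.numeric(coefs),
    valid_chl_range = c(max(model0$valid_chl_range[1], 10^min(x)),
                        min(model0$valid_chl_range[2], 10^max(x))),
    provenance = sprintf("calibrated (%s) on %d pairs from: %s",
                         mode, length(y), model0$provenance),
    strict = FALSE
  )
  out$fit <- list(
    coefficients = data.frame(term = paste0("c", 0:d),
                              estimate = as.numeric(coefs),
                              std_error = as.numeric(se)),
    sigma_log10 = sigma, n = length(y), mode = mode
  )
  out
}

#' Read a bio-optical model from a key-value text file
#' @param path file path (see [write_bio_optical_model()] for the format)
#' @return a [bio_optical_model()]
#' @export
read_bio_optical_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = ":"), ""))
  get <- function(k) vals[match(k, keys)]
  bio_optical_model(
    coefficients = as.numeric(strsplit(get("coefficients"), "\\s+")[[1]]),
    valid_chl_range = as.numeric(strsplit(get("valid_chl_range"), "\\s+")[[1]]),
    provenance = get("provenance")
  )
}

#' Write a bio-optical model as a key-value text file
#' @param model a [bio_optical_model()]
#' @param path output path
#' @export
write_bio_optical_model <- function(model, path) {
  writeLines(c(
    paste("degree:", model$degree),
    paste("coefficients:", paste(format(model$coefficients, digits = 17),
                                 collapse = " ")),
    paste("valid_chl_range:", paste(format(model$valid_chl_range), collapse = " ")),
    paste("provenance:", model$provenance)
  ), path)
  invisible(path)
}
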