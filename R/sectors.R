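#' Fit a bacterial growth-law line
#'
#' Fits, by least squares, the linear relations between relative growth rate
#' and translation-sector proteome fraction that define the bacterial growth
#' laws: the translation line \eqn{\lambda = \kappa_t (\phi_R - \phi_0)}
#' (growth limited by translational activity; positive slope) or the
#' nutrition line \eqn{\lambda = \kappa_n (\phi_R^{max} - \phi_R)} (growth
#' limited by nutrient quality; negative slope). Growth rates are relative
#' (wild-type = 1, i.e. \eqn{\lambda = 1 + s}), matching the competition
#' readout.
#'
#' @param states data.frame of sector states with columns \code{phi_R} and
#'   \code{lambda} (relative growth rate; alternatively \code{s}, converted
#'   as \code{1 + s}).
#' @param type \code{"translation"} or \code{"nutrition"}; \code{"auto"}
#'   classifies by the sign of the fitted slope.
#' @return object of class \code{growth_law_fit}: \code{type}, \code{kappa}
#'   (\eqn{\kappa_t} or \eqn{\kappa_n} > 0), \code{phi0} (translation) or
#'   \code{phi_max} (nutrition), \code{slope}, \code{intercept},
#'   \code{residuals}, \code{data}.
#' @examples
#' st <- data.frame(phi_R = c(0.2, 0.3, 0.4), lambda = 5 * (c(0.2, 0.3, 0.4) - 0.1))
#' fit_growth_line(st, "translation")
#' @export
fit_growth_line <- function(states, type = c("translation", "nutrition",
                                             "auto")) {
  type <- match.arg(type)
  if (!"lambda" %in% names(states) && "s" %in% names(states))
    states$lambda <- 1 + states$s
  stopifnot(all(c("phi_R", "lambda") %in% names(states)))
  if (nrow(states) < 2) stop("need at least 2 states")
  if (length(unique(states$phi_R)) < 2)
    stop("degenerate input: all phi_R values are equal")
  fit <- lm(lambda ~ phi_R, data = states)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (type == "auto") type <- if (slope >= 0) "translation" else "nutrition"
  if (type == "translation") {
    if (slope <= 0) warning("translation line fitted with non-positive slope")
    kappa <- slope; phi0 <- -intercept / slope
    out <- list(type = type, kappa = kappa, phi0 = phi0)
  } else {
    if (slope >= 0) warning("nutrition line fitted with non-negative slope")
    kappa <- -slope; phi_max <- intercept / kappa
    out <- list(type = type, kappa = kappa, phi_max = phi_max)
  }
  out$slope <- slope; out$intercept <- intercept
  out$residuals <- unname(residuals(fit)); out$data <- states; out$lm <- fit
  structure(out, class = "growth_law_fit")
}

#' @export
print.growth_law_fit <- function(x, ...) {
  if (x$type == "translation")
    cat(sprintf("Translation line: lambda = %.3f (phi_R - %.4f)\n",
                x$kappa, x$phi0))
  else
    cat(sprintf("Nutrition line: lambda = %.3f (%.4f - phi_R)\n",
                x$kappa, x$phi_max))
  invisible(x)
}

#' @export
coef.growth_law_fit <- function(object, ...) {
  if (object$type == "translation")
    c(kappa_t = object$kappa, phi0 = object$phi0)
  else c(kappa_n = object$kappa, phi_max = object$phi_max)
}

#' @export
predict.growth_law_fit <- function(object, newdata = NULL, ...) {
  phi <- if (is.null(newdata)) object$data$phi_R else newdata$phi_R
  object$intercept + object$slope * phi
}

#' @export
plot.growth_law_fit <- function(x, ...) {
  plot(x$data$phi_R, x$data$lambda, xlab = expression(phi[R]),
       ylab = "relative growth rate", pch = 19, ...)
  abline(x$intercept, x$slope)
  invisible(x)
}

#' Predicted proteome compression from gratuitous expression
#'
#' Given an excess gratuitous proteome fraction \code{phi_U} (e.g. a
#' massively induced stress regulon), predicts the compression of the
#' translation sector and the growth defect under two models:
#' \describe{
#'   \item{proportional}{all other proteome fractions scale by
#'     \eqn{(1 - \phi_U)} and the growth defect is one-to-one,
#'     \eqn{\Delta s = -\phi_U} (the empirical one-to-one compression).}
#'   \item{growth_law}{the steady state is the intersection of the
#'     translation and nutrition lines with the allocatable proteome reduced,
#'     \eqn{\phi_R^{max} \to \phi_R^{max} - \phi_U}; the implied relative
#'     growth-rate change is returned (growth-law model, reconstructed from
#'     the fitted line parameters).}
#' }
#'
#' @param phi_U excess gratuitous fraction(s), in [0, 1).
#' @param fits for \code{model = "growth_law"}, a list with elements
#'   \code{translation} and \code{nutrition} (two
#'   \code{\link{growth_law_fit}} objects); unused for proportional.
#' @param model \code{"proportional"} or \code{"growth_law"}.
#' @return data.frame: \code{phi_U}, \code{phi_R_factor} (multiplicative
#'   change of the translation sector), \code{delta_s} (change in relative
#'   growth rate).
#' @export
predict_compression <- function(phi_U, fits = NULL,
                                model = c("proportional", "growth_law")) {
  model <- match.arg(model)
  if (any(phi_U < 0)) stop("'phi_U' must be non-negative")
  if (model == "proportional") {
    return(data.frame(phi_U = phi_U, phi_R_factor = 1 - phi_U,
                      delta_s = -phi_U))
  }
  tr <- fits$translation; nu <- fits$nutrition
  if (is.null(tr) || is.null(nu) || tr$type != "translation" ||
      nu$type != "nutrition")
    stop("growth_law model needs fitted translation and nutrition lines")
  kt <- tr$kappa; p0 <- tr$phi0; kn <- nu$kappa; pmax <- nu$phi_max
  if (any(phi_U >= pmax - p0))
    stop("no feasible steady state: phi_U >= phi_R^max - phi0")
  lam0 <- kt * kn * (pmax - p0) / (kt + kn)
  lam <- kt * kn * (pmax - phi_U - p0) / (kt + kn)
  phi_star <- p0 + lam0 / kt
  phi_u <- p0 + lam / kt
  data.frame(phi_U = phi_U, phi_R_factor = phi_u / phi_star,
             delta_s = (lam - lam0) / lam0)
}

#' Slopes of a perturbation trajectory in sector space
#'
#' For a series of sector states ordered by perturbation strength, fits the
#' least-squares slopes of the translation-sector fraction and of the growth
#' difference against the excess gratuitous fraction, with confidence
#' intervals, and flags whether the one-to-one (-1) slope lies inside each
#' CI.
#'
#' @param states data.frame with columns \code{phi_U}, and \code{phi_R}
#'   and/or \code{delta_s}.
#' @param conf confidence level for the slope CIs.
#' @return list of class \code{trajectory_report}; per response a list with
#'   \code{slope}, \code{ci}, \code{covers_minus1}.
#' @export
trajectory_report <- function(states, conf = 0.95) {
  stopifnot("phi_U" %in% names(states))
  if (length(unique(states$phi_U)) < 2) stop("need >= 2 distinct phi_U")
  one <- function(y) {
    fit <- lm(y ~ phi_U, data = cbind(states, y = y))
    ci <- suppressWarnings(as.numeric(confint(fit, "phi_U", level = conf)))
    slope <- unname(coef(fit)[2])
    if (anyNA(ci)) ci <- c(slope, slope)  # exact fit: zero-width CI
    list(slope = slope, ci = ci,
         covers_minus1 = ci[1] <= -1 && -1 <= ci[2])
  }
  out <- list(conf = conf)
  if ("phi_R" %in% names(states)) out$phi_R <- one(states$phi_R)
  if ("delta_s" %in% names(states)) out$delta_s <- one(states$delta_s)
  structure(out, class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  for (nm in intersect(c("phi_R", "delta_s"), names(x))) {
    e <- x[[nm]]
    cat(sprintf("%s vs phi_U: slope %.3f [%.3f, %.3f]%s\n", nm, e$slope,
                e$ci[1], e$ci[2],
                if (e$covers_minus1) " (consistent with one-to-one)" else ""))
  }
  invisible(x)
}
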