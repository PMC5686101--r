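#' Fit the saturating-exponential CMR-versus-population-size curve
#'
#' The CMR is near-constant for large populations and drops exponentially
#' for small ones; the fitted form is `CMR(N) = a - b * exp(-c * N)` with
#' `a, b, c > 0` (plateau `a`, depth `b`, rate `c`), estimated by nonlinear
#' least squares. Starting values come from the data: `a` from the largest
#' CMR, `b` from the plateau-to-minimum drop, `c` from `1 / median(N)`.
#'
#' @param data A data frame of CMR estimates against population size.
#' @param n_col,cmr_col Column names (strings) for population size and CMR.
#' @return A `cmr_exp_fit`: the underlying `nls` fit plus the residual sum
#'   of squares; see [tidy.cmr_exp_fit()] and [glance.cmr_exp_fit()].
#' @examples
#' d <- data.frame(N = c(10, 50, 100, 500, 1000),
#'                 cmr = 3e-4 - 2e-4 * exp(-0.02 * c(10, 50, 100, 500, 1000)))
#' coef(fit_exponential(d))
#' @export
fit_exponential <- function(data, n_col = "N", cmr_col = "cmr") {
  N <- data[[n_col]]
  y <- data[[cmr_col]]
  ok <- stats::complete.cases(N, y)
  N <- N[ok]
  y <- y[ok]
  if (length(N) < 4) {
    stop("fit_exponential needs at least 4 (N, CMR) points, got ",
         length(N))
  }
  if (diff(range(y)) <= .Machine$double.eps^0.5 * max(abs(y))) {
    # flat curve: the model degenerates to the plateau alone
    cf <- c(a = mean(y), b = 0, cc = 1 / median(N))
    return(structure(
      list(fit = NULL, coef = cf, rss = sum((y - mean(y))^2),
           data = tibble::tibble(N = N, cmr = y)),
      class = "cmr_exp_fit"
    ))
  }
  start <- list(a = max(y), b = max(max(y) - min(y), 1e-6 * max(y)),
                cc = 1 / median(N))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a - b * exp(-cc * N), start = start,
                      lower = c(a = 0, b = 0, cc = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("exponential CMR fit failed to converge: ", conditionMessage(e),
           "\n  starting values were a=", signif(start$a, 4),
           " b=", signif(start$b, 4), " cc=", signif(start$cc, 4))
    }
  )
  structure(
    list(fit = fit, coef = coef(fit),
         rss = sum(stats::residuals(fit)^2),
         data = tibble::tibble(N = N, cmr = y)),
    class = "cmr_exp_fit"
  )
}

#' @export
coef.cmr_exp_fit <- function(object, ...) object$coef

#' @export
predict.cmr_exp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  cf <- object$coef
  cf[["a"]] - cf[["b"]] * exp(-cf[["cc"]] * newdata$N)
}

#' @export
print.cmr_exp_fit <- function(x, ...) {
  cat("<cmr_exp_fit> CMR(N) = a - b * exp(-c * N)\n")
  cat(sprintf("  a = %.4g, b = %.4g, c = %.4g, RSS = %.3g\n",
              x$coef[["a"]], x$coef[["b"]], x$coef[["cc"]], x$rss))
  invisible(x)
}

#' Tidy the exponential CMR fit
#' @param x A `cmr_exp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @exportS3Method generics::tidy
tidy.cmr_exp_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"), estimate = unname(x$coef))
}

#' One-row summary of the exponential CMR fit
#' @param x A `cmr_exp_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the parameters, RSS and point count.
#' @exportS3Method generics::glance
glance.cmr_exp_fit <- function(x, ...) {
  tibble::tibble(a = x$coef[["a"]], b = x$coef[["b"]], c = x$coef[["cc"]],
                 rss = x$rss, n = nrow(x$data))
}

#' Fit the quadratic CMR-versus-gene-number curve in log-log space
#'
#' Ordinary least squares of `log10(CMR)` on `log10(n)` and `log10(n)^2`,
#' the coordinate system in which CMR-against-gene-number curves are
#' straightest; a pure power law `CMR ~ n^s` appears with quadratic
#' coefficient 0 and linear coefficient `s`.
#'
#' @param data A data frame of CMR estimates against gene number.
#' @param n_col,cmr_col Column names (strings) for gene number and CMR.
#' @return A `cmr_loglog_fit` wrapping the `lm` fit.
#' @export
fit_quadratic_loglog <- function(data, n_col = "genes", cmr_col = "cmr") {
  n <- data[[n_col]]
  y <- data[[cmr_col]]
  ok <- stats::complete.cases(n, y)
  n <- n[ok]
  y <- y[ok]
  if (length(n) < 3) stop("need at least 3 (gene number, CMR) points")
  if (any(n <= 0) || any(y <= 0)) {
    stop("gene numbers and CMRs must be positive for the log-log fit")
  }
  lx <- log10(n)
  ly <- log10(y)
  fit <- lm(ly ~ lx + I(lx^2))
  cf <- coef(fit)
  structure(
    list(fit = fit,
         coef = c(intercept = unname(cf[1]), linear = unname(cf[2]),
                  quadratic = unname(cf[3])),
         residuals = unname(stats::residuals(fit)),
         data = tibble::tibble(genes = n, cmr = y)),
    class = "cmr_loglog_fit"
  )
}

#' @export
coef.cmr_loglog_fit <- function(object, ...) object$coef

#' @export
print.cmr_loglog_fit <- function(x, ...) {
  cat("<cmr_loglog_fit> log10(CMR) ~ log10(n) + log10(n)^2\n")
  cat(sprintf("  intercept = %.4g, linear = %.4g, quadratic = %.4g\n",
              x$coef[["intercept"]], x$coef[["linear"]],
              x$coef[["quadratic"]]))
  invisible(x)
}

#' Tidy the log-log quadratic fit
#' @param x A `cmr_loglog_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient.
#' @exportS3Method generics::tidy
tidy.cmr_loglog_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' One-row summary of the log-log quadratic fit
#' @param x A `cmr_loglog_fit`.
#' @param ... Unused.
#' @return A one-row tibble with coefficients, RSS and point count.
#' @exportS3Method generics::glance
glance.cmr_loglog_fit <- function(x, ...) {
  tibble::tibble(intercept = x$coef[["intercept"]],
                 linear = x$coef[["linear"]],
                 quadratic = x$coef[["quadratic"]],
                 rss = sum(x$residuals^2), n = nrow(x$data))
}

#' Biological mutation-rate bands for plot annotation
#'
#' Collapses the bundled per-base per-generation mutation-rate table into
#' one band (min, max) per species, for overlay on simulated CMR curves.
#' Purely presentational: the bands never feed the simulator.
#'
#' @param rates The `bio_rates` fixture ([load_fixture()]); any subset may
#'   be passed (an empty table yields no annotations).
#' @return A tibble with `species`, `rate_min`, `rate_max`.
#' @examples
#' reference_overlay(load_fixture("bio_rates"))
#' @export
reference_overlay <- function(rates = load_fixture("bio_rates")) {
  if (nrow(rates) == 0) {
    return(tibble::tibble(species = character(), rate_min = numeric(),
                          rate_max = numeric()))
  }
  rates |>
    dplyr::filter(.data$basis == "per_base",
                  .data$unit == "per_generation") |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(rate_min = min(.data$rate_min),
                     rate_max = max(.data$rate_max), .groups = "drop")
}

#' Plot a CMR curve against population size
#'
#' Points are the CMR estimates; when 4 or more points are available the
#' saturating-exponential fit of [fit_exponential()] is drawn through them.
#'
#' @param data A data frame with population-size and CMR columns.
#' @param n_col,cmr_col Column names (strings).
#' @param group_col Optional column naming the swept covariate, one fitted
#'   line per level.
#' @return A ggplot object.
#' @export
plot_cmr_curve <- function(data, n_col = "N", cmr_col = "cmr",
                           group_col = NULL) {
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data[[n_col]], y = .data[[cmr_col]])
  )
  if (!is.null(group_col)) {
    p <- p + ggplot2::aes(colour = factor(.data[[group_col]])) +
      ggplot2::labs(colour = group_col)
  }
  p <- p + ggplot2::geom_point()
  add_line <- function(d) {
    if (nrow(d) < 4) return(NULL)
    f <- fit_exponential(d, n_col = n_col, cmr_col = cmr_col)
    grid <- data.frame(N = seq(min(d[[n_col]]), max(d[[n_col]]),
                               length.out = 200))
    out <- data.frame(grid$N, predict(f, grid))
    names(out) <- c(n_col, cmr_col)
    out
  }
  lines <- if (is.null(group_col)) {
    add_line(data)
  } else {
    dplyr::bind_rows(lapply(split(data, data[[group_col]]), function(d) {
      ln <- add_line(d)
      if (!is.null(ln)) ln[[group_col]] <- d[[group_col]][1]
      ln
    }))
  }
  if (!is.null(lines) && nrow(lines) > 0) {
    p <- p + ggplot2::geom_line(data = lines)
  }
  p + ggplot2::labs(x = "population size N", y = "critical mutation rate")
}

#' Plot CMR against gene number on log-log axes
#'
#' Adds the quadratic log-log fit, an optional `1/L` reference line, and
#' optional biological mutation-rate bands from [reference_overlay()].
#'
#' @param data A data frame with gene-number and CMR columns.
#' @param n_col,cmr_col Column names (strings).
#' @param gene_length Gene length for the `1/(n * L)` reference line
#'   (`NULL` to omit).
#' @param bands Optional [reference_overlay()] tibble.
#' @return A ggplot object.
#' @export
plot_cmr_gene_number <- function(data, n_col = "genes", cmr_col = "cmr",
                                 gene_length = NULL, bands = NULL) {
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data[[n_col]], y = .data[[cmr_col]])
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10()
  if (nrow(data) >= 3) {
    f <- fit_quadratic_loglog(data, n_col = n_col, cmr_col = cmr_col)
    gx <- exp(seq(log(min(data[[n_col]])), log(max(data[[n_col]])),
                  length.out = 200))
    lx <- log10(gx)
    gy <- 10^(f$coef[["intercept"]] + f$coef[["linear"]] * lx +
                f$coef[["quadratic"]] * lx^2)
    ln <- data.frame(gx, gy)
    names(ln) <- c(n_col, cmr_col)
    p <- p + ggplot2::geom_line(data = ln)
  }
  if (!is.null(gene_length)) {
    rf <- data.frame(x = range(data[[n_col]]))
    rf$y <- 1 / (rf$x * gene_length)
    p <- p + ggplot2::geom_line(
      data = rf, ggplot2::aes(x = .data$x, y = .data$y),
      linetype = "dashed", colour = "grey40"
    )
  }
  if (!is.null(bands) && nrow(bands) > 0) {
    p <- p + ggplot2::geom_hline(
      data = bands,
      ggplot2::aes(yintercept = .data$rate_min, colour = .data$species),
      linetype = "dotted"
    ) +
      ggplot2::geom_hline(
        data = bands,
        ggplot2::aes(yintercept = .data$rate_max, colour = .data$species),
        linetype = "dotted"
      )
  }
  p + ggplot2::labs(x = "gene number", y = "critical mutation rate")
}

#' @exportS3Method ggplot2::autoplot
autoplot.cmr_estimate <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d[!d$censored, ], ggplot2::aes(x = .data$cmr)) +
    ggplot2::geom_histogram(bins = max(5, nrow(d) %/% 2)) +
    ggplot2::geom_vline(xintercept = object$mean, colour = "red") +
    ggplot2::labs(x = "batch CMR", y = "batches")
}
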