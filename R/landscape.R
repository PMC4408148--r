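# Quasi-Poisson GLMs with interaction terms and analysis-of-deviance
# F-tests linking introgression rates and flower-visitor diversity to
# landscape covariates.

#' Fit a quasi-Poisson GLM
#'
#' Log-link quasi-Poisson regression (variance proportional to the mean)
#' fitted by iteratively reweighted least squares. Point estimates are
#' identical to the Poisson-likelihood estimates; the dispersion `phi` is
#' the Pearson statistic over the residual degrees of freedom and affects
#' inference only.
#'
#' @param formula model formula.
#' @param data data.frame with the response and covariates.
#' @param weights optional prior weights.
#' @return object of class `qp_fit`: the underlying `glm` object plus
#'   `dispersion`, `coefficients`, `deviance`, `df_residual`.
#' @export
fit_quasipoisson <- function(formula, data, weights = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0)) stop("negative response values")
  X <- stats::model.matrix(formula, data)
  if (qr(X)$rank < ncol(X)) {
    fit0 <- stats::lm.fit(X, rep(1, nrow(X)))
    aliased <- colnames(X)[is.na(fit0$coefficients)]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  args <- list(formula, data = data,
               family = stats::quasipoisson(link = "log"),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!is.null(weights)) args$weights <- weights
  fit <- do.call(stats::glm, args)
  if (!fit$converged)
    stop("IRLS did not converge in ", fit$iter, " iterations")
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  df_res <- fit$df.residual
  if (df_res < 1) stop("no residual degrees of freedom")
  phi <- pearson / df_res
  flag <- character(0)
  if (phi < .Machine$double.eps) {
    phi <- .Machine$double.eps
    flag <- "dispersion floored at machine epsilon"
  }
  structure(list(glm = fit, coefficients = stats::coef(fit),
                 dispersion = phi, deviance = stats::deviance(fit),
                 df_residual = df_res, n = length(y), flag = flag),
            class = "qp_fit")
}

#' @export
print.qp_fit <- function(x, ...) {
  cat("quasi-Poisson GLM:",
      deparse(stats::formula(x$glm)), "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  dispersion phi = %.3f, deviance = %.2f on %d df\n",
              x$dispersion, x$deviance, x$df_residual))
  invisible(x)
}

#' Analysis-of-deviance F-test between nested quasi-Poisson fits
#'
#' `F = (deviance_nested - deviance_full) / (df_diff * phi_full)`, with
#' the p-value from `F(df_diff, df_residual_full)`.
#'
#' @param fit_nested,fit_full `qp_fit` objects; `fit_nested` must be
#'   nested in `fit_full` (same data).
#' @return one-row data.frame: `F`, `df1`, `df2`, `p`.
#' @export
anova_f <- function(fit_nested, fit_full) {
  stopifnot(inherits(fit_nested, "qp_fit"), inherits(fit_full, "qp_fit"))
  if (fit_nested$n != fit_full$n)
    stop("fits are on different data")
  ddev <- fit_nested$deviance - fit_full$deviance
  ddf <- fit_nested$df_residual - fit_full$df_residual
  if (ddf < 0 || ddev < -1e-8)
    stop("fit_nested must be nested in fit_full")
  if (ddf == 0)
    return(data.frame(F = 0, df1 = 0, df2 = fit_full$df_residual, p = 1))
  Fv <- max(ddev, 0) / (ddf * fit_full$dispersion)
  data.frame(F = Fv, df1 = ddf, df2 = fit_full$df_residual,
             p = stats::pf(Fv, ddf, fit_full$df_residual,
                           lower.tail = FALSE))
}

# Sequential (type-I) term table: terms added in the given order, each
# tested against the dispersion of the full fit.
sequential_anova <- function(response, terms, data) {
  forms <- vapply(seq_along(terms), function(i)
    paste(response, "~", paste(terms[seq_len(i)], collapse = " + ")),
    character(1))
  null_form <- paste(response, "~ 1")
  fits <- c(list(fit_quasipoisson(stats::as.formula(null_form), data)),
            lapply(forms, function(f)
              fit_quasipoisson(stats::as.formula(f), data)))
  full <- fits[[length(fits)]]
  rows <- lapply(seq_along(terms), function(i) {
    nested <- fits[[i]]
    ddev <- nested$deviance - fits[[i + 1]]$deviance
    ddf <- nested$df_residual - fits[[i + 1]]$df_residual
    Fv <- if (ddf > 0) max(ddev, 0) / (ddf * full$dispersion) else 0
    p <- if (ddf > 0)
      stats::pf(Fv, ddf, full$df_residual, lower.tail = FALSE) else 1
    data.frame(term = terms[i], F = Fv, df1 = ddf,
               df2 = full$df_residual, p = p,
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), fit = full)
}

#' Landscape models of the introgression rate (models 1 and 2)
#'
#' Model 1 regresses the per-individual crop-ancestry response on
#' cultivated-apple density, the number of orchards, and their
#' interaction; model 2 replaces orchard number with orchard area. Both
#' are quasi-Poisson with sequential (type-I) F-tests in that term order.
#' Individuals at sites missing from the landscape table are dropped with
#' a warning. The correlation between orchard number and area is reported
#' alongside (the two covariates are strongly collinear, hence the two
#' separate models). A site-level response alternative (mean crop ancestry
#' per site) is available via `granularity = "site"`.
#'
#' @param classified data.frame with `site_id` and `crop_ancestry` per
#'   individual (e.g. from the classification stage or
#'   [simulate_site_individuals()]).
#' @param landscape data.frame with `site_id`, `apple_density`,
#'   `n_orchards`, `orchard_area`.
#' @param granularity `"individual"` (default) or `"site"`.
#' @return list with elements `model1`, `model2` (each: `table`, `fit`),
#'   and `covariate_correlation` (Pearson r between `n_orchards` and
#'   `orchard_area`).
#' @export
run_model_1_2 <- function(classified, landscape,
                          granularity = c("individual", "site")) {
  granularity <- match.arg(granularity)
  need <- c("site_id", "apple_density", "n_orchards", "orchard_area")
  stopifnot(all(need %in% names(landscape)),
            all(c("site_id", "crop_ancestry") %in% names(classified)))
  miss <- !classified$site_id %in% landscape$site_id
  if (any(miss)) {
    warning(sum(miss), " individual(s) at sites without landscape ",
            "covariates dropped")
    classified <- classified[!miss, , drop = FALSE]
  }
  if (granularity == "site") {
    agg <- stats::aggregate(crop_ancestry ~ site_id, classified, mean)
    classified <- agg
  }
  d <- merge(classified, landscape, by = "site_id")
  m1 <- sequential_anova("crop_ancestry",
                         c("apple_density", "n_orchards",
                           "apple_density:n_orchards"), d)
  m2 <- sequential_anova("crop_ancestry",
                         c("apple_density", "orchard_area",
                           "apple_density:orchard_area"), d)
  list(model1 = m1, model2 = m2,
       covariate_correlation = stats::cor(landscape$n_orchards,
                                          landscape$orchard_area))
}

#' Visitor-diversity model (model 3)
#'
#' Tests whether flower-visitor taxon richness depends on the intensity of
#' cultivation and management, controlling for insect order. At
#' `granularity = "cells"` the response is the distinct-taxon count per
#' order x management-class cell; at `"observation"` every observation
#' record contributes the distinct-taxon count of its cell (inflating n to
#' the number of observations). The granularity must be chosen explicitly:
#' the two give different residual degrees of freedom.
#'
#' @param visitors data.frame with `taxon_id`, `insect_order`,
#'   `management_class` (see [simulate_visitor_observations()]).
#' @param granularity `"cells"` or `"observation"` — no default.
#' @return list: `table` (sequential F-tests for management class then
#'   order), `fit`, `cells` (the richness table), `granularity`.
#' @export
run_model_3 <- function(visitors, granularity) {
  if (missing(granularity))
    stop("model 3 granularity must be chosen explicitly: ",
         '"cells" or "observation"')
  granularity <- match.arg(granularity, c("cells", "observation"))
  stopifnot(all(c("taxon_id", "insect_order", "management_class") %in%
                  names(visitors)))
  if (length(unique(visitors$insect_order)) < 2)
    warning("single insect order present: order term is degenerate")
  cells <- stats::aggregate(taxon_id ~ insect_order + management_class,
                            visitors,
                            function(v) length(unique(v)))
  names(cells)[3] <- "richness"
  data3 <- if (granularity == "cells") cells else {
    key <- paste(visitors$insect_order, visitors$management_class)
    ckey <- paste(cells$insect_order, cells$management_class)
    data.frame(insect_order = visitors$insect_order,
               management_class = visitors$management_class,
               richness = cells$richness[match(key, ckey)],
               stringsAsFactors = FALSE)
  }
  terms <- c("management_class", "insect_order")
  if (length(unique(data3$insect_order)) < 2) terms <- terms[1]
  res <- sequential_anova("richness", terms, data3)
  list(table = res$table, fit = res$fit, cells = cells,
       granularity = granularity)
}
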