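# Negative-binomial regression of occurrences per species on public
# interest (web-page counts) and taxonomic research effort (order-level
# publication counts), with the species-selection and outlier-exclusion
# rules used for the per-class models.

#' Select species for a per-class model
#'
#' `Best` takes the `n_target` species with the most occurrences
#' (deterministic tie-break: count descending, then name ascending);
#' `Random` draws a uniform sample without replacement from all recorded
#' species.  When fewer than `n_target` species exist, all are taken.
#'
#' @param species_counts data.frame with columns `species` and `n_occ`.
#' @param mode `"Best"` or `"Random"`.
#' @param n_target sample size (default 1000).
#' @param seed RNG seed (Random mode).
#' @return character vector of selected species names.
#' @export
select_species <- function(species_counts, mode = c("Best", "Random"),
                           n_target = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  sc <- as.data.table(species_counts)
  if (nrow(sc) <= n_target) return(sort(sc$species))
  if (mode == "Best") {
    setorderv(sc, c("n_occ", "species"), order = c(-1L, 1L))
    sc$species[seq_len(n_target)]
  } else {
    set.seed(seed)
    sample(sc$species, n_target, replace = FALSE)
  }
}

#' Exclude extreme species before model fitting
#'
#' A species is an outlier when its occurrence count or its web-search
#' count exceeds `Q3 + multiplier * IQR` for that variable, with Q3 and IQR
#' computed on the selected set before any exclusion (single pass, no
#' re-iteration).  Quantiles use the linear-interpolation convention
#' (R type 7).
#'
#' @param data data.frame with columns `species`, `n_occ`, `interest`.
#' @param multiplier IQR multiplier (default 4).
#' @return the retained rows (same columns).
#' @export
remove_outliers <- function(data, multiplier = 4) {
  dt <- as.data.table(data)
  thr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    q[2] + multiplier * (q[2] - q[1])
  }
  t_occ <- thr(dt$n_occ)
  t_int <- thr(dt$interest)
  dt[n_occ <= t_occ & interest <= t_int]
}

#' Fit the per-class negative-binomial model
#'
#' Log-link negative binomial regression of occurrences per species on the
#' transformed public-interest and research covariates and their
#' interaction: `n_occ ~ t(interest) * t(research)` with `t = log1p` by
#' default (web counts span several orders of magnitude; the transform
#' keeps the linear predictor numerically stable; `identity` is available).
#' The dispersion (theta) is estimated by maximum likelihood
#' ([MASS::glm.nb()]); per-coefficient p-values are Wald tests.
#'
#' @param data data.frame with columns `n_occ`, `interest`, `research`
#'   (after selection and outlier removal).
#' @param transform `"log1p"` (default) or `"identity"`.
#' @param alpha significance threshold (default 0.05).
#' @return an object of class `occbias_nbfit`: list with `coefficients`,
#'   `signs`, `p_values`, `significant`, `theta` (NB dispersion),
#'   `converged`, `n_species_used`, and the underlying `model`.
#' @export
fit_nb_glm <- function(data, transform = c("log1p", "identity"),
                       alpha = 0.05) {
  transform <- match.arg(transform)
  dt <- as.data.frame(data)
  if (nrow(dt) < 30L) stop("need at least 30 species to fit; got ", nrow(dt))
  tf <- if (transform == "log1p") log1p else identity
  df <- data.frame(
    n_occ = dt$n_occ,
    interest = tf(dt$interest),
    research = tf(dt$research)
  )
  if (stats::var(df$n_occ) <= mean(df$n_occ)) {
    message("response variance <= mean: little overdispersion in this set")
  }
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(n_occ ~ interest * research, data = df,
                                  control = stats::glm.control(maxit = 100))),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(
      coefficients = NULL, signs = NULL, p_values = NULL, significant = NULL,
      theta = NA_real_, converged = FALSE, n_species_used = nrow(df),
      message = conditionMessage(fit), model = NULL, transform = transform
    ), class = "occbias_nbfit"))
  }
  sm <- summary(fit)$coefficients
  co <- sm[, "Estimate"]
  pv <- sm[, "Pr(>|z|)"]
  names(co) <- names(pv) <- c("(Intercept)", "interest", "research",
                              "interest:research")
  structure(list(
    coefficients = co,
    signs = ifelse(co > 0, "+", "-"),
    p_values = pv,
    significant = pv < alpha,
    theta = fit$theta,
    converged = isTRUE(fit$converged) && is.null(fit$th.warn),
    n_species_used = nrow(df),
    model = fit,
    transform = transform
  ), class = "occbias_nbfit")
}

#' @export
print.occbias_nbfit <- function(x, ...) {
  cat("Negative-binomial fit on", x$n_species_used, "species",
      if (!x$converged) "(NOT converged)" else "", "\n")
  if (!is.null(x$coefficients)) {
    tab <- data.frame(
      estimate = round(x$coefficients, 4),
      sign = x$signs, p = signif(x$p_values, 3),
      sig = ifelse(x$significant, "*", "")
    )
    print(tab)
    cat("theta (NB dispersion):", round(x$theta, 3), "\n")
  }
  invisible(x)
}

#' Profile 95% confidence intervals of a negative-binomial fit
#' @param fit an `occbias_nbfit`.
#' @param level confidence level.
#' @return matrix with one row per coefficient.
#' @export
nb_confint <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "occbias_nbfit"), !is.null(fit$model))
  ci <- suppressWarnings(suppressMessages(stats::confint(fit$model, level = level)))
  rownames(ci) <- names(fit$coefficients)
  ci
}

#' Residual-homogeneity diagnostics of a fit
#'
#' Pairs deviance residuals with fitted means and computes a trend
#' statistic - the slope of |residual| on the fitted mean - whose p-value
#' flags residual-variance heterogeneity.
#'
#' @param fit an `occbias_nbfit`.
#' @return list with `residuals`, `fitted`, `trend_slope`, `trend_p`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "occbias_nbfit"), !is.null(fit$model))
  res <- stats::residuals(fit$model, type = "deviance")
  mu <- stats::fitted(fit$model)
  tr <- stats::lm(abs(res) ~ mu)
  sm <- summary(tr)$coefficients
  list(
    residuals = as.numeric(res),
    fitted = as.numeric(mu),
    trend_slope = sm["mu", "Estimate"],
    trend_p = sm["mu", "Pr(>|t|)"]
  )
}

#' Run the per-class model battery
#'
#' For each class: select the best-represented species and a random species
#' set, remove outliers, and fit the negative-binomial model, producing one
#' results row per (class, selection).  When a class has no more than
#' `n_target` recorded species, a single model is fitted (selection
#' `"All"`).
#'
#' @param cov_table covariate table with columns `species`, `class_name`,
#'   `order_name`, `n_occ`, `interest`, `research`.
#' @param n_target species per selection (default 1000).
#' @param seed base RNG seed for the Random selections.
#' @param transform covariate transform passed to [fit_nb_glm()].
#' @param multiplier IQR multiplier for [remove_outliers()].
#' @return list with `table` (one row per model: class, selection,
#'   n_species, sign/p per term, converged) and `fits` (the fit objects).
#' @export
glm_battery <- function(cov_table, n_target = 1000L, seed = 1L,
                        transform = "log1p", multiplier = 4) {
  dt <- as.data.table(cov_table)
  classes <- sort(unique(dt$class_name))
  fits <- list(); rows <- list()
  for (cl in classes) {
    sub <- dt[class_name == cl]
    modes <- if (nrow(sub) <= n_target) "All" else c("Best", "Random")
    for (mode in modes) {
      sel <- if (mode == "All") sub$species else
        select_species(sub[, .(species, n_occ)], mode, n_target,
                       seed = seed + match(cl, classes))
      kept <- remove_outliers(sub[species %in% sel], multiplier = multiplier)
      fit <- tryCatch(fit_nb_glm(kept, transform = transform),
                      error = function(e) e)
      key <- paste(cl, mode, sep = ".")
      fits[[key]] <- fit
      if (inherits(fit, "error")) {
        rows[[key]] <- data.table(class = cl, selection = mode,
                                  n_species = nrow(kept), converged = FALSE)
      } else {
        rows[[key]] <- data.table(
          class = cl, selection = mode, n_species = fit$n_species_used,
          interest_sign = fit$signs[["interest"]],
          interest_p = fit$p_values[["interest"]],
          research_sign = fit$signs[["research"]],
          research_p = fit$p_values[["research"]],
          interaction_sign = fit$signs[["interest:research"]],
          interaction_p = fit$p_values[["interest:research"]],
          converged = fit$converged
        )
      }
    }
  }
  list(table = rbindlist(rows, fill = TRUE), fits = fits)
}
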