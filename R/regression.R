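#' Univariate screening of candidate predictors
#'
#' Each candidate is regressed on the response in a simple linear model;
#' \code{"sport"} enters as a block of three dummies (tennis reference) with a
#' joint F-test. Candidates with p below \code{alpha_in} are kept, ranked by
#' explained variance. Constant (degenerate) candidates are excluded with a
#' warning record instead of an error.
#'
#' @param cohort Data frame with one record per athlete (see [synth_cohort()]
#'   for the column conventions; \code{sport} must be a factor or character).
#' @param response Response column name (per-kg scale by convention).
#' @param candidates Character vector of candidate column names;
#'   \code{"sport"} is treated as the dummy block.
#' @param alpha_in Inclusion threshold on the univariate p-value (default
#'   0.10).
#' @return A tibble with columns \code{candidate}, \code{r_squared}, \code{p},
#'   \code{n}, \code{keep}, ranked by \code{r_squared}; excluded degenerate
#'   candidates are attached as the \code{"warnings"} attribute.
#' @export
univariate_screen <- function(cohort, response, candidates, alpha_in = 0.10) {
  stopifnot(response %in% names(cohort))
  rows <- list()
  warn <- character()
  for (cand in candidates) {
    if (!cand %in% names(cohort)) {
      stop("candidate '", cand, "' is not a cohort column", call. = FALSE)
    }
    dat <- cohort[stats::complete.cases(cohort[, c(response, cand)]),
                  c(response, cand)]
    if (nrow(dat) < 3L) {
      warn <- c(warn, paste0(cand, ": fewer than 3 complete pairs"))
      next
    }
    x <- dat[[cand]]
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) x <- droplevels(x)
    degenerate <- if (is.factor(x)) nlevels(x) < 2L else
      isTRUE(stats::var(x) == 0) || !is.finite(stats::var(x))
    if (degenerate) {
      warn <- c(warn, paste0(cand, ": constant in the cohort, excluded"))
      next
    }
    if (is.factor(x) && "tennis" %in% levels(x)) {
      x <- stats::relevel(x, ref = "tennis")
    }
    fit <- stats::lm(dat[[response]] ~ x)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      candidate = cand, r_squared = sm$r.squared, p = unname(p),
      n = nrow(dat), keep = unname(p) < alpha_in
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(candidate = character(), r_squared = numeric(),
                          p = numeric(), n = integer(), keep = logical())
  }
  out <- out[order(-out$r_squared), ]
  attr(out, "warnings") <- warn
  out
}

#' Prune collinear candidates within declared families
#'
#' Sprint outcomes (v_mean, v_max, PO_mean, PO_max) and Wingate outcomes
#' (P30, P5, PO_max) are highly intercorrelated; within each declared family,
#' members with pairwise |r| above the threshold never enter the same model —
#' only the member with the highest univariate R-squared survives.
#'
#' @param screened Screening table from [univariate_screen()] (kept rows are
#'   considered).
#' @param cohort The cohort data frame (for the correlations).
#' @param families Named list of character vectors declaring the variable
#'   families, e.g. \code{list(sprint = c("v_mean", "po_mean"))}.
#' @param threshold Absolute correlation above which two family members are
#'   mutually exclusive (default 0.8).
#' @return Character vector of surviving candidate names (ranked as in
#'   \code{screened}).
#' @export
collinearity_prune <- function(screened, cohort, families, threshold = 0.8) {
  kept <- screened$candidate[screened$keep]
  dropped <- character()
  for (fam in families) {
    members <- intersect(kept, fam)
    if (length(members) < 2L) next
    # rank family members by univariate R^2, best first
    r2 <- screened$r_squared[match(members, screened$candidate)]
    members <- members[order(-r2)]
    survivors <- members[1L]
    for (m in members[-1L]) {
      cors <- vapply(survivors, function(s) {
        ok <- stats::complete.cases(cohort[, c(m, s)])
        stats::cor(cohort[[m]][ok], cohort[[s]][ok])
      }, numeric(1))
      if (any(abs(cors) > threshold)) {
        dropped <- c(dropped, m)
      } else {
        survivors <- c(survivors, m)
      }
    }
  }
  setdiff(kept, dropped)
}

#' Backward elimination with a protected-or-dropped sport block
#'
#' Fits the full linear model, then iteratively removes the unprotected term
#' with the highest p-value until every unprotected term is significant at
#' \code{alpha_out}. The sport dummies enter and leave as one block, judged by
#' a partial F-test, matching how categorical sport is treated in the model
#' construction: individually non-significant dummies stay as long as the
#' block is retained.
#'
#' @param cohort Data frame; \code{sport} column used when \code{"sport"} is
#'   among the predictors.
#' @param response Response column name.
#' @param predictors Character vector of starting predictors (\code{"sport"}
#'   allowed).
#' @param alpha_out Exit threshold (default 0.05).
#' @param protected Character vector of terms never eliminated.
#' @return A \code{fitted_model}: \code{response}, \code{terms},
#'   \code{coefficients} (tibble with estimate, std_error, p_value),
#'   \code{r_squared}, \code{n_used}, \code{dropped} (in elimination order)
#'   and the underlying \code{fit}.
#' @export
backward_eliminate <- function(cohort, response, predictors,
                               alpha_out = 0.05, protected = character()) {
  stopifnot(response %in% names(cohort))
  missing_pred <- setdiff(predictors, names(cohort))
  if (length(missing_pred)) {
    stop("predictor(s) not in cohort: ", paste(missing_pred, collapse = ", "),
         call. = FALSE)
  }
  dat <- cohort[stats::complete.cases(cohort[, c(response, predictors)]),
                c(response, predictors), drop = FALSE]
  if ("sport" %in% predictors) {
    s <- factor(dat$sport)
    if ("tennis" %in% levels(s)) s <- stats::relevel(s, ref = "tennis")
    dat$sport <- s
  }
  terms_now <- predictors
  dropped <- character()
  repeat {
    fml <- stats::reformulate(terms_now, response = response)
    fit <- stats::lm(fml, data = dat)
    if (any(is.na(stats::coef(fit)))) {
      aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient fit; aliased term(s): ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    d1 <- stats::drop1(fit, test = "F")
    cand <- setdiff(rownames(d1), c("<none>", protected))
    if (!length(cand)) break
    pvals <- d1[cand, "Pr(>F)"]
    worst <- which.max(pvals)
    if (pvals[worst] < alpha_out) break
    if (length(terms_now) == 1L) {
      # last term non-significant: drop it and stop at the null model
      dropped <- c(dropped, cand[worst])
      terms_now <- "1"
      fit <- stats::lm(stats::reformulate("1", response = response),
                       data = dat)
      break
    }
    dropped <- c(dropped, cand[worst])
    terms_now <- setdiff(terms_now, cand[worst])
  }
  sm <- summary(fit)
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, "Estimate"]),
    std_error = unname(sm$coefficients[, "Std. Error"]),
    p_value = unname(sm$coefficients[, "Pr(>|t|)"])
  )
  structure(
    list(response = response,
         terms = setdiff(terms_now, "1"),
         coefficients = coefs,
         r_squared = sm$r.squared,
         n_used = nrow(dat),
         dropped = dropped,
         fit = fit),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s ~ %s\n", x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"))
  cf <- x$coefficients
  cat(paste(sprintf("  %-18s %+8.3f (SE %.3f, p %s)", cf$term, cf$estimate,
                    cf$std_error, format.pval(cf$p_value, digits = 2)),
            collapse = "\n"), "\n")
  cat(sprintf("  R^2 = %.3f, n = %d", x$r_squared, x$n_used))
  if (length(x$dropped)) {
    cat(";  eliminated: ", paste(x$dropped, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Turn a fitted model into a prediction equation
#'
#' @param model A \code{fitted_model} from [backward_eliminate()] whose terms
#'   are supported equation predictors (numeric predictors and/or the sport
#'   block).
#' @param name Label for the new equation.
#' @return A [new_prediction_equation()] object usable by [predict_p30()] /
#'   [predict_po_peak()].
#' @export
as_prediction_equation <- function(model, name = model$response) {
  stopifnot(inherits(model, "fitted_model"))
  cf <- model$coefficients
  est <- cf$estimate
  names(est) <- cf$term
  intercept <- unname(est["(Intercept)"])
  est <- est[names(est) != "(Intercept)"]
  names(est) <- sub("^sport", "", names(est))
  new_prediction_equation(name, model$response, intercept, est,
                          r_squared = model$r_squared)
}

#' Compare predicted and measured values pairwise
#'
#' Tests for a systematic difference between paired predicted and measured
#' values: Shapiro-Wilk decides between a paired t-test (differences normal)
#' and a Wilcoxon signed-rank test. The per-athlete percent difference is
#' 100 * (pred - meas) / meas, averaged; the measured value is the
#' denominator by convention.
#'
#' @param pred,meas Numeric vectors of equal length (>= 3).
#' @param alpha Significance level reported against (default 0.05).
#' @return List: \code{test} ("paired t", "wilcoxon" or "identity"),
#'   \code{statistic}, \code{p}, \code{significant}, \code{shapiro_p},
#'   \code{mean_percent_difference}, \code{n}.
#' @export
compare_pred_meas <- function(pred, meas, alpha = 0.05) {
  stopifnot(length(pred) == length(meas), length(pred) >= 3L)
  ok <- stats::complete.cases(pred, meas)
  pred <- pred[ok]; meas <- meas[ok]
  if (length(pred) < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  diffs <- pred - meas
  pct <- mean(100 * (pred - meas) / meas)
  if (all(diffs == 0)) {
    return(list(test = "identity", statistic = NA_real_, p = NA_real_,
                significant = FALSE, shapiro_p = NA_real_,
                mean_percent_difference = 0, n = length(pred)))
  }
  sw <- stats::shapiro.test(diffs)
  if (sw$p.value > alpha) {
    tt <- stats::t.test(pred, meas, paired = TRUE)
    res <- list(test = "paired t", statistic = unname(tt$statistic),
                p = tt$p.value)
  } else {
    wt <- stats::wilcox.test(pred, meas, paired = TRUE, exact = FALSE)
    res <- list(test = "wilcoxon", statistic = unname(wt$statistic),
                p = wt$p.value)
  }
  c(res, list(significant = res$p < alpha, shapiro_p = sw$p.value,
              mean_percent_difference = pct, n = length(pred)))
}

#' Deviation boundaries around a predicted value
#'
#' Boundaries at pred * (1 +/- tolerance) relative to the line of identity;
#' measured values are classified as within, above or below. The default 20%
#' reflects the acceptable GXT duration range of 10 +/- 2 min.
#'
#' @param pred Predicted value(s), > 0.
#' @param tolerance Relative half-width (default 0.20).
#' @return For scalar \code{pred}: list with \code{lower}, \code{upper} and a
#'   \code{classify(meas)} function. For vector \code{pred}: a data frame of
#'   bounds.
#' @export
#' @examples
#' b <- deviation_bounds(100)
#' b$classify(c(79, 100, 121))
deviation_bounds <- function(pred, tolerance = ergo_constants()$deviation_tolerance) {
  if (any(pred <= 0)) stop("pred must be > 0", call. = FALSE)
  lower <- pred * (1 - tolerance)
  upper <- pred * (1 + tolerance)
  if (length(pred) == 1L) {
    return(list(
      lower = lower, upper = upper,
      classify = function(meas) classify_deviation(pred, meas, tolerance)
    ))
  }
  data.frame(pred = pred, lower = lower, upper = upper)
}

#' @rdname deviation_bounds
#' @param meas Measured value(s).
#' @return \code{classify_deviation}: factor with levels within/above/below.
#' @export
classify_deviation <- function(pred, meas,
                               tolerance = ergo_constants()$deviation_tolerance) {
  lower <- pred * (1 - tolerance)
  upper <- pred * (1 + tolerance)
  out <- ifelse(meas > upper, "above", ifelse(meas < lower, "below", "within"))
  factor(out, levels = c("within", "above", "below"))
}

#' Predicted-versus-measured scatter with deviation boundaries
#'
#' Scatter of measured against predicted values with the line of identity and
#' the +/- tolerance boundary lines.
#'
#' @param pred,meas Numeric vectors.
#' @param sport Optional grouping for the point color.
#' @param tolerance Relative boundary half-width (default 0.20).
#' @param lab Axis label stem, e.g. \code{"P30 (W)"}.
#' @return A ggplot object.
#' @export
plot_deviation <- function(pred, meas, sport = NULL,
                           tolerance = ergo_constants()$deviation_tolerance,
                           lab = "value") {
  dat <- data.frame(pred = pred, meas = meas)
  if (!is.null(sport)) dat$sport <- sport
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = pred, y = meas)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = 1 + tolerance, intercept = 0) +
    ggplot2::geom_abline(slope = 1 - tolerance, intercept = 0) +
    ggplot2::labs(x = paste("predicted", lab), y = paste("measured", lab)) +
    ggplot2::theme_minimal()
  if (is.null(sport)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = sport))
  }
}

#' Read / write a cohort table
#'
#' Delimited text with one header row; columns follow the package's cohort
#' conventions (see [synth_cohort()]). Missing values as empty fields or NA.
#'
#' @param path File path.
#' @return \code{read_cohort}: a tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
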