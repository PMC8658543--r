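#' Stepwise linear regression by partial-F p-values
#'
#' Forward/backward selection for the Arc-positive-percentage model: starting
#' from the intercept-only model, the candidate term with the smallest
#' partial-F p-value enters while below `p_enter`; after each entry, terms
#' whose partial-F p-value exceeds `p_remove` are dropped (largest first).
#' Candidate terms adding no explanatory power (e.g. a duplicated or
#' collinear column) can never enter, since their partial F is 0.
#'
#' @param data data frame holding the response and candidate predictors.
#' @param response name of the response column.
#' @param candidates character vector of candidate predictor columns
#'   (default: all non-response columns).
#' @param p_enter,p_remove entry / removal p-value thresholds (defaults 0.05
#'   and 0.10, the documented defaults of the tool the analysis names).
#' @return object of class `stepwise_fit`: `model` (the [lm()] fit),
#'   `selected`, `coefficients` (summary table), `anova_table`
#'   (regression/error/total SS), `adj_r_squared`, `r_squared`, `steps`
#'   (log of entries/removals).
#' @export
stepwise_linear_model <- function(data, response, candidates = NULL,
                                  p_enter = 0.05, p_remove = 0.10) {
  stopifnot(response %in% names(data))
  if (is.null(candidates)) candidates <- setdiff(names(data), response)
  stopifnot(length(candidates) >= 1)
  if (nrow(data) < length(candidates) + 3L)
    stop("need at least 3 more observations than candidate terms",
         call. = FALSE)
  selected <- character(0)
  steps <- list()
  fit <- stats::lm(stats::reformulate("1", response), data = data)
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      a1 <- stats::add1(fit, scope = stats::reformulate(c(selected, pool)),
                        test = "F")
      pv <- a1[["Pr(>F)"]][-1]
      names(pv) <- rownames(a1)[-1]
      pv <- pv[!is.na(pv)]
      if (length(pv) && min(pv) < p_enter) {
        term <- names(pv)[which.min(pv)]
        selected <- c(selected, term)
        fit <- stats::lm(stats::reformulate(selected, response), data = data)
        steps <- c(steps, list(c(action = "add", term = term,
                                 p = unname(min(pv)))))
        changed <- TRUE
      }
    }
    if (length(selected) > 1L) {
      d1 <- stats::drop1(fit, test = "F")
      pv <- d1[["Pr(>F)"]][-1]
      names(pv) <- rownames(d1)[-1]
      while (length(pv) && max(pv, na.rm = TRUE) > p_remove) {
        term <- names(pv)[which.max(pv)]
        selected <- setdiff(selected, term)
        steps <- c(steps, list(c(action = "drop", term = term,
                                 p = unname(max(pv, na.rm = TRUE)))))
        fit <- stats::lm(stats::reformulate(
          if (length(selected)) selected else "1", response), data = data)
        changed <- TRUE
        if (length(selected) <= 1L) break
        d1 <- stats::drop1(fit, test = "F")
        pv <- d1[["Pr(>F)"]][-1]
        names(pv) <- rownames(d1)[-1]
      }
    }
    if (!changed) break
  }
  sm <- summary(fit)
  n <- nrow(data)
  y <- data[[response]]
  ss_total <- sum((y - mean(y))^2)
  ss_error <- sum(stats::residuals(fit)^2)
  ss_reg <- ss_total - ss_error
  df_reg <- length(selected)
  df_err <- n - df_reg - 1L
  anova_table <- data.frame(
    source = c("regression", "error", "total"),
    df = c(df_reg, df_err, n - 1L),
    ss = c(ss_reg, ss_error, ss_total),
    ms = c(if (df_reg > 0) ss_reg / df_reg else NA, ss_error / df_err, NA),
    f = c(if (df_reg > 0) (ss_reg / df_reg) / (ss_error / df_err) else NA,
          NA, NA)
  )
  structure(list(model = fit, selected = selected,
                 coefficients = stats::coef(sm),
                 anova_table = anova_table,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 steps = steps),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit> selected terms:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n")
  print(round(x$coefficients, 5))
  cat(sprintf("R^2 = %.3f, adjusted R^2 = %.3f\n",
              x$r_squared, x$adj_r_squared))
  invisible(x)
}
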