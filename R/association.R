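#' Pairwise privacy-network correlations
#'
#' Crosses every network-structure outcome with every privacy predictor,
#' reporting the Pearson correlation coefficient, its two-sided p-value and
#' a significance tier (`"ns"`, `"*"` for p < 0.05, `"**"` for p < 0.01).
#' Zero-variance columns yield cells marked undefined.
#'
#' @param outcomes data.frame of numeric outcome columns (rows =
#'   residents).
#' @param predictors data.frame of numeric predictor columns, same rows.
#' @return data.frame in long form: `outcome`, `predictor`, `r`, `p`,
#'   `tier`, `undefined`.
#' @export
correlate <- function(outcomes, predictors) {
  if (nrow(outcomes) != nrow(predictors)) {
    stop_invalid("outcomes and predictors must have the same rows")
  }
  if (nrow(outcomes) < 3L) stop_invalid("need at least 3 complete rows")
  grid <- expand.grid(outcome = names(outcomes), predictor = names(predictors),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    y <- outcomes[[grid$outcome[i]]]
    x <- predictors[[grid$predictor[i]]]
    if (stats::sd(y) == 0 || stats::sd(x) == 0) {
      return(data.frame(grid[i, ], r = NA_real_, p = NA_real_,
                        tier = NA_character_, undefined = TRUE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(grid[i, ], r = unname(ct$estimate), p = ct$p.value,
               tier = sig_tier(ct$p.value), undefined = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

sig_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

ASSOCIATION_OUTCOMES <- c(
  "degree_centrality",
  "n_partners_roommates_own_bedroom", "n_partners_nonroommates_other_bedrooms",
  "n_partners_roommates_common", "n_partners_nonroommates_common",
  "freq_roommates_own_bedroom", "freq_nonroommates_other_bedrooms",
  "freq_roommates_common", "freq_nonroommates_common"
)

ASSOCIATION_PREDICTORS <- c(
  "total", "occupancy_score", "visual_privacy_score", "visibility_score",
  "adjacency_score", "transitional_score"
)

#' Privacy-network association table
#'
#' The report-shaped association analysis: nine network outcomes (degree
#' centrality, four partner-count strata, four contact-frequency strata)
#' against six predictors (overall privacy plus the five factors), with
#' per-cell correlation coefficient, p-value and significance stars. The
#' default cell statistic is the zero-order Pearson correlation;
#' standardized OLS coefficients are available via `mode = "regression"`
#' (per outcome, all five factors entered jointly; the overall-privacy
#' column stays a correlation since total is collinear with its parts).
#' Predictors are bedroom-level scores broadcast to residents, so
#' within-bedroom rows are not independent — a caveat, not an error.
#' Optional Benjamini-Hochberg adjustment is off by default.
#'
#' @param features feature data.frame ([compute_features()]).
#' @param privacy per-resident privacy scores ([privacy_by_resident()]).
#' @param mode `"correlation"` (default) or `"regression"`.
#' @param p_adjust apply Benjamini-Hochberg across all cells
#'   (default FALSE).
#' @return long data.frame (`outcome` x `predictor` cells) of class
#'   `association_table`.
#' @export
association_table <- function(features, privacy,
                              mode = c("correlation", "regression"),
                              p_adjust = FALSE) {
  mode <- match.arg(mode)
  stopifnot(identical(features$resident_id, privacy$resident_id))
  outcomes <- features[, ASSOCIATION_OUTCOMES]
  predictors <- privacy[, ASSOCIATION_PREDICTORS]
  if (mode == "correlation") {
    out <- correlate(outcomes, predictors)
  } else {
    factors <- privacy[, setdiff(ASSOCIATION_PREDICTORS, "total")]
    rows <- lapply(ASSOCIATION_OUTCOMES, function(oc) {
      fit <- multiple_regress(features[[oc]], factors, on_collinear = "drop")
      co <- fit$coefficients
      rbind(
        {
          ct <- stats::cor.test(privacy$total, features[[oc]])
          data.frame(outcome = oc, predictor = "total",
                     r = unname(ct$estimate), p = ct$p.value,
                     tier = sig_tier(ct$p.value), undefined = FALSE)
        },
        data.frame(outcome = oc, predictor = co$term, r = co$estimate,
                   p = co$p, tier = sig_tier(co$p),
                   undefined = is.na(co$estimate))
      )
    })
    out <- do.call(rbind, rows)
  }
  if (p_adjust) {
    out$p <- stats::p.adjust(out$p, method = "BH")
    out$tier <- sig_tier(out$p)
  }
  rownames(out) <- NULL
  class(out) <- c("association_table", class(out))
  out
}

#' Multiple regression of an outcome on the five privacy factors
#'
#' Ordinary least squares on standardized variables, reporting
#' standardized coefficients, t-based p-values and R-squared. Bedroom-level
#' predictors broadcast to residents span at most as many distinct rows as
#' there are bedroom types, so rank deficiency is expected and checked:
#' aliased factors raise an error naming them (or are dropped with
#' `on_collinear = "drop"`).
#'
#' @param outcome numeric outcome vector.
#' @param factors data.frame of numeric predictor columns.
#' @param on_collinear `"error"` (default) or `"drop"`.
#' @return list: `coefficients` (data.frame `term`, `estimate`, `se`, `t`,
#'   `p`), `r_squared`, `n`, `dropped` (aliased terms, if any).
#' @export
multiple_regress <- function(outcome, factors, on_collinear = c("error", "drop")) {
  on_collinear <- match.arg(on_collinear)
  n <- length(outcome)
  if (n != nrow(factors)) stop_invalid("outcome and factors differ in rows")
  if (n <= ncol(factors) + 1L) {
    stop_invalid("need n > number of predictors + 1 (n = %d, p = %d)",
                 n, ncol(factors))
  }
  zs <- function(x) if (stats::sd(x) == 0) x * 0 else (x - mean(x)) / stats::sd(x)
  dat <- as.data.frame(lapply(factors, zs))
  dat$.y <- zs(outcome)
  fit <- stats::lm(.y ~ ., data = dat)
  aliased <- names(which(is.na(stats::coef(fit))))
  dropped <- character(0)
  if (length(aliased) > 0L) {
    aliased_terms <- intersect(names(factors), sub("`(.*)`", "\\1", aliased))
    if (on_collinear == "error") {
      stop_invalid("collinear factors (aliased in OLS): %s",
                   paste(aliased_terms, collapse = ", "))
    }
    dropped <- aliased_terms
    dat <- dat[, c(setdiff(names(factors), dropped), ".y")]
    fit <- stats::lm(.y ~ ., data = dat)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  keep <- setdiff(rownames(ct), "(Intercept)")
  co <- data.frame(term = sub("`(.*)`", "\\1", keep),
                   estimate = ct[keep, "Estimate"],
                   se = ct[keep, "Std. Error"],
                   t = ct[keep, "t value"],
                   p = ct[keep, "Pr(>|t|)"],
                   stringsAsFactors = FALSE)
  if (length(dropped) > 0L) {
    co <- rbind(co, data.frame(term = dropped, estimate = NA_real_,
                               se = NA_real_, t = NA_real_, p = NA_real_))
  }
  rownames(co) <- NULL
  list(coefficients = co, r_squared = sm$r.squared, n = n, dropped = dropped)
}

#' Calibration of the association test under the null (and under a planted
#' effect)
#'
#' Repeatedly draws outcomes for a fixed predictor vector and records how
#' often the association test rejects at the 0.05 level. Under the null
#' (`effect_d = 0`) the outcome is independent standard normal noise and
#' the rejection rate estimates the empirical type-I error; with a planted
#' effect the outcome is `sign * r * scale(x) + noise` where the
#' standardized effect size `effect_d` (Cohen's d) converts to a
#' correlation `r = d / sqrt(d^2 + 4)`, and the recorded rate is the power
#' to detect a significant coefficient with the planted sign.
#'
#' @param predictor numeric predictor vector (e.g. occupancy scores of the
#'   default roster).
#' @param n_reps number of replications (must be positive).
#' @param seed RNG seed.
#' @param effect_d standardized effect size of the planted association
#'   (default 0 = null).
#' @param effect_sign sign of the planted effect (default -1, a privacy
#'   factor suppressing interaction).
#' @param alpha test level (default 0.05).
#' @return list: `rate` (rejection / recovery rate), `ci` (95% binomial
#'   confidence interval), `n_reps`, `alpha`.
#' @export
null_calibration <- function(predictor, n_reps = 1000, seed = 1L,
                             effect_d = 0, effect_sign = -1, alpha = 0.05) {
  n_reps <- assert_count(n_reps, "n_reps", min = 1L)
  set.seed(assert_count(seed, "seed", min = 0L))
  x <- as.numeric(predictor)
  if (stats::sd(x) == 0) stop_invalid("predictor has zero variance")
  r_target <- effect_d / sqrt(effect_d^2 + 4)
  beta <- if (r_target >= 1) Inf else r_target / sqrt(1 - r_target^2)
  xs <- (x - mean(x)) / stats::sd(x)
  hits <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    y <- effect_sign * beta * xs + stats::rnorm(length(x))
    ct <- stats::cor.test(x, y, method = "pearson")
    hits[i] <- if (effect_d == 0) {
      ct$p.value < alpha
    } else {
      ct$p.value < alpha && sign(unname(ct$estimate)) == sign(effect_sign)
    }
  }
  k <- sum(hits)
  ci <- stats::binom.test(k, n_reps)$conf.int
  list(rate = k / n_reps, ci = as.numeric(ci), n_reps = n_reps, alpha = alpha)
}
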