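# Competitive-ELISA calibration: four-parameter logistic fits, IC50 at the
# inflection point, and cross-reactivity percentages with censoring.
#
# OD(x) = d + (a - d) / (1 + (x / c)^b): a = upper asymptote (zero analyte),
# d = lower asymptote, c = inflection concentration (IC50, ng/mL), b = slope.
# Concentrations are log-transformed for conditioning during fitting;
# zero-dose wells only anchor the initial value of a.

fourpl <- function(x, a, d, c, b) d + (a - d) / (1 + (x / c)^b)

#' Fit a four-parameter logistic competitive curve
#'
#' Least-squares fit of the 4PL model on log-spaced concentrations via
#' Levenberg-Marquardt ([minpack.lm::nlsLM]) with `c > 0` and `b > 0`
#' enforced by parameterization/bounds. Starting values: `a` = mean zero-dose
#' (or maximum) OD, `d` = minimum OD, `c` = geometric mean concentration,
#' `b` = 1. Curves without measurable inhibition (dynamic range below three
#' times the replicate noise, or essentially flat) are marked censored rather
#' than force-fitted.
#'
#' @param data Data frame with columns `concentration` (ng/mL; a zero dose is
#'   allowed and used only to anchor `a`) and `od`; an optional `replicate`
#'   column is carried through.
#' @param min_levels Minimum number of positive concentration levels
#'   (default 5).
#' @return An `fq_4pl`: list with `coefficients` (`a`, `d`, `c`, `b`),
#'   `converged`, `censored`, `residual_rms`, `max_tested` and `data`.
#' @export
fit_4pl <- function(data, min_levels = 5L) {
  fq_assert(all(c("concentration", "od") %in% names(data)),
            "data needs 'concentration' and 'od' columns", "input")
  fq_assert(all(is.finite(data$od)) && all(data$od >= 0),
            "od must be finite and non-negative", "input")
  fq_assert(all(data$concentration >= 0),
            "concentrations must be non-negative", "input")
  zero <- data$concentration == 0
  pos <- data[!zero, , drop = FALSE]
  levels_ <- sort(unique(pos$concentration))
  fq_assert(length(levels_) >= min_levels,
            paste0("need at least ", min_levels,
                   " positive concentration levels"), "input")
  max_tested <- max(levels_)

  level_mean <- vapply(split(pos$od, pos$concentration), mean, numeric(1))
  noise <- pooled_replicate_sd(pos)
  dyn_range <- max(level_mean) - min(level_mean)
  a0 <- if (any(zero)) mean(data$od[zero]) else max(data$od)
  flat <- dyn_range < max(3 * noise, 0.05 * max(data$od))
  if (flat) {
    return(new_fq_4pl(coefficients = c(a = a0, d = NA_real_, c = NA_real_,
                                       b = NA_real_),
                      converged = FALSE, censored = TRUE,
                      residual_rms = NA_real_, max_tested = max_tested,
                      data = as_tibble(data)))
  }

  df <- tibble(lx = log(pos$concentration), od = pos$od)
  start <- list(a = a0, d = min(pos$od), lc = mean(log(levels_)), b = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(od ~ d + (a - d) / (1 + exp(b * (lx - lc))),
                      data = df, start = start,
                      lower = c(a = 0, d = 0, lc = -Inf, b = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_fq_4pl(coefficients = c(a = a0, d = NA_real_, c = NA_real_,
                                       b = NA_real_),
                      converged = FALSE, censored = TRUE,
                      residual_rms = NA_real_, max_tested = max_tested,
                      data = as_tibble(data)))
  }
  cf <- coef(fit)
  co <- c(a = unname(cf["a"]), d = unname(cf["d"]),
          c = exp(unname(cf["lc"])), b = unname(cf["b"]))
  if (co["a"] <= co["d"]) {
    # not a decreasing competitive curve; treat as unmeasurable inhibition
    return(new_fq_4pl(coefficients = co, converged = FALSE, censored = TRUE,
                      residual_rms = sqrt(mean(resid(fit)^2)),
                      max_tested = max_tested, data = as_tibble(data)))
  }
  new_fq_4pl(coefficients = co, converged = TRUE, censored = FALSE,
             residual_rms = sqrt(mean(resid(fit)^2)),
             max_tested = max_tested, data = as_tibble(data))
}

pooled_replicate_sd <- function(pos) {
  if (!"replicate" %in% names(pos)) return(0)
  sds <- vapply(split(pos$od, pos$concentration),
                function(v) if (length(v) > 1L) sd(v) else NA_real_,
                numeric(1))
  if (all(is.na(sds))) 0 else mean(sds, na.rm = TRUE)
}

new_fq_4pl <- function(coefficients, converged, censored, residual_rms,
                       max_tested, data) {
  structure(list(coefficients = coefficients, converged = converged,
                 censored = censored, residual_rms = residual_rms,
                 max_tested = max_tested, data = data),
            class = "fq_4pl")
}

#' @export
print.fq_4pl <- function(x, ...) {
  if (x$censored) {
    cat("<fq_4pl> censored: no measurable inhibition up to ",
        format(x$max_tested), " ng/mL\n", sep = "")
  } else {
    cat("<fq_4pl> IC50 = ", format(x$coefficients["c"], digits = 4),
        " ng/mL (a = ", format(x$coefficients["a"], digits = 3),
        ", d = ", format(x$coefficients["d"], digits = 3),
        ", b = ", format(x$coefficients["b"], digits = 3), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.fq_4pl <- function(x, ...) {
  tibble(term = c("a_upper", "d_lower", "c_mid", "b_slope"),
         estimate = unname(x$coefficients[c("a", "d", "c", "b")]))
}

#' @export
glance.fq_4pl <- function(x, ...) {
  tibble(converged = x$converged, censored = x$censored,
         residual_rms = x$residual_rms, max_tested = x$max_tested,
         n_obs = sum(x$data$concentration > 0))
}

#' IC50 of a fitted competitive curve
#'
#' The 4PL inflection point `c`, at which the signal is halfway between the
#' asymptotes: `OD(c) = (a + d) / 2`.
#'
#' @param fit An `fq_4pl`.
#' @return IC50 in ng/mL.
#' @export
ic50 <- function(fit) {
  if (!isTRUE(fit$converged)) {
    fq_abort("IC50 undefined: the 4PL fit did not converge (censored curve?)",
             "nofit")
  }
  unname(fit$coefficients["c"])
}

#' Cross-reactivity percentage
#'
#' `CR = IC50_ref / IC50_x * 100` (percent), where the reference is the
#' immunizing hapten. For an analyte without measurable inhibition
#' (`censored = TRUE`), the IC50 is only bounded below by the highest tested
#' concentration, so CR is bounded above by
#' `IC50_ref / max_tested * 100`; the record is reported as censored
#' (displayed `"<0.01"` when the bound falls below 0.01%).
#'
#' @param ic50_ref Reference IC50 (ng/mL), > 0.
#' @param ic50_x Analyte IC50 (ng/mL), or `NA` when censored.
#' @param censored Is the analyte curve censored?
#' @param max_tested Highest tested concentration (required when censored).
#' @return A one-row tibble with `cr`, `censored`, `cr_bound`, `cr_display`.
#' @export
cross_reactivity <- function(ic50_ref, ic50_x, censored = FALSE,
                             max_tested = NULL) {
  fq_assert(is_scalar_number(ic50_ref) && ic50_ref > 0,
            "reference IC50 must be positive", "domain")
  if (censored) {
    fq_assert(is_scalar_number(max_tested) && max_tested > 0,
              "max_tested is required for a censored analyte", "domain")
    bound <- ic50_ref / max_tested * 100
    disp <- if (bound < 0.01) "<0.01" else paste0("<", signif(bound, 2))
    return(tibble(cr = NA_real_, censored = TRUE, cr_bound = bound,
                  cr_display = disp))
  }
  if (!is_scalar_number(ic50_x) || ic50_x <= 0) {
    fq_abort("analyte IC50 must be positive", "domain")
  }
  cr <- ic50_ref / ic50_x * 100
  tibble(cr = cr, censored = FALSE, cr_bound = cr,
         cr_display = format(signif(cr, 3)))
}

#' Cross-reactivity table for a competitive-ELISA panel
#'
#' Fits every analyte's pooled curve, extracts IC50s, and computes CR against
#' the reference analyte (CR = 100 for the reference by construction).
#' Replicate uncertainty is propagated as the standard deviation of
#' per-replicate CRs (each replicate of the analyte fitted against the same
#' replicate of the reference).
#'
#' @param data Panel data frame with columns `analyte`, `concentration`,
#'   `replicate`, `od`.
#' @param reference Name of the reference analyte.
#' @return Tibble with one row per analyte: `analyte`, `ic50`, `ic50_sd`,
#'   `censored`, `cr`, `cr_sd`, `cr_display`.
#' @export
cr_table <- function(data, reference) {
  fq_assert(all(c("analyte", "concentration", "od") %in% names(data)),
            "panel needs 'analyte', 'concentration', 'od' columns", "input")
  if (!reference %in% data$analyte) {
    fq_abort(paste0("reference analyte '", reference, "' not in panel"),
             "input")
  }
  analytes <- unique(data$analyte)
  fits <- lapply(setNames(analytes, analytes),
                 function(an) fit_4pl(data[data$analyte == an, , drop = FALSE]))
  if (!fits[[reference]]$converged) {
    fq_abort("reference analyte curve could not be fitted", "nofit")
  }
  ref_ic50 <- ic50(fits[[reference]])

  rep_ic50 <- function(an) {
    d <- data[data$analyte == an, , drop = FALSE]
    if (!"replicate" %in% names(d)) return(NULL)
    vapply(split(d, d$replicate), function(dd) {
      f <- tryCatch(fit_4pl(dd), error = function(e) NULL)
      if (!is.null(f) && f$converged) ic50(f) else NA_real_
    }, numeric(1))
  }
  ref_reps <- rep_ic50(reference)

  rows <- lapply(analytes, function(an) {
    f <- fits[[an]]
    if (an == reference) {
      return(tibble(analyte = an, ic50 = ref_ic50,
                    ic50_sd = if (is.null(ref_reps)) NA_real_ else
                      sd(ref_reps, na.rm = TRUE),
                    censored = FALSE, cr = 100, cr_sd = 0,
                    cr_display = "100"))
    }
    if (f$censored) {
      rec <- cross_reactivity(ref_ic50, NA, censored = TRUE,
                              max_tested = f$max_tested)
      return(tibble(analyte = an, ic50 = NA_real_, ic50_sd = NA_real_,
                    censored = TRUE, cr = NA_real_, cr_sd = NA_real_,
                    cr_display = rec$cr_display))
    }
    x <- ic50(f)
    rec <- cross_reactivity(ref_ic50, x)
    reps <- rep_ic50(an)
    rep_sd <- if (is.null(reps) || is.null(ref_reps)) NA_real_ else {
      both <- intersect(names(reps)[!is.na(reps)],
                        names(ref_reps)[!is.na(ref_reps)])
      if (length(both) > 1L) sd(ref_reps[both] / reps[both] * 100) else
        NA_real_
    }
    tibble(analyte = an,
           ic50 = x,
           ic50_sd = if (is.null(reps)) NA_real_ else sd(reps, na.rm = TRUE),
           censored = FALSE, cr = rec$cr, cr_sd = rep_sd,
           cr_display = rec$cr_display)
  })
  bind_rows(rows)
}

#' Read a competitive-ELISA panel CSV
#'
#' @param path CSV with columns `analyte`, `concentration_ng_per_ml`,
#'   `replicate`, `od450`.
#' @return Tibble with standardized columns `analyte`, `concentration`,
#'   `replicate`, `od`.
#' @export
read_elisa_csv <- function(path) {
  fq_assert(file.exists(path), paste0("file not found: ", path), "io")
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("analyte", "concentration_ng_per_ml", "replicate", "od450")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    fq_abort(paste0("ELISA CSV lacks column(s): ",
                    paste(miss, collapse = ", ")), "input")
  }
  tibble(analyte = d$analyte, concentration = d$concentration_ng_per_ml,
         replicate = d$replicate, od = d$od450)
}
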