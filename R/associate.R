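#' Build the per-patient TE-activity feature matrix
#'
#' Combines TE expression by evolutionary-age category, TE methylation by age
#' category, the total patient-specific insertion burden in the tumor sample,
#' and clinical covariates (numeric age at diagnosis; disease status and
#' primary site dummy-encoded against their most frequent level).
#'
#' @param expression Data.frame with `patient_id` plus numeric expression
#'   columns (one per age category), or `NULL`.
#' @param methylation_age_means Matrix from [age_category_means()] whose
#'   columns are patient/tumor-sample ids, or `NULL`.
#' @param burdens Data.frame with `patient_id` and `burden`.
#' @param clinical Clinical data.frame from [read_clinical()], or `NULL` to
#'   omit clinical covariates.
#' @return Data.frame with rownames = patient ids: numeric TE-activity
#'   columns, `age_dx`, and 0/1 dummy columns; only patients present in all
#'   supplied sources are kept.
#' @export
build_feature_matrix <- function(expression = NULL, methylation_age_means = NULL,
                                 burdens, clinical = NULL) {
  ids <- burdens$patient_id
  if (!is.null(expression)) ids <- intersect(ids, expression$patient_id)
  if (!is.null(methylation_age_means)) {
    ids <- intersect(ids, colnames(methylation_age_means))
  }
  if (!is.null(clinical)) ids <- intersect(ids, clinical$patient_id)
  ids <- sort(ids)
  if (length(ids) == 0L) stop("no patients shared across feature sources", call. = FALSE)

  out <- data.frame(row.names = ids)
  if (!is.null(expression)) {
    e <- expression[match(ids, expression$patient_id), , drop = FALSE]
    for (nm in setdiff(names(e), "patient_id")) {
      out[[paste0("expr_", nm)]] <- e[[nm]]
    }
  }
  if (!is.null(methylation_age_means)) {
    for (r in rownames(methylation_age_means)) {
      out[[paste0("meth_", r)]] <- methylation_age_means[r, ids]
    }
  }
  out$insertion_burden <- burdens$burden[match(ids, burdens$patient_id)]
  if (!is.null(clinical)) {
    cl <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
    out$age_dx <- cl$age_dx
    for (v in c("disease_status_dx", "primary_site")) {
      f <- factor(cl[[v]])
      if (nlevels(f) < 2L) next
      ref <- names(sort(table(f), decreasing = TRUE))[1L]
      for (lv in setdiff(levels(f), ref)) {
        out[[paste0(v, "_", make.names(lv))]] <- as.integer(f == lv)
      }
    }
  }
  out
}

#' Standardize feature columns
#'
#' Each numeric column is centered and scaled to unit standard deviation
#' (denominator `n - 1`). Constant columns cannot be scaled; they are dropped
#' with a warning. Columns named in `skip` (e.g. 0/1 dummies) pass through
#' unchanged.
#'
#' @param features Data.frame or matrix of numeric features (>= 2 rows).
#' @param skip Character vector of column names to leave unscaled.
#' @return The standardized data.frame; dropped columns are recorded in
#'   `attr(, "dropped")`.
#' @export
standardize_features <- function(features, skip = character(0)) {
  features <- as.data.frame(features)
  if (nrow(features) < 2L) stop("need >= 2 rows to standardize", call. = FALSE)
  dropped <- character(0)
  for (nm in names(features)) {
    if (nm %in% skip) next
    x <- features[[nm]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      dropped <- c(dropped, nm)
      features[[nm]] <- NULL
    } else {
      features[[nm]] <- (x - mean(x)) / s
    }
  }
  if (length(dropped) > 0L) {
    warning("dropped constant feature column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  attr(features, "dropped") <- dropped
  features
}

#' Spearman rank-correlation matrix with significance mask
#'
#' Rho is Pearson correlation of average ranks. P-values use the exact
#' permutation null distribution of the rank correlation for small untied
#' samples (n <= 9, via [stats::cor.test()]), and the t-approximation with
#' `n - 2` degrees of freedom otherwise. The matrix is symmetric with unit
#' diagonal and is invariant under strictly monotone transforms of any
#' column.
#'
#' @param features Numeric data.frame/matrix (patients x features, n >= 3).
#' @param alpha Significance level for the mask.
#' @return List with `rho`, `p` (diagonal `NA`), and logical `significant`
#'   (`p < alpha`).
#' @export
spearman_matrix <- function(features, alpha = 0.05) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 3L) stop("spearman_matrix needs >= 3 rows", call. = FALSE)
  r <- apply(x, 2L, rank)
  rho <- stats::cor(r)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  if (n <= 9L) {
    for (i in seq_len(ncol(x))) {
      for (j in seq_len(ncol(x))) {
        if (i == j) next
        no_ties <- anyDuplicated(x[, i]) == 0L && anyDuplicated(x[, j]) == 0L
        if (no_ties) {
          p[i, j] <- suppressWarnings(
            stats::cor.test(x[, i], x[, j], method = "spearman",
                            exact = TRUE)$p.value)
        }
      }
    }
  }
  diag(p) <- NA_real_
  list(rho = rho, p = p, significant = !is.na(p) & p < alpha)
}

#' Cox proportional-hazards fit for event-free survival
#'
#' Fits a Cox model of event-free survival on the supplied features with
#' Efron tie handling, reporting per-feature hazard ratios, z-scores and Wald
#' p-values, plus the global likelihood-ratio test against the null model.
#'
#' @param features Data.frame (rownames = patient ids) of standardized
#'   predictors.
#' @param clinical Clinical data.frame with `patient_id`, `efs_time`,
#'   `event`.
#' @param max_coef Absolute coefficient beyond which the fit is declared
#'   separated/non-converged.
#' @return A list of class `cox_fit`: `table` (feature, coef, HR, se, z, p),
#'   `lrt` (statistic, df, p), `n`, `n_events`.
#' @export
fit_cox_efs <- function(features, clinical, max_coef = 15) {
  ids <- intersect(rownames(features), clinical$patient_id)
  f <- features[ids, , drop = FALSE]
  cl <- clinical[match(ids, clinical$patient_id), ]
  cc <- stats::complete.cases(f) & !is.na(cl$efs_time) & !is.na(cl$event)
  f <- f[cc, , drop = FALSE]
  cl <- cl[cc, , drop = FALSE]
  if (nrow(f) == 0L || sum(cl$event) < 1L) {
    stop("fit_cox_efs needs complete cases with at least one event",
         call. = FALSE)
  }
  dat <- cbind(data.frame(.time = cl$efs_time, .event = cl$event), f)
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ .,
    data = dat, ties = "efron",
    control = survival::coxph.control(iter.max = 50)
  )
  co <- stats::coef(fit)
  ok <- !is.na(co)
  if (any(!ok)) {
    warning("dropped collinear covariate(s) from the Cox fit: ",
            paste(names(co)[!ok], collapse = ", "), call. = FALSE)
  }
  if (any(abs(co[ok]) > max_coef)) {
    stop("Cox fit did not converge (separation suspected); coefficients: ",
         paste(sprintf("%s=%.2f", names(co)[ok], co[ok]), collapse = ", "),
         call. = FALSE)
  }
  se <- sqrt(diag(fit$var))
  if (length(se) == length(co)) se <- se[ok]
  co <- co[ok]
  z <- co / se
  lrt_stat <- 2 * diff(fit$loglik)
  df <- sum(ok)
  structure(list(
    table = data.frame(
      feature = names(co), coef = unname(co), hr = exp(unname(co)),
      se = unname(se), z = unname(z),
      p = 2 * stats::pnorm(-abs(unname(z))),
      stringsAsFactors = FALSE
    ),
    lrt = list(statistic = unname(lrt_stat), df = df,
               p = stats::pchisq(unname(lrt_stat), df, lower.tail = FALSE)),
    n = fit$n, n_events = fit$nevent
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit: n =", x$n, ", events =", x$n_events, "\n")
  print(x$table, digits = 3)
  cat(sprintf("Likelihood ratio test = %.2f on %d df, p = %.4g\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test stratified by insertion burden
#'
#' Patients with burden strictly above `threshold` form the high group;
#' burden equal to the threshold goes to the low group. Product-limit curves
#' are estimated per group and compared with the two-group log-rank test
#' (1 df).
#'
#' @param clinical Clinical data.frame.
#' @param burdens Data.frame with `patient_id` and `burden`.
#' @param threshold Burden cut.
#' @return List with `curves` (data.frame `group`, `time`, `surv`,
#'   `n_risk`, `n_event`), `chisq`, `df`, `p`, `n_high`, `n_low`.
#' @export
km_logrank_by_burden <- function(clinical, burdens, threshold = 100L) {
  ids <- intersect(clinical$patient_id, burdens$patient_id)
  cl <- clinical[match(ids, clinical$patient_id), ]
  b <- burdens$burden[match(ids, burdens$patient_id)]
  group <- factor(ifelse(b > threshold, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0L)) {
    stop("burden threshold ", threshold, " leaves the '",
         names(which(table(group) == 0L))[1L],
         "' group empty; choose a different threshold", call. = FALSE)
  }
  dat <- data.frame(time = cl$efs_time, event = cl$event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(
    group = sub("^group=", "", strata),
    time = sf$time, surv = sf$surv,
    n_risk = sf$n.risk, n_event = sf$n.event,
    stringsAsFactors = FALSE
  )
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  chisq <- unname(sd$chisq)
  list(curves = curves, chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, 1L, lower.tail = FALSE),
       n_high = sum(group == "high"), n_low = sum(group == "low"))
}
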