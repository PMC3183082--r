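#' Levene's F-test for equality of variances
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group center: the classic Levene test with \code{center = "mean"}
#' (default) or the Brown-Forsythe variant with \code{center = "median"}.
#' When the deviations have zero spread within every group but the group
#' deviation means differ, the F statistic is degenerate (infinite); this is
#' reported as \code{p = 0} with an explicit \code{degenerate} flag rather
#' than a numeric infinity in a p-value computation.
#'
#' @param group_values list of numeric vectors (>= 2 groups, >= 2 values
#'   each), or a data.frame with columns \code{group} and \code{value}.
#' @param center "mean" (Levene) or "median" (Brown-Forsythe).
#' @return List of class \code{levene_test}: \code{statistic} (F),
#'   \code{df} (between, within), \code{p_value}, \code{degenerate},
#'   \code{groups} (per-group n, mean, sd, cv).
#' @export
levene_f <- function(group_values, center = c("mean", "median")) {
  center <- match.arg(center)
  if (is.data.frame(group_values)) {
    abort_if(!all(c("group", "value") %in% names(group_values)),
             "data.frame input needs columns `group` and `value`")
    group_values <- split(group_values$value, group_values$group)
  }
  group_values <- lapply(group_values, function(x) x[!is.na(x)])
  abort_if(length(group_values) < 2, "need >= 2 groups")
  abort_if(any(lengths(group_values) < 2), "every group needs >= 2 values")

  centre_fun <- if (center == "mean") mean else stats::median
  dev <- lapply(group_values, function(x) abs(x - centre_fun(x)))

  k <- length(dev)
  n_i <- lengths(dev)
  N <- sum(n_i)
  m_i <- vapply(dev, mean, numeric(1))
  m <- sum(unlist(dev)) / N
  ss_between <- sum(n_i * (m_i - m)^2)
  ss_within <- sum(vapply(dev, function(d) sum((d - mean(d))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- N - k

  degenerate <- FALSE
  if (ss_within <= 1e-300 * max(1, ss_between)) {
    if (ss_between <= 1e-300) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }

  groups <- data.frame(
    group = names(group_values) %||% as.character(seq_len(k)),
    n = n_i,
    mean = vapply(group_values, mean, numeric(1)),
    sd = vapply(group_values, stats::sd, numeric(1)),
    cv = vapply(group_values, compute_cv, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(statistic = f, df = c(between = df1, within = df2), p_value = p,
         degenerate = degenerate, center = center, groups = groups),
    class = "levene_test"
  )
}

#' @export
print.levene_test <- function(x, ...) {
  cat(sprintf("Levene's F (center = %s): F(%d, %d) = %.4g, p = %.4g%s\n",
              x$center, x$df[1], x$df[2], x$statistic, x$p_value,
              if (x$degenerate) " [degenerate within-group variance]" else ""))
  invisible(x)
}

#' Compare two distributions by Welch t-test or one-way ANOVA
#'
#' Convenience wrapper for comparing e.g. parent-vs-RIL CV distributions.
#' Degenerate inputs (zero variance on both sides and equal means) return
#' p = 1.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @param method "t" (Welch two-sided t-test, default) or "anova".
#' @return List with \code{statistic}, \code{p_value}, \code{method}.
#' @export
compare_distributions <- function(values_a, values_b,
                                  method = c("t", "anova")) {
  method <- match.arg(method)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  abort_if(length(values_a) < 2 || length(values_b) < 2,
           "need >= 2 values per side")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(list(statistic = 0, p_value = 1, method = method))
    }
    return(list(statistic = Inf, p_value = 0, method = method))
  }
  if (method == "t") {
    tt <- stats::t.test(values_a, values_b)
    list(statistic = unname(tt$statistic), p_value = tt$p.value, method = "t")
  } else {
    g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
    fit <- stats::aov(c(values_a, values_b) ~ g)
    s <- summary(fit)[[1]]
    list(statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
         method = "anova")
  }
}

#' Parental-expectation model of RIL CV dispersion
#'
#' Tests for transgressive segregation of stochastic noise: how much spread
#' in per-line CV would be expected if every RIL simply behaved like one of
#' the two parents? Each model assigns every simulated RIL one parent with
#' probability 1/2 and draws its CV by resampling, with replacement, a
#' replicate set of the original size from that parent's replicates. The SD
#' of CV across the simulated RILs is computed per trait and averaged across
#' traits; \code{n_models} repetitions give the null envelope (mean and max).
#' An observed average SD of CV exceeding the max indicates more CV
#' dispersion among the RILs than parental behavior alone can produce.
#'
#' @param parent_a,parent_b replicate values per trait: matrices
#'   (traits x replicates) or named lists of numeric vectors (>= 2 replicates
#'   per trait per parent). Trait sets must match.
#' @param n_lines number of RILs to simulate per model.
#' @param n_models number of models, default 1000.
#' @param observed_cv optional matrix of observed per-line CVs
#'   (lines x traits) whose average SD across traits is reported alongside.
#' @param seed optional integer seed.
#' @return List of class \code{transgression_model}: \code{model_mean},
#'   \code{model_max}, \code{model_sds} (per-model averages),
#'   \code{observed}, \code{exceeds} (observed > model_max or NA), plus the
#'   scheme metadata.
#' @export
parental_expectation_model <- function(parent_a, parent_b, n_lines,
                                       n_models = 1000, observed_cv = NULL,
                                       seed = NULL) {
  as_list <- function(x) {
    if (is.matrix(x) || is.data.frame(x)) {
      x <- as.matrix(x)
      out <- lapply(seq_len(nrow(x)), function(i) x[i, ][!is.na(x[i, ])])
      names(out) <- rownames(x) %||% as.character(seq_len(nrow(x)))
      out
    } else {
      lapply(x, function(v) v[!is.na(v)])
    }
  }
  pa <- as_list(parent_a)
  pb <- as_list(parent_b)
  abort_if(length(pa) != length(pb), "parents must cover the same traits")

  usable <- vapply(seq_along(pa), function(t) {
    length(pa[[t]]) >= 2 && length(pb[[t]]) >= 2 &&
      !is.na(compute_cv(pa[[t]])) && !is.na(compute_cv(pb[[t]]))
  }, logical(1))
  if (any(!usable)) {
    message("skipping ", sum(!usable),
            " trait(s) whose parental replicates cannot yield a CV")
  }
  pa <- pa[usable]; pb <- pb[usable]
  abort_if(length(pa) == 0, "no usable traits")

  model_sds <- with_seed(seed, {
    vapply(seq_len(n_models), function(b) {
      per_trait_sd <- vapply(seq_along(pa), function(t) {
        va <- pa[[t]]; vb <- pb[[t]]
        ka <- length(va); kb <- length(vb)
        from_a <- stats::runif(n_lines) < 0.5
        cvs <- numeric(n_lines)
        n_a <- sum(from_a)
        if (n_a > 0) {
          m <- matrix(va[sample.int(ka, n_a * ka, replace = TRUE)], n_a, ka)
          cvs[from_a] <- row_cv(m)
        }
        if (n_a < n_lines) {
          m <- matrix(vb[sample.int(kb, (n_lines - n_a) * kb, replace = TRUE)],
                      n_lines - n_a, kb)
          cvs[!from_a] <- row_cv(m)
        }
        stats::sd(cvs, na.rm = TRUE)
      }, numeric(1))
      mean(per_trait_sd, na.rm = TRUE)
    }, numeric(1))
  })

  observed <- if (is.null(observed_cv)) {
    NA_real_
  } else {
    mean(apply(as.matrix(observed_cv), 2, stats::sd, na.rm = TRUE),
         na.rm = TRUE)
  }
  structure(
    list(model_mean = mean(model_sds), model_max = max(model_sds),
         model_sds = model_sds, observed = observed,
         exceeds = if (is.na(observed)) NA else observed > max(model_sds),
         n_models = n_models, n_lines = n_lines, n_traits = length(pa),
         scheme = "parent-mixture bootstrap (equal parent probability, replicate sets resampled with replacement at original size)",
         seed = seed),
    class = "transgression_model"
  )
}

# Row-wise CV of a matrix of replicate draws (NA for non-positive means).
row_cv <- function(m) {
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  out <- sdv / mu
  out[!(mu > 0)] <- NA_real_
  out
}

#' @export
print.transgression_model <- function(x, ...) {
  cat(sprintf(
    "parental-expectation model (%d models, %d lines, %d traits):\n",
    x$n_models, x$n_lines, x$n_traits))
  cat(sprintf("  average SD of CV: mean %.4f, max %.4f", x$model_mean,
              x$model_max))
  if (!is.na(x$observed)) {
    cat(sprintf("; observed %.4f (%s the envelope)", x$observed,
                if (isTRUE(x$exceeds)) "exceeds" else "within"))
  }
  cat("\n")
  invisible(x)
}
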