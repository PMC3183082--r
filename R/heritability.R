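#' Broad-sense heritability by one-way variance decomposition
#'
#' Treats each line's independent CV measures (one per experiment) as
#' replicate phenotypes and decomposes their variance with the method-of-
#' moments one-way random-effects (ANOVA) estimator: the within-line mean
#' square estimates the environmental variance, the between-line mean square
#' in excess of it (divided by the effective replicate count
#' \eqn{k_0 = (N - \sum k_i^2 / N) / (n - 1)}) estimates the genetic variance
#' among lines, and \eqn{H = \sigma^2_g / (\sigma^2_g + \sigma^2_e)}.
#' Negative genetic-variance estimates are clipped to 0, so H lies in [0, 1].
#'
#' @param measures per-line measurements: a matrix (lines x measures, NA
#'   allowed) or a named list of numeric vectors, one per line. Lines with
#'   fewer than 2 usable measures are excluded (with a message); at least 2
#'   usable lines are required.
#' @param trait_id optional label carried into the result.
#' @return List of class \code{heritability_estimate} with \code{H},
#'   \code{sigma2_g}, \code{sigma2_e}, \code{sigma2_p}, \code{n_lines},
#'   \code{k0}.
#' @export
broad_sense_h2 <- function(measures, trait_id = NA_character_) {
  if (is.matrix(measures) || is.data.frame(measures)) {
    measures <- as.matrix(measures)
    measures <- lapply(seq_len(nrow(measures)), function(i) measures[i, ])
  }
  measures <- lapply(measures, function(x) x[!is.na(x)])
  k <- lengths(measures)
  if (any(k < 2)) {
    message("excluding ", sum(k < 2), " line(s) with < 2 CV measures")
    measures <- measures[k >= 2]
    k <- k[k >= 2]
  }
  n <- length(measures)
  abort_if(n < 2, "need >= 2 lines with >= 2 measures each")

  N <- sum(k)
  ybar_i <- vapply(measures, mean, numeric(1))
  ybar <- sum(k * ybar_i) / N
  ss_within <- sum(vapply(measures, function(x) sum((x - mean(x))^2), numeric(1)))
  ss_between <- sum(k * (ybar_i - ybar)^2)
  msw <- ss_within / (N - n)
  msb <- ss_between / (n - 1)
  k0 <- (N - sum(k^2) / N) / (n - 1)

  sigma2_e <- msw
  sigma2_g <- max(0, (msb - msw) / k0)
  sigma2_p <- sigma2_g + sigma2_e
  H <- if (sigma2_p > 0) sigma2_g / sigma2_p else 0

  structure(
    list(trait_id = trait_id, H = H, sigma2_g = sigma2_g,
         sigma2_e = sigma2_e, sigma2_p = sigma2_p, n_lines = n, k0 = k0),
    class = "heritability_estimate"
  )
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("H = %.3f  (sigma2_g = %.4g, sigma2_e = %.4g, %d lines)\n",
              x$H, x$sigma2_g, x$sigma2_e, x$n_lines))
  invisible(x)
}

#' Heritability of CV from two parental genotypes
#'
#' The same one-way decomposition applied to exactly two genotype groups
#' (e.g. the two parents of a RIL population), each with >= 2 replicate CV
#' measures.
#'
#' @param parent_a_measures,parent_b_measures numeric vectors (>= 2 values).
#' @param trait_id optional label.
#' @return A \code{heritability_estimate}.
#' @export
parental_h2 <- function(parent_a_measures, parent_b_measures,
                        trait_id = NA_character_) {
  broad_sense_h2(list(A = parent_a_measures, B = parent_b_measures),
                 trait_id = trait_id)
}

#' Per-trait heritability of CV phenotypes
#'
#' Applies \code{\link{broad_sense_h2}} to each trait of a
#' \code{\link{cv_phenotypes}} object, using the per-experiment CVs as the
#' independent per-line measures. Per-experiment values are required:
#' aggregate-only CVs (a single value per line) cannot support a variance
#' decomposition and are refused.
#'
#' @param cvp a \code{cv_phenotypes} object with >= 2 experiments.
#' @return data.frame with columns \code{trait_id}, \code{H},
#'   \code{sigma2_g}, \code{sigma2_e}, \code{n_lines}.
#' @export
cv_heritability <- function(cvp) {
  stopifnot(inherits(cvp, "cv_phenotypes"))
  abort_if(dim(cvp$cv)[3] < 2,
           "heritability needs >= 2 independent CV measures per line ",
           "(per-experiment values; aggregate-only input is not usable)")
  res <- lapply(seq_along(cvp$traits), function(j) {
    h <- tryCatch(
      suppressMessages(broad_sense_h2(cvp$cv[, j, ], trait_id = cvp$traits[j])),
      error = function(e) NULL
    )
    if (is.null(h)) {
      data.frame(trait_id = cvp$traits[j], H = NA_real_, sigma2_g = NA_real_,
                 sigma2_e = NA_real_, n_lines = 0L)
    } else {
      data.frame(trait_id = h$trait_id, H = h$H, sigma2_g = h$sigma2_g,
                 sigma2_e = h$sigma2_e, n_lines = h$n_lines)
    }
  })
  do.call(rbind, res)
}

#' Pearson and partial correlations among CV, mean and heritability
#'
#' Descriptive relationships across traits: pairwise Pearson correlations
#' (with R-squared and two-sided p-values) among the average CV, the average
#' abundance and the heritability of CV, plus the partial correlation of
#' heritability with CV controlling for mean abundance — computed as the
#' correlation of the residuals of each variable regressed on the control.
#'
#' @param cv_by_trait,mean_by_trait,h2_by_trait aligned numeric vectors
#'   (same traits, same order; NAs tolerated pairwise).
#' @return List with \code{pairwise} (data.frame: var1, var2, r, r2, p, n)
#'   and \code{partial_h2_cv_given_mean} (list: r, p, n).
#' @export
cv_mean_relationships <- function(cv_by_trait, mean_by_trait, h2_by_trait) {
  vars <- list(cv = cv_by_trait, mean = mean_by_trait, h2 = h2_by_trait)
  n_all <- unique(lengths(vars))
  abort_if(length(n_all) != 1, "input vectors must be aligned (equal length)")

  pair <- function(a, b) {
    ok <- stats::complete.cases(vars[[a]], vars[[b]])
    if (sum(ok) < 3) {
      return(data.frame(var1 = a, var2 = b, r = NA_real_, r2 = NA_real_,
                        p = NA_real_, n = sum(ok)))
    }
    ct <- stats::cor.test(vars[[a]][ok], vars[[b]][ok])
    data.frame(var1 = a, var2 = b, r = unname(ct$estimate),
               r2 = unname(ct$estimate)^2, p = ct$p.value, n = sum(ok))
  }
  pairwise <- rbind(pair("cv", "mean"), pair("cv", "h2"), pair("mean", "h2"))

  ok <- stats::complete.cases(cv_by_trait, mean_by_trait, h2_by_trait)
  partial <- if (sum(ok) < 4) {
    list(r = NA_real_, p = NA_real_, n = sum(ok))
  } else {
    rx <- stats::resid(stats::lm(h2_by_trait[ok] ~ mean_by_trait[ok]))
    ry <- stats::resid(stats::lm(cv_by_trait[ok] ~ mean_by_trait[ok]))
    r <- stats::cor(rx, ry)
    n <- sum(ok)
    tt <- r * sqrt((n - 3) / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 3), n = n)
  }
  list(pairwise = pairwise, partial_h2_cv_given_mean = partial)
}
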