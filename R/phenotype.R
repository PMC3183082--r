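#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' each column's sorted values are replaced by the across-sample mean of the
#' order statistics, ties within a sample receiving the mean of the reference
#' values they span. This is the standard pre-processing step before CVs are
#' computed on the absolute expression scale. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param mat numeric matrix, traits (rows) x samples (columns), no missing
#'   values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  abort_if(anyNA(mat), "missing values: impute or drop before normalization")
  if (ncol(mat) < 2) {
    warning("single-sample input: quantile normalization is the identity")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Coefficient of variation of a replicate set
#'
#' CV = sample standard deviation (n - 1 denominator) divided by the mean;
#' dimensionless and invariant under positive rescaling. On expression-scale
#' data a non-positive mean makes the CV meaningless, so such cells are
#' flagged undefined (\code{NA}) rather than returned negative.
#'
#' @param x numeric vector of replicate measurements.
#' @return CV, or \code{NA} when fewer than 2 non-missing values or the mean
#'   is <= 0.
#' @examples
#' compute_cv(c(2, 4))   # sqrt(2)/3
#' @export
compute_cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  stats::sd(x) / m
}

# Vectorized CV over the replicate (4th) dimension of a 4-d array.
# Returns the 3-d array of per-(line, trait, experiment) CVs.
cv_over_replicates <- function(values) {
  d <- dim(values)
  flat <- matrix(values, nrow = prod(d[1:3]), ncol = d[4])
  n <- rowSums(!is.na(flat))
  m <- rowMeans(flat, na.rm = TRUE)
  ss <- rowSums((flat - m)^2, na.rm = TRUE)
  sdv <- sqrt(ss / (n - 1))
  cv <- sdv / m
  cv[n < 2 | !(m > 0)] <- NA_real_
  array(cv, dim = d[1:3], dimnames = dimnames(values)[1:3])
}

#' Per-line CV phenotypes from replicated trait data
#'
#' Computes, for every (line, trait) pair, one CV per experiment (over that
#' experiment's replicates) and their arithmetic mean across experiments —
#' the phenotype that is subsequently mapped. Cells with fewer than 2
#' replicates or a non-positive mean are undefined and a line's \code{cv_mean}
#' averages the remaining experiments. Traits with no valid cell in any line
#' are dropped with a message.
#'
#' @param traits a \code{\link{replicated_traits}} object.
#' @param pooled if TRUE, additionally compute a single CV per (line, trait)
#'   from all experiments' replicates pooled (\code{cv_pooled}); the default
#'   phenotype remains the per-experiment average.
#' @return An object of class \code{cv_phenotypes}: list with
#'   \code{cv} (3-d array lines x traits x experiments),
#'   \code{cv_mean} (matrix lines x traits) and optionally \code{cv_pooled}.
#' @export
cv_phenotypes <- function(traits, pooled = FALSE) {
  stopifnot(inherits(traits, "replicated_traits"))
  v <- traits$values
  cv <- cv_over_replicates(v)
  cv_mean <- apply(cv, c(1, 2), function(z) {
    z <- z[!is.na(z)]
    if (length(z) == 0) NA_real_ else mean(z)
  })

  dead <- colSums(!is.na(cv_mean)) == 0
  if (any(dead)) {
    message("dropping ", sum(dead), " trait(s) with no valid CV in any line: ",
            paste(utils::head(colnames(cv_mean)[dead], 5), collapse = ", "))
    cv <- cv[, !dead, , drop = FALSE]
    cv_mean <- cv_mean[, !dead, drop = FALSE]
  }

  out <- list(cv = cv, cv_mean = cv_mean,
              lines = rownames(cv_mean), traits = colnames(cv_mean))
  if (pooled) {
    d <- dim(v)
    flat <- array(v, dim = c(d[1], d[2], 1, d[3] * d[4]),
                  dimnames = c(dimnames(v)[1:2], list(NULL, NULL)))
    pooled_arr <- cv_over_replicates(flat)
    out$cv_pooled <- matrix(pooled_arr, dim(pooled_arr)[1],
                            dim(pooled_arr)[2],
                            dimnames = dimnames(pooled_arr)[1:2])
  }
  structure(out, class = "cv_phenotypes")
}

#' @export
print.cv_phenotypes <- function(x, ...) {
  cat(sprintf("cv_phenotypes: %d lines x %d traits, %d experiment(s)\n",
              nrow(x$cv_mean), ncol(x$cv_mean), dim(x$cv)[3]))
  invisible(x)
}

#' Network expression values (z-transform then average)
#'
#' Implements the a-priori network summary: every member trait is z-scored
#' across all samples (all line x experiment x replicate measurements pooled:
#' mean 0, SD 1), then for each sample the network value is the average of
#' the member z-scores. The result is a \code{replicated_traits} object with
#' one "trait" per network, so network CVs are obtained by passing it to
#' \code{\link{cv_phenotypes}}.
#'
#' @param traits a \code{\link{replicated_traits}} object.
#' @param networks named list: network id -> character vector of member
#'   trait ids (memberships may overlap between networks).
#' @return A \code{replicated_traits} object of network values (z-units).
#' @export
network_values <- function(traits, networks) {
  stopifnot(inherits(traits, "replicated_traits"))
  abort_if(is.null(names(networks)) || any(names(networks) == ""),
           "`networks` must be a named list")
  v <- traits$values
  d <- dim(v)

  miss <- setdiff(unique(unlist(networks)), traits$traits)
  abort_if(length(miss) > 0,
           "network members absent from trait data: ",
           paste(utils::head(miss, 5), collapse = ", "))

  # z-score each trait across all pooled samples
  flat <- aperm(v, c(1, 3, 4, 2))               # line, exp, rep, trait
  flat <- matrix(flat, ncol = d[2])             # samples x traits
  mu <- colMeans(flat, na.rm = TRUE)
  sdv <- apply(flat, 2, stats::sd, na.rm = TRUE)
  zero_var <- !(sdv > 0) | is.na(sdv)
  z <- sweep(sweep(flat, 2, mu, "-"), 2, sdv, "/")
  colnames(z) <- traits$traits

  out <- array(NA_real_, dim = c(d[1], length(networks), d[3], d[4]),
               dimnames = list(dimnames(v)[[1]], names(networks),
                               dimnames(v)[[3]], dimnames(v)[[4]]))
  for (k in seq_along(networks)) {
    members <- networks[[k]]
    drop_m <- members[zero_var[match(members, traits$traits)]]
    if (length(drop_m) > 0) {
      message("network ", names(networks)[k], ": excluding zero-variance member(s) ",
              paste(drop_m, collapse = ", "))
      members <- setdiff(members, drop_m)
    }
    abort_if(length(members) == 0,
             "network ", names(networks)[k], " has no usable members")
    nv <- rowMeans(z[, members, drop = FALSE])
    out[, k, , ] <- array(nv, dim = d[c(1, 3, 4)])
  }
  replicated_traits(out)
}

#' Genome-wide average CV per line
#'
#' The per-line "global" CV: the unweighted mean of \code{cv_mean} across all
#' traits, the single phenotype summarizing a line's overall stochastic
#' noise.
#'
#' @param cvp a \code{\link{cv_phenotypes}} object.
#' @return Named numeric vector, one value per line.
#' @export
global_cv <- function(cvp) {
  stopifnot(inherits(cvp, "cv_phenotypes"))
  ok <- rowSums(!is.na(cvp$cv_mean)) >= 1
  out <- rowMeans(cvp$cv_mean, na.rm = TRUE)
  out[!ok] <- NA_real_
  out
}

#' Circadian-time phase-group values
#'
#' Groups traits into (up to) 24 circadian-time phase groups by their time of
#' peak expression and summarizes each group exactly as a network: member
#' traits are z-scored, then averaged per sample. Empty groups are omitted
#' with a warning.
#'
#' @param traits a \code{\link{replicated_traits}} object.
#' @param phase_assignments named integer vector (or named factor):
#'   trait id -> phase group in 0..23.
#' @return A \code{replicated_traits} object with one "trait" per phase
#'   group, named \code{CT<group>}.
#' @export
phase_group_values <- function(traits, phase_assignments) {
  abort_if(is.null(names(phase_assignments)),
           "`phase_assignments` must be named by trait id")
  grp <- as.integer(phase_assignments)
  abort_if(any(!grp %in% 0:23), "phase groups must be integers in 0..23")
  networks <- split(names(phase_assignments), grp)
  names(networks) <- sprintf("CT%s", names(networks))
  empty <- setdiff(sprintf("CT%d", 0:23), names(networks))
  if (length(empty) > 0) {
    warning("omitting empty phase group(s): ", paste(empty, collapse = ", "))
  }
  network_values(traits, networks)
}
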