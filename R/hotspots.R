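#' Count QTL calls per genome position
#'
#' Aggregates peak positions of QTL calls from many traits onto the scan
#' grid: each call contributes 1 at its peak position (off-grid peaks are
#' assigned to the nearest position on the same chromosome, with a message).
#' The counts sum exactly to the number of calls.
#'
#' @param calls a \code{qtl_calls} data.frame pooled over traits (columns
#'   \code{chrom}, \code{pos}; extra columns ignored).
#' @param positions data.frame with \code{chrom}, \code{pos} defining the
#'   genome positions (e.g. \code{grid$positions}).
#' @return Integer vector of counts, one per row of \code{positions}.
#' @export
count_qtl_per_position <- function(calls, positions) {
  counts <- integer(nrow(positions))
  if (nrow(calls) == 0) return(counts)
  off_grid <- 0L
  for (i in seq_len(nrow(calls))) {
    same <- which(positions$chrom == calls$chrom[i])
    abort_if(length(same) == 0,
             "call on chromosome ", calls$chrom[i], " absent from positions")
    d <- abs(positions$pos[same] - calls$pos[i])
    j <- same[which.min(d)]
    if (min(d) > 1e-9) off_grid <- off_grid + 1L
    counts[j] <- counts[j] + 1L
  }
  if (off_grid > 0) {
    message(off_grid, " call(s) were off-grid and assigned to the nearest position")
  }
  counts
}

#' Sliding-window profile of QTL counts
#'
#' At each position, the mean of the raw per-position counts over all
#' positions on the same chromosome within +/- window/2 cM. Chromosome ends
#' use truncated windows (fewer positions in the mean).
#'
#' @param counts raw counts from \code{\link{count_qtl_per_position}}.
#' @param positions matching positions data.frame.
#' @param window_cM full window width, default 2.5 cM.
#' @return Numeric vector of window-averaged counts.
#' @export
sliding_window_profile <- function(counts, positions, window_cM = 2.5) {
  abort_if(window_cM <= 0, "`window_cM` must be > 0")
  half <- window_cM / 2
  out <- numeric(length(counts))
  for (ch in unique(positions$chrom)) {
    idx <- which(positions$chrom == ch)
    p <- positions$pos[idx]
    for (k in seq_along(idx)) {
      inwin <- abs(p - p[k]) <= half
      out[idx[k]] <- mean(counts[idx][inwin])
    }
  }
  out
}

#' Permutation threshold for QTL hotspots
#'
#' Null model for co-localization: the observed total number of QTLs is
#' thrown independently and uniformly onto the genome positions (optionally
#' weighted), the maximum per-position count is recorded for each
#' permutation, and the threshold is the (1 - alpha) quantile of those
#' maxima. A position whose observed count exceeds the threshold is a
#' significant hotspot. With \code{method = "per_trait"} each trait's QTLs
#' are instead placed at distinct positions (sampled without replacement
#' within a trait), preserving the per-trait QTL counts.
#'
#' @param total_qtl_count total number of QTLs (>= 1); ignored when
#'   \code{qtl_counts_per_trait} is given with \code{method = "per_trait"}.
#' @param n_positions number of genome positions (grid size).
#' @param n_perm number of permutations, default 1000.
#' @param alpha significance level, default 0.05.
#' @param weights optional per-position placement probabilities (e.g.
#'   interval cM lengths); default uniform.
#' @param method "independent" (default) throws all QTLs independently;
#'   "per_trait" preserves per-trait counts and forbids two QTLs of one trait
#'   landing on the same position.
#' @param qtl_counts_per_trait integer vector of per-trait QTL counts
#'   (required for \code{method = "per_trait"}).
#' @param seed optional integer seed.
#' @return List of class \code{hotspot_threshold} with \code{threshold}
#'   (count), \code{max_counts} (the n_perm maxima), \code{alpha},
#'   \code{n_perm}.
#' @export
hotspot_threshold <- function(total_qtl_count, n_positions, n_perm = 1000,
                              alpha = 0.05, weights = NULL,
                              method = c("independent", "per_trait"),
                              qtl_counts_per_trait = NULL, seed = NULL) {
  method <- match.arg(method)
  abort_if(n_positions < 1, "`n_positions` must be >= 1")
  prob <- weights %||% rep(1, n_positions)
  abort_if(length(prob) != n_positions, "`weights` length must equal n_positions")
  with_seed(seed, {
    if (method == "independent") {
      abort_if(is.null(total_qtl_count) || total_qtl_count < 1,
               "`total_qtl_count` must be >= 1")
      draws <- stats::rmultinom(n_perm, size = total_qtl_count,
                                prob = prob / sum(prob))
      maxima <- apply(draws, 2, max)
    } else {
      abort_if(is.null(qtl_counts_per_trait),
               "`qtl_counts_per_trait` is required for method = 'per_trait'")
      abort_if(any(qtl_counts_per_trait > n_positions),
               "a trait has more QTLs than there are positions")
      maxima <- integer(n_perm)
      for (b in seq_len(n_perm)) {
        counts <- integer(n_positions)
        for (m in qtl_counts_per_trait) {
          hit <- sample.int(n_positions, m, replace = FALSE,
                            prob = prob / sum(prob))
          counts[hit] <- counts[hit] + 1L
        }
        maxima[b] <- max(counts)
      }
    }
    structure(
      list(threshold = stats::quantile(maxima, 1 - alpha, names = FALSE,
                                       type = 1),
           max_counts = maxima, alpha = alpha, n_perm = n_perm,
           method = method, seed = seed),
      class = "hotspot_threshold"
    )
  })
}

#' @export
print.hotspot_threshold <- function(x, ...) {
  cat(sprintf("hotspot_threshold: %g QTLs per position at alpha = %g (%d perms, %s null)\n",
              x$threshold, x$alpha, x$n_perm, x$method))
  invisible(x)
}

#' Co-localization threshold for a small phenotype family
#'
#' The hotspot permutation machinery applied to the pooled QTL calls of a
#' small, focused trait family (e.g. a few dozen metabolite CV traits):
#' returns the count above which co-localized QTLs are more clustered than
#' uniform placement explains.
#'
#' @param calls pooled \code{qtl_calls} for the family (its row count is the
#'   total thrown per permutation).
#' @param n_positions,n_perm,alpha,weights,seed as in
#'   \code{\link{hotspot_threshold}}.
#' @return A \code{hotspot_threshold} object.
#' @export
colocalization_threshold <- function(calls, n_positions, n_perm = 1000,
                                     alpha = 0.05, weights = NULL,
                                     seed = NULL) {
  hotspot_threshold(nrow(calls), n_positions, n_perm = n_perm, alpha = alpha,
                    weights = weights, seed = seed)
}

#' Sign bias of additive effects near a hotspot
#'
#' Collects the QTL calls within a window around a hotspot position, counts
#' positive and negative additive effects (B/Sha-allele convention), and
#' tests the split against 0.5 with a two-sided exact binomial test. Zero
#' effects belong to neither class and are reported separately.
#'
#' @param calls pooled \code{qtl_calls} (needs \code{chrom}, \code{pos},
#'   \code{effect}).
#' @param center list with \code{chrom} and \code{pos} of the hotspot.
#' @param window_cM full window width, default 2.5 cM (the profile window).
#' @return List with \code{n_positive}, \code{n_negative}, \code{n_zero},
#'   \code{p_value}, \code{window_cM}.
#' @export
effect_sign_summary <- function(calls, center, window_cM = 2.5) {
  half <- window_cM / 2
  inwin <- calls$chrom == as.character(center$chrom) &
    abs(calls$pos - center$pos) <= half
  abort_if(!any(inwin), "no QTL calls within the window around the hotspot")
  eff <- calls$effect[inwin]
  n_pos <- sum(eff > 0)
  n_neg <- sum(eff < 0)
  n_zero <- sum(eff == 0)
  p <- if (n_pos + n_neg == 0) {
    NA_real_
  } else {
    stats::binom.test(n_pos, n_pos + n_neg, p = 0.5)$p.value
  }
  list(n_positive = n_pos, n_negative = n_neg, n_zero = n_zero,
       p_value = p, window_cM = window_cM)
}
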