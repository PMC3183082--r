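#' Build the genome scan grid of expected QTL genotypes
#'
#' Lays pseudomarkers at a fixed walking step along every chromosome and, for
#' each line, computes the expected genotype score E[x] in [-1, 1] at every
#' position by conditioning on the nearest non-missing flanking markers under
#' the selfed-RIL Markov transition probabilities (Haldane distances inflated
#' by \code{\link{rf_selfed_ril}}). At an observed marker E[x] equals the
#' observed -1/+1 code; a line with no genotyped marker on a chromosome gets
#' E[x] = 0 (the population mean) there, with a warning.
#'
#' @param geno genotype matrix (lines x markers, -1/+1/NA).
#' @param map matching \code{cvqtl_map}.
#' @param step_cM walking speed in cM (> 0), default 1.
#' @return Object of class \code{scan_grid}: list with \code{positions}
#'   (data.frame chrom, pos), \code{Ex} (lines x positions), and the marker
#'   genotypes (column-mean imputed) used for cofactor regression.
#' @export
build_scan_grid <- function(geno, map, step_cM = 1) {
  validate_map(map)
  abort_if(step_cM <= 0, "`step_cM` must be > 0")
  abort_if(!all(map$marker %in% colnames(geno)),
           "genotype matrix is missing markers named in the map")
  geno <- geno[, map$marker, drop = FALSE]
  n <- nrow(geno)

  pos_list <- list()
  ex_list <- list()
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    mpos <- sub$pos
    G <- geno[, sub$marker, drop = FALSE]
    gpos <- seq(mpos[1], mpos[length(mpos)], by = step_cM)
    if (gpos[length(gpos)] < mpos[length(mpos)]) {
      gpos <- c(gpos, mpos[length(mpos)])
    }
    # snap grid points onto marker positions they (nearly) coincide with,
    # so E[x] reduces exactly to the observed code there
    snap <- vapply(gpos, function(p) {
      j <- which.min(abs(mpos - p))
      if (abs(mpos[j] - p) < 1e-9) mpos[j] else p
    }, numeric(1))
    gpos <- snap

    Ex <- matrix(NA_real_, n, length(gpos),
                 dimnames = list(rownames(geno), NULL))
    iL <- findInterval(gpos, mpos)
    for (k in seq_along(gpos)) {
      p <- gpos[k]
      l <- iL[k]
      if (mpos[l] == p) {
        Ex[, k] <- G[, l]
      } else {
        r <- l + 1
        RL <- rf_selfed_ril(p - mpos[l])
        RR <- rf_selfed_ril(mpos[r] - p)
        gL <- G[, l]; gR <- G[, r]
        pB <- ifelse(gL == 1, 1 - RL, RL) * ifelse(gR == 1, 1 - RR, RR)
        pA <- ifelse(gL == -1, 1 - RL, RL) * ifelse(gR == -1, 1 - RR, RR)
        Ex[, k] <- (pB - pA) / (pB + pA)
      }
    }

    # lines with missing data on this chromosome: condition on the nearest
    # non-missing flanks individually
    bad <- which(rowSums(is.na(G)) > 0)
    for (i in bad) {
      obs <- which(!is.na(G[i, ]))
      if (length(obs) == 0) {
        warning("line ", rownames(geno)[i], " has no genotyped marker on ",
                "chromosome ", ch, "; E[x] set to 0 there")
        Ex[i, ] <- 0
        next
      }
      opos <- mpos[obs]
      og <- G[i, obs]
      li <- findInterval(gpos, opos)
      for (k in seq_along(gpos)) {
        p <- gpos[k]
        l <- li[k]
        if (l >= 1 && opos[l] == p) {
          Ex[i, k] <- og[l]
        } else if (l == 0) {
          Ex[i, k] <- og[1] * (1 - 2 * rf_selfed_ril(opos[1] - p))
        } else if (l == length(obs)) {
          Ex[i, k] <- og[l] * (1 - 2 * rf_selfed_ril(p - opos[l]))
        } else {
          RL <- rf_selfed_ril(p - opos[l])
          RR <- rf_selfed_ril(opos[l + 1] - p)
          gL <- og[l]; gR <- og[l + 1]
          pB <- (if (gL == 1) 1 - RL else RL) * (if (gR == 1) 1 - RR else RR)
          pA <- (if (gL == -1) 1 - RL else RL) * (if (gR == -1) 1 - RR else RR)
          Ex[i, k] <- (pB - pA) / (pB + pA)
        }
      }
    }
    colnames(Ex) <- sprintf("%s@%g", ch, gpos)
    pos_list[[ch]] <- data.frame(chrom = ch, pos = gpos,
                                 stringsAsFactors = FALSE)
    ex_list[[ch]] <- Ex
  }

  marker_geno <- geno
  if (anyNA(marker_geno)) {
    for (j in seq_len(ncol(marker_geno))) {
      nas <- is.na(marker_geno[, j])
      if (any(nas)) marker_geno[nas, j] <- mean(marker_geno[, j], na.rm = TRUE)
    }
  }

  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  structure(
    list(positions = positions,
         Ex = do.call(cbind, ex_list),
         marker_geno = marker_geno,
         marker_chrom = map$chrom, marker_pos = map$pos,
         markers = map$marker, step_cM = step_cM,
         lines = rownames(geno)),
    class = "scan_grid"
  )
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("scan_grid: %d lines, %d positions on %d chromosome(s), step %g cM\n",
              nrow(x$Ex), ncol(x$Ex), length(unique(x$positions$chrom)),
              x$step_cM))
  invisible(x)
}

# Forward-stepwise BIC core on an arbitrary candidate matrix.
# Returns integer indices of selected columns (genome order breaks ties via
# which.min taking the first minimum).
forward_bic <- function(y, X, max_terms) {
  n <- length(y)
  if (max_terms == 0 || ncol(X) == 0) return(integer(0))
  sel <- integer(0)
  ry <- y - mean(y)
  RX <- sweep(X, 2, colMeans(X), "-")
  rss <- sum(ry^2)
  p <- 1L
  bic <- n * log(rss / n) + p * log(n)
  repeat {
    sxx <- colSums(RX^2)
    sxy <- as.vector(crossprod(RX, ry))
    gain <- ifelse(sxx > 1e-10, sxy^2 / sxx, 0)
    gain[sel] <- 0
    rss_new <- rss - gain
    bic_new <- n * log(pmax(rss_new, 1e-300) / n) + (p + 1) * log(n)
    j <- which.min(bic_new)
    if (bic_new[j] >= bic || gain[j] <= 0) break
    sel <- c(sel, j)
    # residualize y and remaining candidates on the accepted column
    xj <- RX[, j]
    sxxj <- sum(xj^2)
    ry <- ry - xj * (sum(xj * ry) / sxxj)
    beta <- as.vector(crossprod(RX, xj)) / sxxj
    RX <- RX - outer(xj, beta)
    rss <- sum(ry^2)
    p <- p + 1L
    bic <- n * log(pmax(rss, 1e-300) / n) + p * log(n)
    if (length(sel) >= max_terms) break
  }
  sel  # in selection order
}

#' Select background cofactor markers for composite interval mapping
#'
#' Forward stepwise regression of the phenotype on marker genotypes, adding
#' at each step the marker that most reduces the BIC, stopping when no marker
#' improves it or \code{max_cofactors} are chosen. Deterministic; ties are
#' broken by genome order.
#'
#' @param y phenotype vector aligned to the grid's lines (NA = missing).
#' @param grid a \code{\link{build_scan_grid}} result.
#' @param max_cofactors maximum number of cofactors (default 5); 0 yields
#'   pure interval mapping.
#' @return Character vector of selected marker names (possibly empty).
#' @export
select_cofactors <- function(y, grid, max_cofactors = 5) {
  stopifnot(inherits(grid, "scan_grid"))
  ok <- !is.na(y)
  abort_if(sum(ok) < 3, "need >= 3 non-missing phenotype values")
  sel <- forward_bic(y[ok], grid$marker_geno[ok, , drop = FALSE], max_cofactors)
  grid$markers[sel]
}

# Core CIM statistics at every grid position.
# y: complete phenotype vector; Ex: matching rows of grid$Ex; cof: matrix of
# cofactor genotype columns (may have 0 columns); returns lrt and effect
# vectors. Positions sharing an active-cofactor set are solved together.
scan_core <- function(y, Ex, cof, cof_chrom, cof_pos, pos_chrom, pos_cM,
                      window_cM) {
  n <- length(y)
  npos <- length(pos_cM)
  lrt <- numeric(npos)
  eff <- numeric(npos)
  ncof <- ncol(cof)

  if (ncof == 0) {
    keys <- rep("", npos)
  } else {
    excl <- matrix(FALSE, npos, ncof)
    for (j in seq_len(ncof)) {
      excl[, j] <- pos_chrom == cof_chrom[j] &
        abs(pos_cM - cof_pos[j]) <= window_cM
    }
    keys <- apply(excl, 1, function(e) paste(which(!e), collapse = ","))
  }

  for (key in unique(keys)) {
    idx <- which(keys == key)
    active <- if (key == "") integer(0) else as.integer(strsplit(key, ",")[[1]])
    D <- cbind(1, cof[, active, drop = FALSE])
    qrD <- qr(D)
    ry <- qr.resid(qrD, y)
    rssy <- sum(ry^2)
    RE <- qr.resid(qrD, Ex[, idx, drop = FALSE])
    sxx <- colSums(RE^2)
    sxy <- as.vector(crossprod(RE, ry))
    degen <- sxx <= 1e-10 * n
    if (any(degen)) {
      # E[x] collinear with an active cofactor at these positions: drop the
      # most collinear cofactor and refit position by position
      for (kk in idx[degen]) {
        act <- active
        repeat {
          if (length(act) == 0) break
          cors <- abs(stats::cor(cof[, act, drop = FALSE], Ex[, kk]))
          act2 <- act[-which.max(cors)]
          D2 <- cbind(1, cof[, act2, drop = FALSE])
          q2 <- qr(D2)
          re2 <- qr.resid(q2, Ex[, kk])
          act <- act2
          if (sum(re2^2) > 1e-10 * n) {
            ry2 <- qr.resid(q2, y)
            rss2 <- sum(ry2^2)
            sxy2 <- sum(re2 * ry2)
            r2 <- if (rss2 > 0) sxy2^2 / (sum(re2^2) * rss2) else 0
            r2 <- min(r2, 1 - 1e-12)
            lrt[kk] <- n * log(1 / (1 - r2))
            eff[kk] <- sxy2 / sum(re2^2)
            break
          }
        }
      }
      idx <- idx[!degen]
      if (length(idx) == 0) next
      keep <- !degen
      sxx <- sxx[keep]; sxy <- sxy[keep]
    }
    if (rssy <= 0) {
      lrt[idx] <- 0; eff[idx] <- 0
    } else {
      r2 <- pmin(sxy^2 / (sxx * rssy), 1 - 1e-12)
      lrt[idx] <- n * log(1 / (1 - r2))
      eff[idx] <- sxy / sxx
    }
  }
  list(lrt = lrt, effect = eff)
}

#' Composite interval mapping scan by Haley-Knott regression
#'
#' At each grid position the phenotype is regressed on the expected genotype
#' score E[x] plus the selected cofactor markers, excluding any cofactor
#' within \code{window_cM} of the test position on the same chromosome
#' (closed interval). The test statistic is
#' \eqn{LRT = n \ln(RSS_{reduced} / RSS_{full})}, with the reduced model
#' lacking E[x]; \eqn{LOD = LRT / (2 \ln 10)}. The additive effect is the
#' regression coefficient on E[x], so a positive effect means the B (Sha)
#' allele raises the phenotype.
#'
#' @param y phenotype vector aligned to the grid's lines (NA = missing;
#'   complete-case per trait).
#' @param grid a \code{\link{build_scan_grid}} result.
#' @param cofactors character vector of cofactor marker names (typically from
#'   \code{\link{select_cofactors}}); NULL or empty for pure interval mapping.
#' @param window_cM exclusion window around the test position, default 10 cM.
#' @param trait_id optional label stored on the result.
#' @return data.frame of class \code{qtl_scan} with columns \code{chrom},
#'   \code{pos}, \code{lrt}, \code{lod}, \code{effect}; attribute \code{n} is
#'   the number of lines used.
#' @export
cim_scan <- function(y, grid, cofactors = NULL, window_cM = 10,
                     trait_id = NULL) {
  stopifnot(inherits(grid, "scan_grid"))
  ok <- !is.na(y)
  cofactors <- cofactors %||% character(0)
  abort_if(!all(cofactors %in% grid$markers),
           "unknown cofactor marker(s): ",
           paste(setdiff(cofactors, grid$markers), collapse = ", "))
  abort_if(sum(ok) < length(cofactors) + 3,
           "need at least (number of cofactors + 3) complete lines")
  ci <- match(cofactors, grid$markers)
  st <- scan_core(
    y = y[ok],
    Ex = grid$Ex[ok, , drop = FALSE],
    cof = grid$marker_geno[ok, ci, drop = FALSE],
    cof_chrom = grid$marker_chrom[ci], cof_pos = grid$marker_pos[ci],
    pos_chrom = grid$positions$chrom, pos_cM = grid$positions$pos,
    window_cM = window_cM
  )
  out <- data.frame(
    chrom = grid$positions$chrom, pos = grid$positions$pos,
    lrt = st$lrt, lod = st$lrt / (2 * log(10)), effect = st$effect,
    stringsAsFactors = FALSE
  )
  attr(out, "trait_id") <- trait_id
  attr(out, "n") <- sum(ok)
  attr(out, "cofactors") <- cofactors
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Genome-wide permutation threshold for CV QTL scans
#'
#' Estimates the genome-wide null distribution of the maximum LRT: for each
#' of \code{n_traits} randomly sampled phenotypes, the phenotype values are
#' permuted across lines \code{n_perm} times (genotypes fixed), cofactors are
#' reselected and the genome rescanned for each permutation, and the maximum
#' LRT recorded. The default threshold is the (1 - alpha) quantile of the
#' pooled \code{n_traits x n_perm} maxima; the per-trait (1 - alpha)
#' thresholds and their own (1 - alpha) quantile (the quantile-of-thresholds
#' reading) are reported alongside.
#'
#' @param cv_matrix phenotype matrix, lines x traits (e.g. \code{cv_mean}
#'   from \code{\link{cv_phenotypes}}).
#' @param grid a \code{\link{build_scan_grid}} result.
#' @param n_traits number of phenotypes to sample (default 100; all traits,
#'   with a warning, when fewer are available).
#' @param n_perm permutations per phenotype (default 1000).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param max_cofactors,window_cM scan settings, as in \code{\link{cim_scan}}.
#' @param seed optional integer seed; the threshold reproduces under a fixed
#'   seed.
#' @return Object of class \code{perm_threshold}: list with \code{threshold}
#'   (pooled LRT threshold), \code{per_trait_thresholds},
#'   \code{threshold_of_thresholds}, \code{max_lrt} (n_perm x n_traits
#'   matrix), \code{alpha}, \code{n_perm}, \code{n_traits}, \code{seed}.
#' @export
permutation_threshold <- function(cv_matrix, grid, n_traits = 100,
                                  n_perm = 1000, alpha = 0.05,
                                  max_cofactors = 5, window_cM = 10,
                                  seed = NULL) {
  stopifnot(inherits(grid, "scan_grid"))
  cv_matrix <- as.matrix(cv_matrix)
  if (n_perm < 1 / alpha) {
    warning("n_perm = ", n_perm, " is small for alpha = ", alpha,
            "; the tail quantile will be coarse")
  }
  if (ncol(cv_matrix) < n_traits) {
    warning("only ", ncol(cv_matrix), " traits available; using all of them")
    n_traits <- ncol(cv_matrix)
  }
  with_seed(seed, {
    pick <- sort(sample.int(ncol(cv_matrix), n_traits))
    maxima <- matrix(NA_real_, n_perm, n_traits)
    for (t_i in seq_along(pick)) {
      y0 <- cv_matrix[, pick[t_i]]
      ok <- !is.na(y0)
      y0 <- y0[ok]
      n <- length(y0)
      Ex <- grid$Ex[ok, , drop = FALSE]
      Exc <- sweep(Ex, 2, colMeans(Ex), "-")
      sxx0 <- colSums(Exc^2)
      M <- grid$marker_geno[ok, , drop = FALSE]
      for (p_i in seq_len(n_perm)) {
        yp <- y0[sample.int(n)]
        sel <- forward_bic(yp, M, max_cofactors)
        if (length(sel) == 0) {
          # fast interval-mapping path: no cofactors anywhere
          yc <- yp - mean(yp)
          rssy <- sum(yc^2)
          r2 <- pmin((as.vector(crossprod(Exc, yc)))^2 /
                       pmax(sxx0, 1e-300) / rssy, 1 - 1e-12)
          maxima[p_i, t_i] <- n * log(1 / (1 - max(r2)))
        } else {
          st <- scan_core(
            yp, Ex, M[, sel, drop = FALSE],
            grid$marker_chrom[sel], grid$marker_pos[sel],
            grid$positions$chrom, grid$positions$pos, window_cM
          )
          maxima[p_i, t_i] <- max(st$lrt)
        }
      }
    }
    per_trait <- apply(maxima, 2, stats::quantile, probs = 1 - alpha,
                       names = FALSE)
    structure(
      list(threshold = stats::quantile(maxima, 1 - alpha, names = FALSE),
           per_trait_thresholds = per_trait,
           threshold_of_thresholds = stats::quantile(per_trait, 1 - alpha,
                                                     names = FALSE),
           max_lrt = maxima, alpha = alpha, n_perm = n_perm,
           n_traits = n_traits, sampled_traits = colnames(cv_matrix)[pick],
           seed = seed),
      class = "perm_threshold"
    )
  })
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf(
    "perm_threshold: pooled LRT threshold %.3f (LOD %.3f) at alpha = %g\n",
    x$threshold, x$threshold / (2 * log(10)), x$alpha))
  cat(sprintf("  %d traits x %d permutations; quantile-of-thresholds %.3f\n",
              x$n_traits, x$n_perm, x$threshold_of_thresholds))
  invisible(x)
}

#' Call QTL peaks from a scan
#'
#' Greedy peak picking: the genome-wide maximum LRT above the threshold is
#' called, its contiguous above-threshold support region recorded, all
#' positions within \code{min_separation_cM} of the peak (same chromosome,
#' closed interval) are masked, and the process repeats. Ties in LRT are
#' broken by leftmost genome order.
#'
#' @param scan a \code{\link{cim_scan}} result.
#' @param threshold LRT threshold: a number or a
#'   \code{\link{permutation_threshold}} object (its pooled threshold is
#'   used).
#' @param min_separation_cM exclusion radius between called peaks, default
#'   5 cM.
#' @return data.frame of class \code{qtl_calls} with columns
#'   \code{trait_id}, \code{chrom}, \code{pos}, \code{lrt}, \code{lod},
#'   \code{effect}, \code{support_start}, \code{support_end}; empty when
#'   nothing exceeds the threshold.
#' @export
call_qtl <- function(scan, threshold, min_separation_cM = 5) {
  stopifnot(inherits(scan, "qtl_scan"))
  if (inherits(threshold, "perm_threshold")) threshold <- threshold$threshold
  trait_id <- attr(scan, "trait_id") %||% NA_character_

  above <- scan$lrt > threshold
  work <- ifelse(above, scan$lrt, -Inf)
  calls <- list()
  while (any(is.finite(work))) {
    k <- which.max(work)
    same <- scan$chrom == scan$chrom[k]
    # contiguous above-threshold run around the peak on its chromosome
    runs <- rle(above & same)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    ri <- which(starts <= k & ends >= k)
    calls[[length(calls) + 1]] <- data.frame(
      trait_id = trait_id, chrom = scan$chrom[k], pos = scan$pos[k],
      lrt = scan$lrt[k], lod = scan$lod[k], effect = scan$effect[k],
      support_start = scan$pos[starts[ri]], support_end = scan$pos[ends[ri]],
      stringsAsFactors = FALSE
    )
    work[same & abs(scan$pos - scan$pos[k]) <= min_separation_cM] <- -Inf
  }
  out <- if (length(calls) == 0) {
    data.frame(trait_id = character(0), chrom = character(0),
               pos = numeric(0), lrt = numeric(0), lod = numeric(0),
               effect = numeric(0), support_start = numeric(0),
               support_end = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, calls)
  }
  class(out) <- c("qtl_calls", "data.frame")
  out
}

#' Classify QTL calls as cis or trans
#'
#' A call is cis when it sits on the same chromosome as the gene whose
#' transcript (or trait) it controls and within \code{cis_window_cM} of that
#' locus (closed interval: exactly at the window edge is still cis); anything
#' else is trans. Calls for traits without a known location are unclassified.
#'
#' @param calls a \code{\link{call_qtl}} result (any data.frame with
#'   \code{chrom}, \code{pos}).
#' @param trait_locus list or data.frame row with \code{chrom} and \code{pos}
#'   of the trait's own genomic location, or NULL if unknown.
#' @param cis_window_cM window half-width, default 5 cM.
#' @return Character vector ("cis"/"trans"/"unclassified"), one per call.
#' @export
classify_cis_trans <- function(calls, trait_locus, cis_window_cM = 5) {
  if (is.null(trait_locus) || is.na(trait_locus$chrom %||% NA)) {
    return(rep("unclassified", nrow(calls)))
  }
  ifelse(
    calls$chrom == as.character(trait_locus$chrom) &
      abs(calls$pos - trait_locus$pos) <= cis_window_cM,
    "cis", "trans"
  )
}
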