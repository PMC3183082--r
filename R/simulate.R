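#' Build an evenly spaced framework genetic map
#'
#' Creates a grid of markers at a fixed cM spacing on each chromosome,
#' mimicking the ~5 cM framework maps used for biparental RIL populations.
#' The grid runs from 0 cM up to the largest multiple of \code{spacing_cM}
#' that does not exceed \code{chrom_length_cM}, inclusive of 0.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length_cM chromosome length in centimorgans.
#' @param spacing_cM marker spacing in centimorgans (> 0).
#' @param seed ignored; the map is deterministic given the other arguments.
#'   Kept so map construction slots into seeded simulation pipelines.
#' @return A data.frame of class \code{cvqtl_map} with columns
#'   \code{marker}, \code{chrom}, \code{pos} (cM). Markers are named
#'   \code{M<chrom>_<index>} and are unique genome-wide.
#' @examples
#' simulate_genetic_map(1, 10, 5)
#' @export
simulate_genetic_map <- function(n_chrom, chrom_length_cM, spacing_cM,
                                 seed = NULL) {
  abort_if(!is.numeric(n_chrom) || n_chrom < 1,
           "`n_chrom` must be a positive integer")
  abort_if(!is.numeric(spacing_cM) || spacing_cM <= 0,
           "`spacing_cM` must be > 0")
  abort_if(!is.numeric(chrom_length_cM) || chrom_length_cM < spacing_cM,
           "`chrom_length_cM` must be >= `spacing_cM`")
  pos <- seq(0, chrom_length_cM, by = spacing_cM)
  maps <- lapply(seq_len(n_chrom), function(ch) {
    data.frame(
      marker = sprintf("M%d_%02d", ch, seq_along(pos)),
      chrom = as.character(ch),
      pos = pos,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  class(map) <- c("cvqtl_map", "data.frame")
  validate_map(map)
  map
}

#' Validate a genetic map
#'
#' Checks the map invariants: >= 2 markers per chromosome, strictly
#' increasing positions within each chromosome, non-negative positions and
#' genome-wide unique marker names.
#'
#' @param map a data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos}.
#' @return The map, invisibly, with class \code{cvqtl_map} added.
#' @export
validate_map <- function(map) {
  abort_if(!all(c("marker", "chrom", "pos") %in% names(map)),
           "map needs columns marker, chrom, pos")
  abort_if(anyDuplicated(map$marker) > 0,
           "duplicate marker ids: ",
           paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  abort_if(any(map$pos < 0), "negative cM positions in map")
  abort_if(anyDuplicated(rle(as.character(map$chrom))$values) > 0,
           "map rows must be grouped by chromosome")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    abort_if(length(p) < 2, "chromosome ", ch, " has fewer than 2 markers")
    abort_if(any(diff(p) <= 0),
             "positions not strictly increasing on chromosome ", ch)
  }
  if (!inherits(map, "cvqtl_map")) class(map) <- c("cvqtl_map", "data.frame")
  invisible(map)
}

#' Map-distance to recombination fraction for selfed RILs
#'
#' Converts a cM distance to the recombination fraction observed between
#' homozygous genotypes of selfed recombinant inbred lines:
#' \eqn{r = (1 - e^{-2d/100})/2} (Haldane, no interference), inflated to
#' \eqn{R = 2r/(1 + 2r)} by the accumulation of breakpoints over the selfing
#' generations (Haldane-Waddington).
#'
#' @param d_cM distance in centimorgans (vectorized, >= 0).
#' @return Recombination fraction(s) in [0, 0.5).
#' @export
rf_selfed_ril <- function(d_cM) {
  r <- 0.5 * (1 - exp(-2 * d_cM / 100))
  2 * r / (1 + 2 * r)
}

#' Simulate selfed-RIL genotypes on a genetic map
#'
#' Each line is an independent, fully homozygous mosaic of the two parental
#' genomes. Along a chromosome the genotype follows a two-state Markov chain:
#' the first marker is A or B with probability 1/2 and adjacent markers at
#' distance d cM switch parent with probability \code{rf_selfed_ril(d)}.
#' Chromosomes are independent.
#'
#' @param map a \code{cvqtl_map}.
#' @param n_lines number of RILs (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return Numeric matrix (lines x markers) coded -1 (parent A, e.g. Bay)
#'   and +1 (parent B, e.g. Sha); rownames are line ids, colnames marker ids.
#' @export
simulate_ril_genotypes <- function(map, n_lines, seed = NULL) {
  validate_map(map)
  abort_if(!is.numeric(n_lines) || n_lines < 1, "`n_lines` must be >= 1")
  n_lines <- as.integer(n_lines)
  with_seed(seed, {
    cols <- vector("list", length(unique(map$chrom)))
    names(cols) <- unique(map$chrom)
    for (ch in unique(map$chrom)) {
      sub <- map[map$chrom == ch, ]
      m <- nrow(sub)
      g <- matrix(0, n_lines, m, dimnames = list(NULL, sub$marker))
      g[, 1] <- sample(c(-1, 1), n_lines, replace = TRUE)
      if (m > 1) {
        R <- rf_selfed_ril(diff(sub$pos))
        for (j in 2:m) {
          switch_ <- stats::runif(n_lines) < R[j - 1]
          g[, j] <- g[, j - 1] * ifelse(switch_, -1, 1)
        }
      }
      cols[[ch]] <- g
    }
    geno <- do.call(cbind, cols)
    colnames(geno) <- map$marker   # strip chromosome-list name prefixes
    rownames(geno) <- sprintf("RIL%04d", seq_len(n_lines))
    geno
  })
}

#' Mask genotypes at random (missing-at-random stress utility)
#'
#' @param geno genotype matrix from \code{\link{simulate_ril_genotypes}}.
#' @param rate fraction of entries to set missing, in [0, 1).
#' @param seed optional seed.
#' @return The genotype matrix with \code{NA}s introduced.
#' @export
mask_genotypes <- function(geno, rate, seed = NULL) {
  abort_if(rate < 0 || rate >= 1, "`rate` must be in [0, 1)")
  if (rate == 0) return(geno)
  with_seed(seed, {
    idx <- which(stats::runif(length(geno)) < rate)
    geno[idx] <- NA_real_
    geno
  })
}

#' Declare a simulated trait with planted mean- and CV-QTLs
#'
#' A trait specification holds the baseline mean and baseline CV of a trait
#' plus the loci that perturb them. Effects follow the B-allele (Sha)
#' convention: the genotype score x is -1 for the A and +1 for the B
#' homozygote at the marker nearest the stated position, the per-line mean is
#' \eqn{\mu_0 + \sum a_{mean} x} and the per-line CV is
#' \eqn{c_0 \exp(\sum a_{cv} x)}, so CV effects are additive on log-CV and
#' the CV stays positive for any effect size.
#'
#' @param trait_id character scalar.
#' @param baseline_mean baseline mean, > 0 (arbitrary expression units).
#' @param baseline_cv baseline CV, > 0 (dimensionless).
#' @param mean_qtls,cv_qtls data.frames with columns \code{chrom},
#'   \code{pos}, \code{effect} (or NULL).
#' @param network_id,phase_group optional annotations (phase group an
#'   integer in 0..23).
#' @return A list of class \code{trait_spec}.
#' @export
trait_spec <- function(trait_id, baseline_mean, baseline_cv,
                       mean_qtls = NULL, cv_qtls = NULL,
                       network_id = NULL, phase_group = NULL) {
  abort_if(baseline_mean <= 0, "baseline_mean must be > 0 for trait ", trait_id)
  abort_if(baseline_cv <= 0, "baseline_cv must be > 0 for trait ", trait_id)
  chk <- function(q) {
    if (is.null(q)) return(NULL)
    abort_if(!all(c("chrom", "pos", "effect") %in% names(q)),
             "QTL tables need columns chrom, pos, effect (trait ", trait_id, ")")
    q$chrom <- as.character(q$chrom)
    q
  }
  if (!is.null(phase_group)) {
    abort_if(!phase_group %in% 0:23, "phase_group must be an integer in 0..23")
  }
  structure(
    list(trait_id = as.character(trait_id),
         baseline_mean = baseline_mean, baseline_cv = baseline_cv,
         mean_qtls = chk(mean_qtls), cv_qtls = chk(cv_qtls),
         network_id = network_id, phase_group = phase_group),
    class = "trait_spec"
  )
}

# Index of the marker nearest to (chrom, pos); errors if pos is off-map.
nearest_marker <- function(map, chrom, pos) {
  sub <- which(map$chrom == as.character(chrom))
  abort_if(length(sub) == 0, "no markers on chromosome ", chrom)
  p <- map$pos[sub]
  abort_if(pos < min(p) || pos > max(p),
           "QTL position ", pos, " cM outside map range on chromosome ", chrom)
  sub[which.min(abs(p - pos))]
}

#' Simulate replicated trait measurements over a RIL population
#'
#' Generates the replicated (line x trait x experiment x replicate) trait
#' array that the CV phenotyping works from. For line i and trait j the
#' genotype score x at each planted QTL is the -1/+1 code at the nearest
#' marker; the line's mean and CV follow the \code{\link{trait_spec}} model
#' and every replicate is drawn independently as
#' \eqn{N(\mu_{ij}, (\mu_{ij} c_{ij})^2)}. Replicate noise heavier-tailed
#' than Gaussian is out of scope.
#'
#' @param geno genotype matrix (lines x markers, -1/+1, NA allowed; QTL
#'   markers must be non-missing).
#' @param map the matching \code{cvqtl_map}.
#' @param trait_specs list of \code{\link{trait_spec}} objects.
#' @param n_experiments,n_reps layout: independent experiments and replicates
#'   per experiment (n_reps >= 2 so a CV can be computed per cell). The
#'   default 2 x 2 reproduces a duplicate-in-two-experiments design.
#' @param parental_lines if TRUE, two extra lines \code{Parent_A} (all -1)
#'   and \code{Parent_B} (all +1) are appended.
#' @param experiment_sd standard deviation of an optional additive
#'   experiment-level shift applied to every value of an experiment
#'   (default 0: normalization removes such batch shifts in real pipelines).
#' @param seed optional integer seed.
#' @return An object of class \code{replicated_traits}: a list with
#'   \code{values} (4-d array lines x traits x experiments x replicates) and
#'   layout metadata.
#' @export
simulate_replicated_traits <- function(geno, map, trait_specs,
                                       n_experiments = 2, n_reps = 2,
                                       parental_lines = FALSE,
                                       experiment_sd = 0, seed = NULL) {
  validate_map(map)
  abort_if(n_reps < 2, "`n_reps` must be >= 2 (a CV needs replicates)")
  abort_if(n_experiments < 1, "`n_experiments` must be >= 1")
  if (inherits(trait_specs, "trait_spec")) trait_specs <- list(trait_specs)

  if (parental_lines) {
    pa <- matrix(-1, 1, ncol(geno), dimnames = list("Parent_A", colnames(geno)))
    pb <- matrix(+1, 1, ncol(geno), dimnames = list("Parent_B", colnames(geno)))
    geno <- rbind(geno, pa, pb)
  }
  n_lines <- nrow(geno)
  traits <- vapply(trait_specs, function(s) s$trait_id, character(1))
  abort_if(anyDuplicated(traits) > 0, "duplicate trait ids in trait_specs")

  # per-line mean and CV for every trait
  mu <- matrix(0, n_lines, length(traits))
  cv <- matrix(0, n_lines, length(traits))
  for (j in seq_along(trait_specs)) {
    s <- trait_specs[[j]]
    mu_j <- rep(s$baseline_mean, n_lines)
    log_cv_j <- rep(log(s$baseline_cv), n_lines)
    score <- function(chrom, pos) {
      x <- geno[, nearest_marker(map, chrom, pos)]
      abort_if(anyNA(x), "QTL marker has missing genotypes (trait ",
               s$trait_id, ")")
      x
    }
    if (!is.null(s$mean_qtls)) {
      for (k in seq_len(nrow(s$mean_qtls))) {
        q <- s$mean_qtls[k, ]
        mu_j <- mu_j + q$effect * score(q$chrom, q$pos)
      }
    }
    if (!is.null(s$cv_qtls)) {
      for (k in seq_len(nrow(s$cv_qtls))) {
        q <- s$cv_qtls[k, ]
        log_cv_j <- log_cv_j + q$effect * score(q$chrom, q$pos)
      }
    }
    abort_if(any(mu_j <= 0),
             "planted mean effects drive the mean of trait ", s$trait_id,
             " to <= 0; CV is undefined for non-positive means")
    mu[, j] <- mu_j
    cv[, j] <- exp(log_cv_j)
  }

  dn <- list(
    line = rownames(geno),
    trait = traits,
    experiment = sprintf("E%d", seq_len(n_experiments)),
    replicate = sprintf("R%d", seq_len(n_reps))
  )
  values <- with_seed(seed, {
    v <- array(NA_real_, dim = c(n_lines, length(traits), n_experiments, n_reps),
               dimnames = dn)
    for (e in seq_len(n_experiments)) {
      shift <- if (experiment_sd > 0) stats::rnorm(1, 0, experiment_sd) else 0
      for (r in seq_len(n_reps)) {
        v[, , e, r] <- mu + shift +
          matrix(stats::rnorm(length(mu)), n_lines) * (mu * cv)
      }
    }
    v
  })

  structure(
    list(values = values,
         lines = dn$line, traits = dn$trait,
         n_experiments = n_experiments, n_reps = n_reps,
         true_mean = mu, true_cv = cv),
    class = "replicated_traits"
  )
}

#' Assemble a replicated_traits object from a 4-d array
#'
#' @param values numeric array (lines x traits x experiments x replicates)
#'   with dimnames; NAs mark absent measurements.
#' @return A \code{replicated_traits} object.
#' @export
replicated_traits <- function(values) {
  abort_if(length(dim(values)) != 4,
           "`values` must be a 4-d array (line x trait x experiment x replicate)")
  dn <- dimnames(values)
  abort_if(is.null(dn) || any(vapply(dn[1:2], is.null, logical(1))),
           "`values` needs line and trait dimnames")
  structure(
    list(values = values, lines = dn[[1]], traits = dn[[2]],
         n_experiments = dim(values)[3], n_reps = dim(values)[4],
         true_mean = NULL, true_cv = NULL),
    class = "replicated_traits"
  )
}

#' @export
print.replicated_traits <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "replicated_traits: %d lines x %d traits, %d experiment(s) x %d replicate(s)\n",
    d[1], d[2], d[3], d[4]))
  invisible(x)
}
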