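#' Write / read a genotype matrix as delimited text
#'
#' On disk, genotypes use the biparental homozygous codes \code{A}
#' (parent 1, e.g. Bay), \code{B} (parent 2, e.g. Sha) and \code{NA}
#' (missing); in memory they are -1 / +1 / NA. The first column is the line
#' id, remaining columns are markers.
#'
#' @param geno genotype matrix (lines x markers, -1/+1/NA).
#' @param path file path (tab-delimited).
#' @export
write_genotypes <- function(geno, path) {
  codes <- matrix(c("A", "B")[(geno + 3) / 2], nrow(geno),
                  dimnames = dimnames(geno))
  df <- data.frame(line = rownames(geno), codes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @param path file path of a tab-delimited genotype table (header row,
#'   first column line ids, codes A/B/NA).
#' @return \code{read_genotypes}: the -1/+1/NA genotype matrix.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  abort_if(ncol(df) < 2, "genotype file needs a line column plus markers")
  abort_if(anyDuplicated(df[[1]]) > 0, "duplicate line ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- !(m %in% c("A", "B")) & !is.na(m) & m != "NA"
  if (any(bad)) {
    cell <- which(bad, arr.ind = TRUE)[1, ]
    stop("unknown genotype code \"", m[cell[1], cell[2]], "\" at line ",
         df[[1]][cell[1]], " (file row ", cell[1] + 1, "), marker ",
         colnames(m)[cell[2]], call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(m), ncol(m),
                dimnames = list(df[[1]], colnames(m)))
  out[m == "A"] <- -1
  out[m == "B"] <- 1
  out
}

#' Write / read a genetic map as delimited text
#'
#' Columns: \code{marker}, \code{chrom}, \code{pos} (cM). Reading validates
#' the map invariants and names the offending chromosome when positions are
#' not strictly increasing.
#'
#' @param map a \code{cvqtl_map}.
#' @param path file path (tab-delimited).
#' @export
write_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("marker", "chrom", "pos")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @return \code{read_map}: a validated \code{cvqtl_map}.
#' @export
read_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  abort_if(!all(c("marker", "chrom", "pos") %in% names(df)),
           "map file needs columns marker, chrom, pos")
  df$chrom <- as.character(df$chrom)
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    abort_if(any(diff(p) <= 0),
             "map positions not strictly increasing on chromosome ", ch,
             " in ", path)
  }
  validate_map(df)
  class(df) <- c("cvqtl_map", "data.frame")
  df
}

#' Write / read replicated trait data in long format
#'
#' Long format columns: \code{line}, \code{trait}, \code{experiment},
#' \code{replicate}, \code{value}. Reading reassembles the 4-d array; cells
#' absent from the file become NA.
#'
#' @param traits a \code{\link{replicated_traits}} object.
#' @param path file path (tab-delimited).
#' @export
write_traits <- function(traits, path) {
  stopifnot(inherits(traits, "replicated_traits"))
  v <- traits$values
  dn <- dimnames(v)
  long <- expand.grid(line = dn[[1]], trait = dn[[2]], experiment = dn[[3]],
                      replicate = dn[[4]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$value <- as.vector(v)
  long <- long[!is.na(long$value), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @return \code{read_traits}: a \code{replicated_traits} object.
#' @export
read_traits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(line = "character",
                                         trait = "character",
                                         experiment = "character",
                                         replicate = "character"))
  need <- c("line", "trait", "experiment", "replicate", "value")
  abort_if(!all(need %in% names(df)),
           "trait file needs columns ", paste(need, collapse = ", "))
  dup <- duplicated(df[, c("line", "trait", "experiment", "replicate")])
  abort_if(any(dup), "duplicate (line, trait, experiment, replicate) rows, ",
           "first at file row ", which(dup)[1] + 1)
  dn <- list(line = unique(df$line), trait = unique(df$trait),
             experiment = sort(unique(df$experiment)),
             replicate = sort(unique(df$replicate)))
  v <- array(NA_real_, dim = unname(lengths(dn)), dimnames = dn)
  idx <- cbind(match(df$line, dn$line), match(df$trait, dn$trait),
               match(df$experiment, dn$experiment),
               match(df$replicate, dn$replicate))
  v[idx] <- df$value
  replicated_traits(v)
}

#' Read network or phase-group definitions
#'
#' Two-column tab-delimited file: \code{member_id}, \code{group_id}. Returns
#' a named list (group id -> member trait ids) suitable for
#' \code{\link{network_values}}; for phase groups, group ids should be the
#' integers 0..23.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_networks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  abort_if(!all(c("member_id", "group_id") %in% names(df)),
           "network file needs columns member_id, group_id")
  split(df$member_id, df$group_id)
}

#' Write a QTL-call table
#'
#' @param calls a \code{qtl_calls} data.frame (pooled over traits is fine).
#' @param path file path (tab-delimited).
#' @export
write_qtl_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_qtl_calls
#' @return \code{read_qtl_calls}: the calls data.frame (class
#'   \code{qtl_calls}). Externally produced QTL lists in the same schema
#'   (trait_id, chrom, pos, effect, ...) can be read with this and fed to the
#'   hotspot functions directly.
#' @export
read_qtl_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  abort_if(!all(c("chrom", "pos") %in% names(df)),
           "QTL list needs at least columns chrom, pos")
  df$chrom <- as.character(df$chrom)
  class(df) <- c("qtl_calls", "data.frame")
  df
}

#' Assemble, write and read a pipeline configuration
#'
#' The configuration is a plain nested list, serialized as YAML. It is the
#' single source of every randomized stage's seed: stage sub-seeds are
#' derived deterministically from \code{seed}. \code{write_config} /
#' \code{read_config} round-trip losslessly.
#'
#' @param simulate list of simulation parameters (n_lines, n_chrom,
#'   chrom_length_cM, spacing_cM, n_traits, baseline_mean, baseline_cv,
#'   n_experiments, n_reps, cv_qtls, mean_qtls), or NULL to read data from
#'   \code{paths}.
#' @param paths list of input file paths (genotypes, map, traits) when not
#'   simulating.
#' @param scan list: step_cM, window_cM, max_cofactors.
#' @param permutation list: n_traits, n_perm, alpha.
#' @param hotspot list: window_cM, n_perm.
#' @param normalize quantile-normalize the trait matrix before CV (default
#'   FALSE for simulated data).
#' @param seed master integer seed.
#' @param out_dir output directory for \code{\link{run_pipeline}}.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            scan = list(), permutation = list(),
                            hotspot = list(), normalize = FALSE,
                            seed = 1L, out_dir = tempfile("cvqtl_run_")) {
  abort_if(is.null(simulate) && is.null(paths),
           "either `simulate` parameters or input `paths` are required")
  cfg <- list(
    simulate = simulate, paths = paths,
    scan = utils::modifyList(
      list(step_cM = 1, window_cM = 10, max_cofactors = 5), scan),
    permutation = utils::modifyList(
      list(n_traits = 100, n_perm = 1000, alpha = 0.05), permutation),
    hotspot = utils::modifyList(
      list(window_cM = 2.5, n_perm = 1000), hotspot),
    normalize = normalize,
    seed = as.integer(seed), out_dir = out_dir
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}
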