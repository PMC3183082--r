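#' Quantile-normalize a replicated trait array across samples
#'
#' Flattens the (line x trait x experiment x replicate) array into a
#' traits x samples matrix (every line/experiment/replicate combination is a
#' sample, the analogue of one array), applies
#' \code{\link{quantile_normalize}}, and restores the array layout.
#'
#' @param traits a \code{\link{replicated_traits}} object (no missing
#'   values).
#' @return A \code{replicated_traits} object on the normalized scale.
#' @export
normalize_replicated_traits <- function(traits) {
  stopifnot(inherits(traits, "replicated_traits"))
  v <- traits$values
  d <- dim(v)
  flat <- aperm(v, c(2, 1, 3, 4))           # trait, line, exp, rep
  mat <- matrix(flat, nrow = d[2])          # traits x samples
  norm <- quantile_normalize(mat)
  out <- array(norm, dim = d[c(2, 1, 3, 4)])
  out <- aperm(out, c(2, 1, 3, 4))
  dimnames(out) <- dimnames(v)
  replicated_traits(out)
}

# Build trait specs from a pipeline config's simulate block: planted QTLs
# carry a `frac` field (fraction of traits affected); affected traits are
# sampled reproducibly from the stage sub-seed.
sim_trait_specs <- function(sim, seed) {
  n_traits <- sim$n_traits
  mk_assign <- function(qtls, tag) {
    if (is.null(qtls)) return(NULL)
    qtls <- as.data.frame(do.call(rbind, lapply(qtls, as.data.frame)))
    with_seed(derive_seed(seed, tag), {
      lapply(seq_len(nrow(qtls)), function(k) {
        n_aff <- max(1, round((qtls$frac[k] %||% 1) * n_traits))
        list(chrom = as.character(qtls$chrom[k]), pos = qtls$pos[k],
             effect = qtls$effect[k],
             traits = sample.int(n_traits, min(n_aff, n_traits)))
      })
    })
  }
  cv_q <- mk_assign(sim$cv_qtls, "assign_cv")
  mean_q <- mk_assign(sim$mean_qtls, "assign_mean")
  lapply(seq_len(n_traits), function(j) {
    pick <- function(qs) {
      if (is.null(qs)) return(NULL)
      rows <- Filter(function(q) j %in% q$traits, qs)
      if (length(rows) == 0) return(NULL)
      do.call(rbind, lapply(rows, function(q) {
        data.frame(chrom = q$chrom, pos = q$pos, effect = q$effect,
                   stringsAsFactors = FALSE)
      }))
    }
    trait_spec(sprintf("T%04d", j),
               baseline_mean = sim$baseline_mean %||% 100,
               baseline_cv = sim$baseline_cv %||% 0.1,
               mean_qtls = pick(mean_q), cv_qtls = pick(cv_q))
  })
}

#' Run the full CV-QTL pipeline
#'
#' Executes the stages in order: simulate (or read) genotypes, map and
#' replicated traits; optional quantile normalization; CV phenotypes;
#' per-trait heritability; genome-wide permutation threshold; per-trait CIM
#' scans and QTL calls; hotspot profile and hotspot permutation threshold.
#' Every output table is written to \code{config$out_dir} with a header
#' comment carrying the seed and a hash of the configuration; a run log
#' records stage timings and counts. A stage failure aborts with the stage
#' name; outputs of completed stages are left on disk.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, a list with all in-memory results (map, geno, traits,
#'   cvp, heritability, grid, threshold, calls, hotspots, global_cv,
#'   out_dir).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL   # the hash identifies the analysis, not where it lands
  hash <- config_hash(cfg_for_hash)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- character(0)
  t_all <- proc.time()[3]

  stamp_write <- function(df, name) {
    path <- file.path(config$out_dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# cvqtl run: seed=%d config_hash=%s", seed, hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s", name,
                                      conditionMessage(e))), log_path)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines,
                    sprintf("%-22s %8.2fs", name, proc.time()[3] - t0))
    out
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    map <- stage("simulate_map", simulate_genetic_map(
      sim$n_chrom %||% 5, sim$chrom_length_cM %||% 90,
      sim$spacing_cM %||% 5))
    geno <- stage("simulate_genotypes", simulate_ril_genotypes(
      map, sim$n_lines, seed = derive_seed(seed, "geno")))
    specs <- sim_trait_specs(sim, seed)
    traits <- stage("simulate_traits", simulate_replicated_traits(
      geno, map, specs,
      n_experiments = sim$n_experiments %||% 2, n_reps = sim$n_reps %||% 2,
      seed = derive_seed(seed, "traits")))
    write_genotypes(geno, file.path(config$out_dir, "genotypes.tsv"))
    write_map(map, file.path(config$out_dir, "map.tsv"))
    write_traits(traits, file.path(config$out_dir, "traits.tsv"))
    write_config(config, file.path(config$out_dir, "config.yaml"))
  } else {
    map <- stage("read_map", read_map(config$paths$map))
    geno <- stage("read_genotypes", read_genotypes(config$paths$genotypes))
    traits <- stage("read_traits", read_traits(config$paths$traits))
  }

  if (isTRUE(config$normalize)) {
    traits <- stage("quantile_normalize", normalize_replicated_traits(traits))
  }

  cvp <- stage("cv_phenotypes", cv_phenotypes(traits))
  stamp_write(data.frame(line = rownames(cvp$cv_mean), cvp$cv_mean,
                         check.names = FALSE), "cv_matrix.tsv")

  herit <- stage("heritability", cv_heritability(cvp))
  stamp_write(herit, "heritability.tsv")

  gcv <- stage("global_cv", global_cv(cvp))
  stamp_write(data.frame(line = names(gcv), global_cv = gcv), "global_cv.tsv")

  # scan lines = lines with genotypes (parental rows, if present, drop out
  # of the mapping automatically)
  grid <- stage("scan_grid", build_scan_grid(geno, map,
                                             config$scan$step_cM %||% 1))
  cvm <- cvp$cv_mean[match(grid$lines, rownames(cvp$cv_mean)), , drop = FALSE]

  thr <- stage("permutation_threshold", permutation_threshold(
    cvm, grid,
    n_traits = min(config$permutation$n_traits %||% 100, ncol(cvm)),
    n_perm = config$permutation$n_perm %||% 1000,
    alpha = config$permutation$alpha %||% 0.05,
    max_cofactors = config$scan$max_cofactors %||% 5,
    window_cM = config$scan$window_cM %||% 10,
    seed = derive_seed(seed, "perm")))

  calls <- stage("scan_and_call", {
    out <- lapply(colnames(cvm), function(tr) {
      y <- cvm[, tr]
      cof <- select_cofactors(y, grid, config$scan$max_cofactors %||% 5)
      sc <- cim_scan(y, grid, cof, config$scan$window_cM %||% 10,
                     trait_id = tr)
      call_qtl(sc, thr)
    })
    do.call(rbind, out)
  })
  stamp_write(calls, "qtl_calls.tsv")

  hot <- stage("hotspots", {
    counts <- count_qtl_per_position(calls, grid$positions)
    profile <- sliding_window_profile(counts, grid$positions,
                                      config$hotspot$window_cM %||% 2.5)
    ht <- if (nrow(calls) > 0) {
      hotspot_threshold(nrow(calls), nrow(grid$positions),
                        n_perm = config$hotspot$n_perm %||% 1000,
                        alpha = config$permutation$alpha %||% 0.05,
                        seed = derive_seed(seed, "hotspot"))
    } else NULL
    list(counts = counts, profile = profile, threshold = ht)
  })
  stamp_write(data.frame(grid$positions, count = hot$counts,
                         window_mean = hot$profile,
                         hotspot_threshold =
                           if (is.null(hot$threshold)) NA
                           else hot$threshold$threshold),
              "hotspot_profile.tsv")

  log_lines <- c(log_lines,
                 sprintf("traits: %d, lines: %d, calls: %d",
                         ncol(cvm), nrow(cvm), nrow(calls)),
                 sprintf("total %.2fs", proc.time()[3] - t_all))
  writeLines(log_lines, log_path)

  invisible(list(map = map, geno = geno, traits = traits, cvp = cvp,
                 heritability = herit, global_cv = gcv, grid = grid,
                 threshold = thr, calls = calls, hotspots = hot,
                 out_dir = config$out_dir))
}
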