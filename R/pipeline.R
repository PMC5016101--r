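## End-to-end orchestration: simulate/load -> register -> detect ->
## {intensity, morphology, colocalization, compartmentalization}, with
## deterministic outputs (identical config + seed => byte-identical CSVs).
## One cell = one input image; per-cell statistics aggregate within an
## image and histograms pool across cells by count addition.

#' Assemble a pipeline run configuration
#'
#' @param scene a [scene_spec()] or list of them (one per cell), or `NULL`
#'   when reading TIFF inputs.
#' @param inputs character vector of TIFF paths written by [write_stack()]
#'   (used when `scene` is `NULL`).
#' @param channels named list mapping roles to channel indices; `matrix` is
#'   required, `protein_a`/`protein_b` optional but must be distinct.
#' @param params stage parameters; defaults are the analysis constants
#'   (smoothing sigma 2.0, noise tolerance 10, region diameter 19 px,
#'   random radius 180 px, drift window 18 px, patch sigma 1.0, 50%
#'   maxima retention, 25 intensity bins, 40 colocalization bins).
#' @param drift_px integer `(dr, dc)` drift simulated on the STED channels
#'   (and on a second reference acquisition) before registration; the
#'   pipeline then estimates and corrects it. `c(0, 0)` disables.
#' @param out_dir output directory for CSV/JSON artifacts.
#' @param seed integer seed for the pipeline's random stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(scene = NULL, inputs = NULL,
                       channels = list(matrix = 1, protein_a = 2, protein_b = 3),
                       params = list(), drift_px = c(0L, 0L),
                       out_dir = "peroxiquant_out", seed = 1) {
  defaults <- list(sigma = 2.0, noise_tolerance = 10, diameter_px = 19L,
                   random_radius_px = 180L, drift_window_px = 18L,
                   patch_sigma = 1.0, retain_frac = 0.5,
                   intensity_bins = 25L, coloc_bins = 40L)
  params <- utils::modifyList(defaults, params)
  if (inherits(scene, "scene_spec")) scene <- list(scene)
  structure(list(scene = scene, inputs = inputs, channels = channels,
                 params = params, drift_px = as.integer(drift_px),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ch <- config$channels
  if (is.null(ch$matrix)) stop("config invalid: no matrix channel assigned")
  idx <- unlist(ch)
  if (anyDuplicated(idx)) stop("config invalid: channel roles must be distinct")
  if (is.null(config$scene) && is.null(config$inputs))
    stop("config invalid: provide a scene spec or input paths")
  if (any(abs(config$drift_px) > config$params$drift_window_px))
    stop("config invalid: simulated drift exceeds the search window")
  invisible(config)
}

#' Serialize / restore a run configuration (YAML)
#' @param config a [run_config()].
#' @param path YAML path.
#' @return `path` (write) or the restored `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config_canonical(config), path)
  invisible(path)
}

## Canonical plain-list form (also what gets hashed): YAML-representable,
## so types that YAML cannot distinguish collapse consistently.
config_canonical <- function(config) {
  raw <- unclass(config)
  raw$scene <- lapply(raw$scene, function(s) {
    s <- unclass(s)
    s$morphology_mix <- as.list(s$morphology_mix)
    s
  })
  raw
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  scene <- if (!is.null(raw$scene)) {
    lapply(raw$scene, function(s) {
      s$morphology_mix <- unlist(s$morphology_mix)
      do.call(scene_spec, s)
    })
  }
  run_config(scene = scene, inputs = raw$inputs,
             channels = raw$channels, params = raw$params,
             drift_px = raw$drift_px, out_dir = raw$out_dir, seed = raw$seed)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  raw <- config_canonical(config)
  raw$out_dir <- NULL # the hash identifies the analysis, not its destination
  writeLines(yaml::as.yaml(raw), tf)
  unname(tools::md5sum(tf))
}

write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config %s", hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a pipeline CSV (skipping the config-hash header)
#' @param path CSV written by [run_pipeline()].
#' @return data.frame.
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: acquire -> register -> detect -> intensity,
#' morphology, colocalization, compartmentalization. Downstream stages
#' consume the corrected stack only. Reruns with an identical config are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly; artifacts under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  p <- config$params
  roles <- config$channels
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)

  ## --- acquire ----------------------------------------------------------
  stacks <- if (!is.null(config$scene)) {
    lapply(config$scene, function(s) generate_scene(s)$stack)
  } else {
    lapply(config$inputs, read_stack)
  }
  n_cells <- length(stacks)

  ## --- register ---------------------------------------------------------
  drift_est <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    stk <- stacks[[ci]]
    if (any(config$drift_px != 0)) {
      sted <- which(stk$meta$modality == "sted")
      for (ch in sted)
        stk <- apply_known_shift(stk, config$drift_px, ch)
      ref_b <- translate_zero(stk$channels[[roles$matrix]], config$drift_px)
      est <- estimate_drift(stk$channels[[roles$matrix]], ref_b,
                            window = p$drift_window_px)
      stk <- apply_correction(stk, correction_transform(
        drift_shift_px = est, search_window_px = p$drift_window_px),
        drift_channels = sted, chromatic_channels = integer(0))
      drift_est[[ci]] <- est
    } else {
      drift_est[[ci]] <- c(dr = 0L, dc = 0L)
    }
    stacks[[ci]] <- stk
  }

  ## --- detect -----------------------------------------------------------
  all_regions <- list(); all_random <- list()
  n_dropped <- 0L; n_failed <- 0L; n_maxima <- 0L
  for (ci in seq_len(n_cells)) {
    mat <- stacks[[ci]]$channels[[roles$matrix]]
    mx <- find_maxima(mat, sigma = p$sigma, noise_tolerance = p$noise_tolerance)
    n_maxima <- n_maxima + nrow(mx)
    regs <- make_regions(mx, dim(stacks[[ci]]), diameter_px = p$diameter_px)
    n_dropped <- n_dropped + attr(regs, "n_dropped")
    excl <- exclusion_mask(mat, sigma = p$sigma,
                           noise_tolerance = p$noise_tolerance)
    rnd <- make_random_regions(regs, excl, dim(stacks[[ci]]),
                               radius_px = p$random_radius_px,
                               seed = config$seed + ci)
    n_failed <- n_failed + attr(rnd, "n_failed")
    if (nrow(regs)) regs$cell <- ci
    if (nrow(rnd)) rnd$cell <- ci
    all_regions[[ci]] <- regs
    all_random[[ci]] <- rnd
  }
  bind <- function(lst, proto) {
    lst <- Filter(function(x) nrow(x) > 0, lst)
    if (length(lst)) do.call(rbind, lst) else proto
  }
  regions <- bind(all_regions, cbind(all_regions[[1]], cell = integer(0)))
  random <- bind(all_random, cbind(all_random[[1]], cell = integer(0)))
  write_csv_hashed(rbind(regions[setdiff(names(regions), "source_id")],
                         random[setdiff(names(random), "source_id")]),
                   out("regions.csv"), hash)

  ## --- intensity --------------------------------------------------------
  proteins <- intersect(c("protein_a", "protein_b"), names(roles))
  proteins <- proteins[!vapply(roles[proteins], is.null, logical(1))]
  pairs_rows <- list(); corr_rows <- list()
  hist_perox <- list(); hist_rand <- list()
  for (ci in seq_len(n_cells)) {
    regs <- all_regions[[ci]]; rnd <- all_random[[ci]]
    if (nrow(regs) == 0) next
    for (pr in proteins) {
      ip <- integrate_regions(stacks[[ci]], regs, roles$matrix, roles[[pr]])
      ir <- integrate_regions(stacks[[ci]], rnd, roles$matrix, roles[[pr]])
      ip$cell <- ci; ip$protein <- pr
      ir$cell <- ci; ir$protein <- pr
      pairs_rows[[length(pairs_rows) + 1]] <- rbind(ip, ir)
      if (nrow(ip) >= 2 && stats::var(ip$g) > 0 && stats::var(ip$r) > 0) {
        cc <- cell_correlation(ip, cell_id = ci)
        cc$protein <- pr
        corr_rows[[length(corr_rows) + 1]] <- cc
      }
      if (pr == proteins[1]) {
        ref <- max(ip$g)
        if (ref > 0) {
          hist_perox[[length(hist_perox) + 1]] <-
            normalized_histogram(ip$g, ref, "peroxisomal")
          if (nrow(ir) > 0)
            hist_rand[[length(hist_rand) + 1]] <-
              normalized_histogram(ir$g, ref, "random")
        }
      }
    }
  }
  pairs <- if (length(pairs_rows)) do.call(rbind, pairs_rows) else
    data.frame(id = integer(0), kind = character(0), g = numeric(0),
               r = numeric(0), cell = integer(0), protein = character(0))
  write_csv_hashed(pairs, out("intensity_pairs.csv"), hash)
  corr <- if (length(corr_rows)) do.call(rbind, corr_rows) else
    data.frame(cell = integer(0), pearson_r = numeric(0),
               n_regions = integer(0), protein = character(0))
  write_csv_hashed(corr, out("cell_correlations.csv"), hash)
  hist_df <- function(hs, kind) {
    if (!length(hs)) return(NULL)
    h <- pool_histograms(hs)
    data.frame(kind = kind, bin_lo = h$breaks[-26], bin_hi = h$breaks[-1],
               count = h$counts)
  }
  write_csv_hashed(rbind(hist_df(hist_perox, "peroxisomal"),
                         hist_df(hist_rand, "random")),
                   out("intensity_histograms.csv"), hash)

  ## --- morphology -------------------------------------------------------
  morph_rows <- list()
  for (ci in seq_len(n_cells)) {
    both <- rbind(all_regions[[ci]][names(all_regions[[ci]]) != "source_id"],
                  all_random[[ci]][names(all_random[[ci]]) != "source_id"])
    for (pr in proteins) {
      chan <- stacks[[ci]]$channels[[roles[[pr]]]]
      for (i in seq_len(nrow(both))) {
        m <- measure_region_morphology(
          extract_patch(chan, both[i, ]),
          pixel_size_nm = stacks[[ci]]$pixel_size_nm,
          region_id = both$id[i])
        if (nrow(m)) {
          m$cell <- ci; m$kind <- both$kind[i]; m$protein <- pr
          morph_rows[[length(morph_rows) + 1]] <- m
        }
      }
    }
  }
  morph <- if (length(morph_rows)) do.call(rbind, morph_rows) else
    data.frame(region_id = integer(0), cluster = integer(0),
               area_px = integer(0), perimeter_px = integer(0),
               area_nm2 = numeric(0), perimeter_nm = numeric(0),
               cell = integer(0), kind = character(0), protein = character(0))
  write_csv_hashed(morph, out("morphology.csv"), hash)

  ## --- colocalization & compartmentalization ---------------------------
  n_coloc_real <- 0L; n_coloc_flagged <- 0L; n_compart <- 0L
  n_compart_invalid <- 0L
  if (length(proteins) == 2) {
    ctabs <- list(); chists <- list(); crecs <- list()
    for (ci in seq_len(n_cells)) {
      if (nrow(all_regions[[ci]]) == 0) next
      ch <- coloc_histograms(stacks[[ci]], all_regions[[ci]],
                             roles$protein_a, roles$protein_b,
                             all_random[[ci]], n_bins = p$coloc_bins)
      tab <- ch$table; tab$cell <- ci
      ctabs[[length(ctabs) + 1]] <- tab
      chists[[length(chists) + 1]] <- ch$histograms
      cp <- compartmentalization_table(stacks[[ci]], all_regions[[ci]],
                                       roles$protein_a, roles$protein_b,
                                       sigma = p$patch_sigma,
                                       retain_frac = p$retain_frac)
      if (nrow(cp$records)) {
        cp$records$cell <- ci
        crecs[[length(crecs) + 1]] <- cp$records
      }
      n_compart_invalid <- n_compart_invalid + cp$n_invalid
    }
    ctab <- if (length(ctabs)) do.call(rbind, ctabs) else
      data.frame(id = integer(0), variant = character(0),
                 pearson = numeric(0), cell = integer(0))
    write_csv_hashed(ctab, out("coloc.csv"), hash)
    pooled <- if (length(chists)) {
      agg <- chists[[1]]
      for (h in chists[-1]) agg$count <- agg$count + h$count
      agg
    } else data.frame(variant = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), count = integer(0))
    write_csv_hashed(pooled, out("coloc_histograms.csv"), hash)
    crec <- if (length(crecs)) do.call(rbind, crecs) else
      data.frame(id = integer(0), distance_px = numeric(0),
                 distance_nm = numeric(0), pearson = numeric(0),
                 n_maxima_ch1 = integer(0), n_maxima_ch2 = integer(0),
                 cell = integer(0))
    write_csv_hashed(crec, out("compartments.csv"), hash)
    n_coloc_real <- sum(ctab$variant == "real" & !is.na(ctab$pearson))
    n_coloc_flagged <- sum(ctab$variant == "real" & is.na(ctab$pearson))
    n_compart <- nrow(crec)
  }

  ## --- report -----------------------------------------------------------
  manifest <- sort(list.files(config$out_dir, pattern = "\\.csv$"))
  report <- list(
    package_version = as.character(utils::packageVersion("peroxiquant")),
    config_hash = hash,
    seed = config$seed,
    n_cells = n_cells,
    drift_applied = as.integer(config$drift_px),
    drift_estimated = lapply(drift_est, as.integer),
    n_maxima = n_maxima,
    n_regions = nrow(regions),
    n_dropped_border = n_dropped,
    n_random = nrow(random),
    n_random_failed = n_failed,
    n_intensity_pairs = nrow(pairs),
    n_coloc_real = n_coloc_real,
    n_coloc_flagged = n_coloc_flagged,
    n_compartment_records = n_compart,
    n_compartment_invalid = n_compart_invalid,
    manifest = manifest
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_run_config(config, out("config_echo.yaml"))
  invisible(report)
}
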