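# Config-driven stage runner: deterministic outputs for a fixed seed plus
# a manifest (inputs, parameters, seed, package version, output checksums)
# written alongside the artifacts.

stage_registry <- function() {
  list(
    "make-fixtures" = function(params, seed, out_dir) {
      model <- do.call(quantal_model, params$model %||% list(
        n_sites = 11, q = 3.9, p_by_condition = c(high_pr = 0.8,
                                                  low_pr = 0.45)))
      n <- params$n_trials %||% 33
      d <- bind_rows(lapply(names(model$p_by_condition), function(cc)
        simulate_quantal(model, cc, n, seed = derive_seed(seed,
                                                          match(cc, names(model$p_by_condition))))))
      f <- file.path(out_dir, "amplitudes.csv")
      utils::write.csv(d, f, row.names = FALSE)
      f
    },
    "grow-axons" = function(params, seed, out_dir) {
      gp <- do.call(growth_params, params$growth %||% list())
      n <- params$n_cells %||% 3
      files <- character()
      for (i in seq_len(n)) {
        m <- grow_axon(gp, seed = derive_seed(seed, i))
        m <- place_boutons(m, params$spacing_mean %||% 3.36,
                           params$spacing_sd %||% 2.54,
                           seed = derive_seed(seed, 1000 + i))
        f1 <- file.path(out_dir, sprintf("cell_%03d.swc", i))
        f2 <- file.path(out_dir, sprintf("cell_%03d_boutons.csv", i))
        write_swc(m, f1); write_boutons_csv(m, f2, cell_id = i)
        files <- c(files, f1, f2)
      }
      files
    },
    "population-coverage" = function(params, seed, out_dir) {
      dims <- unlist(params$dims %||% c(80, 80, 60))
      som <- sample_somata(dims = dims, n = params$n_cells %||% 8,
                           seed = derive_seed(seed, 1))
      gp <- do.call(growth_params, params$growth %||%
                      list(total_length_mean = 1500, total_length_sd = 300,
                           n_branch_mean = 12, n_branch_sd = 3))
      lay <- population_layout(som, gp, seed = derive_seed(seed, 2),
                               dims = dims)
      cov <- build_coverage(lay, radius = params$radius %||% 1.5)
      mult <- source_multiplicity(cov, params$active_fraction %||% 1,
                                  seed = derive_seed(seed, 3))
      f1 <- file.path(out_dir, "coverage.csv")
      f2 <- file.path(out_dir, "multiplicity.json")
      utils::write.csv(as.data.frame(cov), f1, row.names = FALSE)
      jsonlite::write_json(mult, f2, digits = NA)
      c(f1, f2)
    },
    "bqa" = function(params, seed, out_dir) {
      if (is.null(params$input))
        abort("bqa stage requires `input` (amplitude CSV).",
              class = "ngf_error_io")
      if (!file.exists(params$input))
        abort(paste0("input file not found: ", params$input),
              class = "ngf_error_io")
      d <- utils::read.csv(params$input)
      fit <- bqa_fit(d, seed = seed)
      f <- file.path(out_dir, "posterior.json")
      jsonlite::write_json(list(
        nfrs_median = fit$nfrs_median, q_median = fit$q_median,
        p_by_condition = as.list(fit$p_by_condition)),
        f, auto_unbox = TRUE, digits = NA)
      f
    },
    "ecs-validate" = function(params, seed, out_dir) {
      lat <- do.call(ecs_lattice, params$lattice %||% list())
      out <- list(volume_fraction = lat$volume_fraction,
                  domain_volume = lat$domain_volume)
      if (isTRUE(params$tortuosity)) {
        tt <- estimate_tortuosity(lat,
                                  n_walkers = params$n_walkers %||% 2000,
                                  n_steps = params$n_steps %||% 100000,
                                  seed = seed)
        out$lambda <- tt$lambda
      }
      f <- file.path(out_dir, "ecs.json")
      jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
      f
    }
  )
}

#' Run a pipeline stage from a configuration
#'
#' Executes one named analysis stage with an explicit seed and writes its
#' artifacts plus a `manifest.json` (stage, parameters, seed, package
#' version, MD5 checksums of every output) into `out_dir`.  Unknown
#' top-level keys or an unknown stage name fail validation.
#'
#' @param config list with elements `stage`, `seed`, `out_dir` and
#'   optionally `params` (stage-specific), or the path of a YAML file
#'   holding the same.
#' @return Invisibly, the manifest as a list.
#' @export
run_stage <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- c("stage", "seed", "out_dir", "params")
  extra <- setdiff(names(config), allowed)
  if (length(extra))
    abort(paste0("unknown configuration key(s): ",
                 paste(extra, collapse = ", ")),
          class = "ngf_error_validation")
  for (key in c("stage", "seed", "out_dir")) {
    if (is.null(config[[key]]))
      abort(paste0("missing configuration key: ", key),
            class = "ngf_error_validation")
  }
  reg <- stage_registry()
  if (!config$stage %in% names(reg))
    abort(paste0("unknown stage '", config$stage, "'; available: ",
                 paste(names(reg), collapse = ", ")),
          class = "ngf_error_validation")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- reg[[config$stage]](config$params %||% list(),
                               as.integer(config$seed), config$out_dir)
  manifest <- list(
    stage = config$stage, seed = as.integer(config$seed),
    params = config$params %||% list(),
    package_version = as.character(utils::packageVersion("ngfsum")),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
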