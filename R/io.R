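#' Read and validate a configuration file
#'
#' Flat key/value configuration in JSON or YAML. Required keys: `N`,
#' `Lambda`, `sigma2`, `twoNU`, `seed`. Optional keys with defaults:
#' `effect_family` (`"point"` or `"exponential"`, default `"point"`),
#' `effect_params` (family parameters; `Se` for point, `mean_Se` for
#' exponential — always population-scaled, i.e. dimensionless), `Se_min`
#' (20), `Se_max` (2000), `generations` (engine default), `replicates`
#' (100), `thin` (1), `output_dir` (`"."`), `engine` (`"hybrid"`), `VS`,
#' `internal_units` (`TRUE`), and for the `scan` subcommand `axis1_name`,
#' `axis1_values`, `axis2_name`, `axis2_values`, `bandwidth`, `statistic`.
#'
#' When `internal_units` is `FALSE`, `VS` is required and `Lambda` /
#' `sigma2` are interpreted in raw trait units and converted to internal
#' \eqn{\delta} units via [trait_scale()]; effect parameters are always in
#' `Se` units. Unknown keys are rejected; `Lambda > sqrt(VS)` draws a
#' warning but the run proceeds.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with `scenario` (a validated [scenario()]), `options`
#'   (seed, generations, replicates, thin, output_dir, engine, scan
#'   settings), and `config` (the raw key/value list with defaults filled
#'   in).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else stop("config must be .json, .yaml or .yml", call. = FALSE)
  known <- c("N", "VS", "internal_units", "Lambda", "sigma2", "twoNU",
             "effect_family", "effect_params", "Se_min", "Se_max", "seed",
             "generations", "replicates", "thin", "output_dir", "engine",
             "axis1_name", "axis1_values", "axis2_name", "axis2_values",
             "bandwidth", "statistic")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  need <- c("N", "Lambda", "sigma2", "twoNU", "seed")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing required config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  defaults <- list(effect_family = "point", effect_params = list(Se = 100),
                   Se_min = 20, Se_max = 2000, generations = NULL,
                   replicates = 100, thin = 1, output_dir = ".",
                   engine = "hybrid", internal_units = TRUE,
                   bandwidth = 0, statistic = "p_fix")
  cfg <- utils::modifyList(defaults, raw)
  num_keys <- c("N", "Lambda", "sigma2", "twoNU", "Se_min", "Se_max",
                "seed", "replicates", "thin")
  for (k in num_keys)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || !is.finite(cfg[[k]]))
      stop("config key `", k, "` must be a single finite number",
           call. = FALSE)
  for (k in c("sigma2", "twoNU"))
    if (cfg[[k]] < 0) stop("config key `", k, "` must be >= 0", call. = FALSE)
  if (cfg$Lambda < 0) stop("config key `Lambda` must be >= 0", call. = FALSE)
  if (!cfg$engine %in% c("hybrid", "polygenic"))
    stop("config key `engine` must be \"hybrid\" or \"polygenic\"",
         call. = FALSE)
  Lambda <- cfg$Lambda
  sigma2 <- cfg$sigma2
  if (!isTRUE(cfg$internal_units)) {
    if (is.null(cfg$VS))
      stop("config key `VS` is required when internal_units is false",
           call. = FALSE)
    sc_raw <- trait_scale(cfg$N, cfg$VS)
    Lambda <- to_internal(Lambda, sc_raw, power = 1)
    sigma2 <- to_internal(sigma2, sc_raw, power = 2)
  }
  ed <- switch(cfg$effect_family,
    point = effect_dist_point(cfg$effect_params$Se,
                              large_cutoff = min(20, cfg$Se_min)),
    exponential = effect_dist_exponential(cfg$effect_params$mean_Se,
                                          Se_min = cfg$Se_min,
                                          Se_max = cfg$Se_max,
                                          large_cutoff = min(20, cfg$Se_min)),
    stop("config key `effect_family` must be \"point\" or \"exponential\"",
         call. = FALSE))
  sc <- scenario(N = cfg$N, Lambda = Lambda, sigma2 = sigma2,
                 twoNU = cfg$twoNU, effect_dist = ed)
  list(scenario = sc,
       options = cfg[c("seed", "generations", "replicates", "thin",
                       "output_dir", "engine", "axis1_name", "axis1_values",
                       "axis2_name", "axis2_values", "bandwidth",
                       "statistic")],
       config = cfg)
}

# single tabular dialect: tab-separated, header row, '.' decimal, no quoting
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_standing <- function(arch, path) {
  write_tsv(as.data.frame(arch), path)
}

#' Serialize simulation outputs as TSV
#'
#' `write_trajectory` writes a [run_hybrid()] trajectory as `series.tsv`
#' (per-generation `t`, `D`, `VA_large`, `sigma2`, `n_segregating`) and
#' `alleles.tsv` (terminal allele table with fates) in `dir`;
#' `write_standing` writes a standing architecture as a single TSV. Both use
#' tab separation, a header row, '.' decimals and no quoting, so outputs
#' diff bit-exactly across reproduced runs.
#'
#' @param tr A `"shift_trajectory"`.
#' @param arch A `standing_architecture`.
#' @param dir,path Output directory / file path.
#' @return The written path(s), invisibly.
#' @export
write_trajectory <- function(tr, dir) {
  stopifnot(inherits(tr, "shift_trajectory"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- write_tsv(tr$series, file.path(dir, "series.tsv"))
  p2 <- write_tsv(tr$alleles, file.path(dir, "alleles.tsv"))
  invisible(c(p1, p2))
}

#' Run manifest for byte-reproducible outputs
#'
#' Records the configuration snapshot, master seed, package version,
#' timestamp and (once results exist) an inventory of output files with MD5
#' checksums. Re-running the same manifest reproduces byte-identical TSVs.
#'
#' @param dir Output directory; the manifest is written as
#'   `manifest.json` inside it.
#' @param config Raw configuration list (as in `load_config()$config`).
#' @param seed Master seed of the run.
#' @param files Character vector of result files to checksum (may be empty
#'   when writing the pre-run manifest).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(dir, config, seed, files = character()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inv <- if (length(files))
    data.frame(file = basename(files),
               md5 = unname(tools::md5sum(files)))
  else data.frame(file = character(0), md5 = character(0))
  man <- list(package = "optimshift",
              version = as.character(utils::packageVersion("optimshift")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config, files = inv)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}
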