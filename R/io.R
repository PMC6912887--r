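# File formats: encounter histories and m-arrays as CSV, configuration as
# YAML/JSON, run manifests as JSON. Occasions are 1-based everywhere
# (occasion 1 = first release occasion; interval t spans occasions t..t+1).

#' Read and write encounter histories as CSV
#'
#' One row per individual: `id`, `release_occasion`, `age_at_release`
#' (`juvenile`/`adult`; `sy` is accepted on input for second-year releases of
#' real datasets), then `y1..yT` columns of 0/1 detections.
#'
#' @param histories An `encounter_histories` object.
#' @param path File path.
#' @return `read_histories()` returns an `encounter_histories`.
#' @export
write_histories <- function(histories, path) {
  y <- histories$y
  df <- data.frame(id = seq_len(nrow(y)),
                   release_occasion = histories$release,
                   age_at_release = histories$age)
  colnames(y) <- paste0("y", seq_len(ncol(y)))
  write.csv(cbind(df, y), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histories
#' @export
read_histories <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ycols <- grep("^y[0-9]+$", names(df), value = TRUE)
  ycols <- ycols[order(as.integer(sub("^y", "", ycols)))]
  if (length(ycols) < 2L) stop("no detection columns y1..yT found", call. = FALSE)
  y <- as.matrix(df[, ycols])
  dimnames(y) <- NULL
  structure(list(y = y, release = as.integer(df$release_occasion),
                 age = df$age_at_release, T = length(ycols)),
            class = "encounter_histories")
}

#' Write the generating annual rates alongside a simulated dataset
#'
#' @param rates An `annual_rates` object.
#' @param path File path.
#' @export
write_rates <- function(rates, path) {
  write.csv(data.frame(interval = seq_along(rates$phi_ad),
                       phi_ad = rates$phi_ad, phi_juv = rates$phi_juv,
                       eta_ad = rates$eta_ad, eta_juv = rates$eta_juv,
                       rho = rates$rho),
            path, row.names = FALSE)
  invisible(path)
}

#' Read and write m-array sets as CSV
#'
#' Two files, `<prefix>_juv.csv` and `<prefix>_ad.csv`, with occasion columns
#' `occ2..occT` and a `never` column.
#'
#' @param marrays An [build_marrays()] result.
#' @param prefix Path prefix for the two files.
#' @export
write_marrays <- function(marrays, prefix) {
  write.csv(as.data.frame(marrays$juv), paste0(prefix, "_juv.csv"))
  write.csv(as.data.frame(marrays$ad), paste0(prefix, "_ad.csv"))
  invisible(prefix)
}

#' @rdname write_marrays
#' @export
read_marrays <- function(prefix) {
  juv <- as.matrix(read.csv(paste0(prefix, "_juv.csv"), row.names = 1))
  ad <- as.matrix(read.csv(paste0(prefix, "_ad.csv"), row.names = 1))
  structure(list(juv = juv, ad = ad, T = ncol(juv)), class = "marray_set")
}

config_defaults <- function() {
  list(
    simulation = list(T = 10L, releases_per_occasion = 100L, mu_ad = 1,
                      mu_juv = -1, sigma2_ad = 0.1, sigma2_juv = 0.1,
                      rho = "random", juvenile_fraction = 0.5, p = 0.5),
    prior = list(parameterization = "separated", df = 3,
                 sigma_lower = 0, sigma_upper = 5,
                 rho_lower = -1, rho_upper = 1, sigma_dist = "uniform",
                 sigma_hn_var = 10),
    mcmc = list(n_chains = 2L, n_iter = 25000L, n_burn = 15000L, thin = 5L,
                parameterization = "centered"),
    study = list(occasions = c(10L, 20L, 30L),
                 releases = c(100L, 1000L, 5000L), V = 100L))
}

#' Parse a YAML or JSON configuration file
#'
#' Reads a configuration with sections `simulation`, `prior`, `mcmc` and
#' `study`, fills unspecified entries with the package defaults (the standard
#' simulation design and MCMC protocol), and rejects unknown sections or keys
#' with their key paths. An empty file yields the full defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Nested named list with all defaults filled in.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  }
  if (is.null(raw)) raw <- list()
  defs <- config_defaults()
  bad <- setdiff(names(raw), names(defs))
  if (length(bad)) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(raw)) {
    badkey <- setdiff(names(raw[[sec]]), names(defs[[sec]]))
    if (length(badkey)) {
      stop("unknown config key(s): ",
           paste(paste0(sec, ".", badkey), collapse = ", "), call. = FALSE)
    }
    defs[[sec]] <- utils::modifyList(defs[[sec]], raw[[sec]])
  }
  validate_config(defs)
  defs
}

validate_config <- function(cfg) {
  s <- cfg$simulation
  if (!identical(s$rho, "random")) {
    if (!is.numeric(s$rho) || abs(s$rho) > 1) {
      stop("config error at simulation.rho: must be \"random\" or in [-1, 1]",
           call. = FALSE)
    }
  }
  if (s$T < 2) stop("config error at simulation.T: need >= 2", call. = FALSE)
  if (s$p <= 0 || s$p >= 1) {
    stop("config error at simulation.p: must be in (0, 1)", call. = FALSE)
  }
  if (!cfg$prior$parameterization %in% c("separated", "iw")) {
    stop("config error at prior.parameterization: must be 'separated' or 'iw'",
         call. = FALSE)
  }
  if (cfg$mcmc$n_burn >= cfg$mcmc$n_iter) {
    stop("config error at mcmc.n_burn: must be < mcmc.n_iter", call. = FALSE)
  }
  invisible(cfg)
}

#' Serialize a configuration back to file
#'
#' @param config A configuration list (as returned by [parse_config()]).
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Generate small bundled example datasets
#'
#' Writes two deterministic fixtures: a T = 5, 50-releases-per-occasion
#' dataset, and a T = 3 micro dataset small enough that its m-array can be
#' verified by hand enumeration. Histories, m-arrays, generating rates and a
#' run manifest are all written under `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (default 1).
#' @return Invisibly, the named list of written paths.
#' @export
generate_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  small_cfg <- sim_config(T = 5, releases_per_occasion = 50, rho = 0.5)
  small <- simulate_cmr(small_cfg, seed = seed)
  paths$small_histories <- file.path(dir, "small_histories.csv")
  write_histories(small$histories, paths$small_histories)
  paths$small_rates <- file.path(dir, "small_rates.csv")
  write_rates(small$rates, paths$small_rates)
  write_marrays(build_marrays(small$histories), file.path(dir, "small_marray"))
  paths$small_marray <- file.path(dir, "small_marray")
  micro_cfg <- sim_config(T = 3, releases_per_occasion = 4, rho = 0)
  micro <- simulate_cmr(micro_cfg, seed = seed + 1)
  paths$micro_histories <- file.path(dir, "micro_histories.csv")
  write_histories(micro$histories, paths$micro_histories)
  paths$micro_rates <- file.path(dir, "micro_rates.csv")
  write_rates(micro$rates, paths$micro_rates)
  write_marrays(build_marrays(micro$histories), file.path(dir, "micro_marray"))
  paths$micro_marray <- file.path(dir, "micro_marray")
  paths$manifest <- file.path(dir, "manifest.json")
  write_manifest(paths$manifest, seeds = c(small = seed, micro = seed + 1),
                 config = list(small = unclass(small_cfg),
                               micro = unclass(micro_cfg)),
                 outputs = unlist(paths[names(paths) != "manifest"]))
  invisible(paths)
}

#' Ingest real encounter histories with a second-year age class
#'
#' Reads a CSV in the [write_histories()] dialect whose
#' `age_at_release` column may contain `juv`/`juvenile`, `sy`/`second-year`,
#' or `ad`/`adult`. Second-year releases share the adult survival class but
#' keep their own detection class, matching the age/time detection variant of
#' [cjs_corr()]: a bird released as a juvenile is in the second-year
#' detection class at its first post-release occasion and in the adult class
#' thereafter.
#'
#' @param path CSV path.
#' @return An `encounter_histories` with `age` collapsed to
#'   `juvenile`/`adult` for survival and an extra element
#'   `detection_age` holding the original three-class codes.
#' @export
brent_ingest <- function(path) {
  h <- read_histories(path)
  if (nrow(h$y) == 0L) stop("empty encounter-history file: ", path, call. = FALSE)
  code <- tolower(h$age)
  map <- c(juv = "juv", juvenile = "juv", sy = "sy", "second-year" = "sy",
           ad = "ad", adult = "ad")
  if (any(!code %in% names(map))) {
    stop("unknown age code(s): ",
         paste(unique(code[!code %in% names(map)]), collapse = ", "),
         call. = FALSE)
  }
  cls <- unname(map[code])
  # survival classes: sy and ad collapse; only true juveniles get the
  # juvenile first-interval survival (and second-year detection next year)
  h$age <- ifelse(cls == "juv", "juvenile", "adult")
  h$detection_age <- cls
  h
}

#' Write a run manifest
#'
#' Records what produced a set of artifact files: package version, seeds, a
#' content hash of the configuration, timestamps and output paths, so any
#' output file is traceable to exactly one run.
#'
#' @param path Output JSON path.
#' @param seeds Named vector/list of seeds used.
#' @param config Configuration list.
#' @param outputs Character vector of produced files.
#' @export
write_manifest <- function(path, seeds, config, outputs) {
  man <- list(package = "cjscorr",
              version = as.character(utils::packageVersion("cjscorr")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seeds = as.list(seeds),
              config_hash = config_hash(config),
              config = config,
              outputs = as.character(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# FNV-1a over the serialized configuration; stable across sessions.
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
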