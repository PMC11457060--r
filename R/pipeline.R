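#' Read a plot-level phenotype table
#'
#' Reads the comma-separated phenotype file (UTF-8, "." decimal, `#` comment
#' header lines allowed), maps the design-factor columns to the canonical
#' names `location`, `rep`, `block`, `line`, `tester`, coerces the remaining
#' columns to numeric traits, and validates that each
#' (location, rep, block, line, tester) key occurs once.
#'
#' @param path CSV path.
#' @param mapping named list translating canonical factor names to the
#'   file's column names; defaults to identity. `block` and `tester` may be
#'   omitted from the file.
#' @param na_strings tokens read as missing.
#' @return Data frame of validated plot records; factors as character,
#'   traits numeric.
#' @export
read_phenotypes <- function(path, mapping = NULL,
                            na_strings = c("NA", "")) {
  defaults <- list(location = "location", rep = "rep", block = "block",
                   line = "line", tester = "tester", entry = "entry")
  mapping <- utils::modifyList(defaults, as.list(mapping %||% list()))
  df <- read.csv(path, na.strings = na_strings, comment.char = "#",
                 check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("location", "rep", "line")
  miss <- vapply(required, function(k) !(mapping[[k]] %in% names(df)), TRUE)
  if (any(miss))
    stop("phenotype file lacks required column(s): ",
         paste(unlist(mapping[required][miss]), collapse = ", "),
         " (expected design factors location/rep/line, optionally ",
         "block/tester; adjust `mapping` if the file names them differently)")
  present <- names(mapping)[vapply(mapping, function(v) v %in% names(df), TRUE)]
  for (k in present) {
    names(df)[names(df) == mapping[[k]]] <- k
    df[[k]] <- as.character(df[[k]])
  }
  id_cols <- intersect(c("location", "rep", "block", "line", "tester", "entry"),
                       names(df))
  key_cols <- setdiff(id_cols, "entry")
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate plot key at row(s): ",
         paste(head(which(duplicated(key)), 5), collapse = ", "))
  trait_cols <- setdiff(names(df), id_cols)
  for (tc in trait_cols) {
    raw <- df[[tc]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad))
      stop("non-numeric value in trait column '", tc, "' at row(s): ",
           paste(head(bad, 5), collapse = ", "))
    df[[tc]] <- num
  }
  df
}

#' Read a dominant marker matrix
#'
#' First column = line ID, remaining columns = 0/1 calls (missing tokens
#' surfaced as `NA`). Duplicated line IDs and non-binary cells are hard
#' errors with coordinates.
#'
#' @param path CSV path.
#' @param na_strings tokens read as missing.
#' @return Integer matrix with line IDs as row names.
#' @export
read_markers <- function(path, na_strings = c("NA", "")) {
  df <- read.csv(path, na.strings = na_strings, comment.char = "#",
                 check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("marker file needs a line-ID column plus markers")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated line ID(s): ",
         paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  M <- as.matrix(df[-1])
  suppressWarnings(storage.mode(M) <- "numeric")
  bad <- which(!is.na(M) & M != 0 & M != 1, arr.ind = TRUE)
  nonnum <- which(is.na(M) & !is.na(as.matrix(df[-1])), arr.ind = TRUE)
  bad <- rbind(bad, nonnum)
  if (nrow(bad))
    stop("non-binary marker call at line '", ids[bad[1, 1]], "', marker '",
         colnames(M)[bad[1, 2]], "'",
         if (nrow(bad) > 1) paste0(" (and ", nrow(bad) - 1, " more)"))
  storage.mode(M) <- "integer"
  rownames(M) <- ids
  M
}

#' Write a table with a provenance comment header
#'
#' Writes `# strigaGS <version> seed=<seed> config=<hash>` followed by the
#' CSV body, the format [read_phenotypes()] and [read_markers()] accept.
#'
#' @param x data frame or matrix (matrices get their row names as a first
#'   `line` column).
#' @param path output path.
#' @param seed,config_hash provenance fields recorded in the header.
#' @return `path`, invisibly.
#' @export
write_csv_stamped <- function(x, path, seed = NA, config_hash = "") {
  header <- sprintf("# strigaGS %s seed=%s config=%s",
                    as.character(utils::packageVersion("strigaGS")),
                    as.character(seed), config_hash)
  if (is.matrix(x)) {
    x <- data.frame(line = rownames(x), as.data.frame(x, row.names = NULL),
                    check.names = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(x, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Gathers every setting of [run_pipeline()]. Either point `phenotype_file`
#' and `marker_file` at deposited-style CSVs, or leave them `NULL` to run on
#' a synthetic dataset generated from `sim`.
#'
#' @param output_dir directory for all outputs (created if needed).
#' @param phenotype_file,marker_file input CSVs, or `NULL` to simulate.
#' @param sim a [sim_config()] used when simulating.
#' @param traits trait columns to analyse (after derivation); intersected
#'   with what the data provides.
#' @param maf_threshold marker QC threshold.
#' @param wap weeks-after-planting schedule for AUSNPC.
#' @param plot_area plot area (m^2) for the yield conversion.
#' @param iterations,burn_in,thin reaction-norm sampler schedule.
#' @param cv_schemes subset of CV0/CV1/CV2 to run (`character(0)` to skip).
#' @param n_folds,test_fraction cross-validation controls.
#' @param run_gebv fit the full-data reaction norm and write GEBVs?
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it (per-trait streams are keyed by trait name so dropping a trait
#'   leaves the others unchanged).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            phenotype_file = NULL, marker_file = NULL,
                            sim = sim_config(),
                            traits = c("str8wap", "str10wap", "str12wap",
                                       "sdr1", "sdr2", "sdr", "ausnpc", "gy"),
                            maf_threshold = 0.05, wap = c(8, 10, 12),
                            plot_area = 3,
                            iterations = 30000, burn_in = 15000, thin = 10,
                            cv_schemes = c("CV0", "CV1", "CV2"),
                            n_folds = 50, test_fraction = 0.2,
                            run_gebv = TRUE, seed = 1L) {
  if (missing(output_dir)) stop("output_dir is required")
  if (xor(is.null(phenotype_file), is.null(marker_file)))
    stop("provide both phenotype_file and marker_file, or neither")
  structure(list(output_dir = output_dir, phenotype_file = phenotype_file,
                 marker_file = marker_file, sim = sim, traits = traits,
                 maf_threshold = maf_threshold, wap = wap,
                 plot_area = plot_area, iterations = iterations,
                 burn_in = burn_in, thin = thin, cv_schemes = cv_schemes,
                 n_folds = n_folds, test_fraction = test_fraction,
                 run_gebv = run_gebv, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full genomic-selection analysis
#'
#' Orchestrates the stages in dependency order: data (simulate or read),
#' trait derivation, marker QC and relationship matrix, per-environment
#' BLUEs and across-site variance components/heritability, the full-data
#' reaction-norm fit with GEBVs for all lines, and cross-validation. Each
#' stage is logged (name, wall time, seed) to `log.json`; every CSV output
#' carries a provenance header. Identical config + seed reproduces every
#' output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`varcomps`,
#'   `blues`, `blups`, `correlations`, `gebv`, `accuracy`, `log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- .config_hash(config)
  stamp <- function(x, name) write_csv_stamped(
    x, file.path(config$output_dir, name), seed = config$seed, config_hash = cfg_hash)
  log <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[length(log) + 1L]] <<- list(stage = stage,
                                     seconds = round(proc.time()[["elapsed"]] - t0, 3),
                                     seed = config$seed)
    res
  }

  dat <- tick("data", {
    if (is.null(config$phenotype_file)) {
      sim <- config$sim
      sim$seed <- config$seed
      simulate_striga_dataset(sim, plot_area = config$plot_area)
    } else {
      list(phenotypes = read_phenotypes(config$phenotype_file),
           markers = read_markers(config$marker_file))
    }
  })
  phen <- tick("traits", derive_traits(dat$phenotypes, wap = config$wap,
                                       plot_area = config$plot_area))
  stamp(phen, "phenotypes_derived.csv")

  grm <- tick("grm", {
    m <- qc_markers(dat$markers, config$maf_threshold)
    compute_grm(impute_markers(m))
  })
  stamp(round(grm, 6), "grm.csv")

  traits <- intersect(config$traits, names(phen))
  if (!length(traits)) stop("none of the requested traits are present")

  across <- tick("mixed_models", lapply(setNames(traits, traits), function(tr)
    fit_across_sites(phen, tr)))
  varcomps <- do.call(rbind, lapply(traits, function(tr) {
    vc <- across[[tr]]$varcomps
    data.frame(trait = tr, sigma2_G = vc$sigma2_G, sigma2_GE = vc$sigma2_GE,
               sigma2_error = vc$sigma2_error,
               heritability = across[[tr]]$heritability,
               lsd05 = across[[tr]]$lsd05, stringsAsFactors = FALSE)
  }))
  stamp(varcomps, "varcomps.csv")

  blups <- do.call(cbind, lapply(across, function(ts) ts$blups))
  stamp(data.frame(line = rownames(blups), blups, check.names = FALSE),
        "blups.csv")
  if (length(traits) >= 2 && nrow(blups) >= 3)
    stamp(as.data.frame(round(trait_correlations(blups), 4)),
          "correlations.csv")

  blues <- tick("blues", lapply(setNames(traits, traits), function(tr)
    blues_by_environment(phen, tr)))
  blues_long <- do.call(rbind, lapply(traits, function(tr)
    cbind(trait = tr, blues[[tr]])))
  stamp(blues_long, "blues.csv")

  gebv <- NULL
  if (config$run_gebv) {
    gebv <- tick("reaction_norm", {
      tabs <- lapply(setNames(traits, traits), function(tr) {
        design <- build_design(blues[[tr]], grm)
        fit <- fit_gibbs(design, iterations = config$iterations,
                         burn_in = config$burn_in, thin = config$thin,
                         seed = .trait_seed(config$seed, tr))
        predict_gebv(fit, design)
      })
      base <- tabs[[1]][c("line", "set")]
      for (tr in traits) base[[tr]] <- tabs[[tr]]$gebv
      base
    })
    stamp(gebv, "gebv.csv")
  }

  accuracy <- NULL
  if (length(config$cv_schemes)) {
    accuracy <- tick("cross_validation", {
      rows <- list()
      for (tr in traits) {
        for (sch in config$cv_schemes) {
          cv <- run_cv(blues[[tr]], grm, sch, n_folds = config$n_folds,
                       test_fraction = config$test_fraction,
                       seed = .trait_seed(config$seed, paste0(tr, sch)),
                       iterations = config$iterations,
                       burn_in = config$burn_in, thin = config$thin)
          rows[[length(rows) + 1L]] <- data.frame(
            trait = tr, scheme = sch,
            env = c(names(cv$per_environment), "across"),
            r = c(unname(cv$per_environment), cv$across),
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
    stamp(accuracy, "accuracy.csv")
  }

  jsonlite::write_json(list(package = "strigaGS",
                            version = as.character(utils::packageVersion("strigaGS")),
                            seed = config$seed, config_hash = cfg_hash,
                            stages = log),
                       file.path(config$output_dir, "log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(varcomps = varcomps, blues = blues_long, blups = blups,
                 gebv = gebv, accuracy = accuracy, log = log))
}

# Cheap deterministic config fingerprint (provenance only, not cryptographic).
.config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "output_dir")]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% .Machine$integer.max)
}

# Per-trait RNG stream keyed by name, so removing one trait from the config
# leaves every other trait's stochastic outputs unchanged.
.trait_seed <- function(seed, key) {
  as.integer((seed + sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))) %% 2147483647L)
}
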