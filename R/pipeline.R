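# Keys a pipeline config may contain; anything else is rejected.
.config_keys <- c(
  "design", "design_file", "attributes", "n_respondents", "strata",
  "utilities", "seed", "reference", "subgroups", "output_dir",
  "responses_file", "continuity_correction", "digits"
)

#' Load and validate a pipeline configuration
#'
#' A configuration is a YAML (or JSON) file, or an equivalent named list,
#' with keys:
#' \describe{
#'   \item{design}{list `v`, `k`, `lambda` for [construct_bibd()], or}
#'   \item{design_file}{path to a design CSV ([read_design()]).}
#'   \item{attributes}{optional list with `codes` and `labels`; default
#'     [nurse_sow_attributes()].}
#'   \item{n_respondents}{cohort size for simulation (ignored when
#'     `responses_file` is given).}
#'   \item{strata}{per-variable category proportions; default
#'     [study_strata()].}
#'   \item{utilities}{named utility map for simulation; default
#'     [default_utilities()].}
#'   \item{responses_file}{optional survey CSV to analyse instead of
#'     simulating.}
#'   \item{seed}{integer master seed.}
#'   \item{reference}{reference attribute code or `"auto"`.}
#'   \item{subgroups}{demographic variables for [subgroup_fit()].}
#'   \item{output_dir}{where [run_pipeline()] writes its files.}
#'   \item{continuity_correction, digits}{counting/report options.}
#' }
#' Unknown keys are an error (no silent typo tolerance).
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return Validated config list of class `bws_config`.
#' @export
read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    bws_validation_error("config must be a file path or a named list")
  }
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown)) {
    bws_validation_error("unknown config keys",
                         paste(unknown, collapse = ", "))
  }
  defaults <- list(
    design = list(v = 7L, k = 3L, lambda = 1L),
    attributes = NULL, n_respondents = 51L, strata = NULL,
    utilities = NULL, seed = 1L, reference = "auto",
    subgroups = demographic_columns(), output_dir = "bws_output",
    responses_file = NULL, design_file = NULL,
    continuity_correction = FALSE, digits = 2L
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    bws_validation_error("config seed must be a single integer")
  }
  structure(config, class = c("bws_config", "list"))
}

config_attributes <- function(config) {
  if (is.null(config$attributes)) return(nurse_sow_attributes())
  attribute_set(config$attributes$codes,
                config$attributes$labels %||% config$attributes$codes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_strata <- function(config) {
  if (is.null(config$strata)) return(study_strata())
  lapply(config$strata, unlist)
}

config_utilities <- function(config) {
  if (is.null(config$utilities)) return(default_utilities())
  u <- config$utilities
  if (!is.null(u$by)) {
    u$profiles <- lapply(u$profiles, unlist)
    return(u)
  }
  unlist(u)
}

# md5 of the canonical JSON serialisation of an R object
object_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full best-worst scaling pipeline
#'
#' Stages: construct/load the design, simulate choices (or ingest a
#' response CSV), run the counting analysis, fit the pooled maxdiff
#' conditional logit, fit the subgroup models, and write all outputs to
#' `output_dir`:
#' `design.csv`, `survey.csv`, `counting.csv`, `score_distribution.csv`
#' (long: attribute, score level, frequency), `clm.csv`,
#' `subgroups.csv`, and `run_log.json` (seed, config/design hashes,
#' package version). With a fixed config and seed the statistical outputs
#' are byte-identical across runs.
#'
#' Any stage failure aborts with the stage name and cause.
#'
#' @param config A config path or list, see [read_config()].
#' @return Invisibly, a list with the in-memory results (`design`,
#'   `dataset`, `counting`, `scoredist`, `fit`, `subgroups`, `paths`).
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  attrs <- stage("design", config_attributes(config))
  bound <- stage("design", {
    if (!is.null(config$design_file)) {
      read_design(config$design_file, attrs)
    } else {
      d <- config$design
      bind_attributes(construct_bibd(d$v, d$k, d$lambda), attrs)
    }
  })

  dataset <- stage("data", {
    if (!is.null(config$responses_file)) {
      read_responses(config$responses_file, bound)
    } else {
      roster <- simulate_respondents(config$n_respondents,
                                     strata = config_strata(config),
                                     seed = config$seed)
      simulate_choices(roster, bound, config_utilities(config),
                       seed = config$seed)
    }
  })

  counting <- stage("count", bws_count(
    dataset, continuity = isTRUE(config$continuity_correction)))
  tl <- bws_tally(dataset)
  sdist <- stage("count", score_distribution(tl))

  reference <- config$reference
  if (identical(reference, "auto")) reference <- choose_reference(dataset)
  fit <- stage("fit", bws_clm(dataset, reference = reference))

  subgroups <- stage("subgroups", {
    vars <- intersect(unlist(config$subgroups), names(dataset$roster))
    out <- lapply(vars, function(v) subgroup_fit(dataset, v,
                                                 reference = reference))
    names(out) <- vars
    out
  })

  paths <- list(
    design = file.path(outdir, "design.csv"),
    survey = file.path(outdir, "survey.csv"),
    counting = file.path(outdir, "counting.csv"),
    scoredist = file.path(outdir, "score_distribution.csv"),
    clm = file.path(outdir, "clm.csv"),
    subgroups = file.path(outdir, "subgroups.csv"),
    log = file.path(outdir, "run_log.json")
  )
  stage("report", {
    write_design(bound, paths$design)
    write_responses(dataset, paths$survey)
    utils::write.csv(as.data.frame(counting), paths$counting,
                     row.names = FALSE, quote = FALSE)
    hist <- sdist$histogram
    long <- data.frame(
      attribute = rep(rownames(hist), times = ncol(hist)),
      score = rep(as.integer(colnames(hist)), each = nrow(hist)),
      frequency = as.integer(hist),
      stringsAsFactors = FALSE
    )
    utils::write.csv(long, paths$scoredist, row.names = FALSE, quote = FALSE)
    clm_tab <- data.frame(
      attribute = names(fit$beta),
      estimate = as.numeric(fit$beta),
      robust_se = as.numeric(fit$robust_se),
      classical_se = as.numeric(fit$classical_se),
      p_value = as.numeric(fit$p_value),
      stars = as.character(fit$stars),
      stringsAsFactors = FALSE
    )
    utils::write.csv(clm_tab, paths$clm, row.names = FALSE, quote = FALSE)
    sub_tab <- do.call(rbind, lapply(subgroups, function(s) s$table))
    if (is.null(sub_tab)) sub_tab <- data.frame()
    utils::write.csv(sub_tab, paths$subgroups, row.names = FALSE,
                     quote = FALSE)
    log <- list(
      package = "bwstools",
      version = as.character(utils::packageVersion("bwstools")),
      timestamp = format(Sys.time(), tz = "UTC"),
      seed = config$seed,
      config_hash = object_hash(unclass(config)),
      design_hash = object_hash(bound$tasks),
      reference = reference,
      n_respondents = nrow(dataset$roster),
      n_obs = nrow(dataset$responses),
      ll_model = fit$ll_model,
      pseudo_r2 = fit$pseudo_r2
    )
    jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })

  invisible(list(design = bound, dataset = dataset, counting = counting,
                 scoredist = sdist, fit = fit, subgroups = subgroups,
                 paths = paths, config = config))
}
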