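pipeline_keys <- c("input", "integration", "dose", "tumor_label",
                   "survival", "seed", "out_dir", "radionuclide")

#' Validate a pipeline configuration
#'
#' Schema check for [run_pipeline()] configurations: unknown top-level keys
#' are rejected, the dose method must be `"local"` or `"svalue"`, and the
#' input stage must name either a biodistribution file or a simulation.
#' Validation runs before any computation so a malformed config fails fast.
#'
#' @param config Named list or YAML file path.
#' @return The validated config list, with defaults filled in.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config$integration <- utils::modifyList(
    list(tail = "terminal_exp", t0 = "rise", k = 2L),
    config$integration %||% list()
  )
  if (!config$integration$tail %in% c("terminal_exp", "physical", "none")) {
    stop("unknown tail model: ", config$integration$tail, call. = FALSE)
  }
  config$dose <- utils::modifyList(
    list(method = "local", absorbed_fraction = 1),
    config$dose %||% list()
  )
  if (!config$dose$method %in% c("local", "svalue")) {
    stop("unknown dose method: ", config$dose$method, call. = FALSE)
  }
  if (config$dose$method == "svalue" &&
      (is.null(config$dose$svalue_path) || is.null(config$dose$masses_path))) {
    stop("dose method 'svalue' needs `svalue_path` and `masses_path`.",
         call. = FALSE)
  }
  config$tumor_label <- config$tumor_label %||% "tumor"
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$input) ||
      (is.null(config$input$biodist) && is.null(config$input$simulate))) {
    stop("config `input` must provide `biodist` (a file) or `simulate`.",
         call. = FALSE)
  }
  config
}

#' Run the end-to-end dosimetry pipeline
#'
#' One call from input (a biodistribution file, or a seeded simulation) to
#' cumulated activity, organ doses, therapeutic indices and, optionally,
#' survival summaries. The bundle is deterministic given the config seed,
#' and each table carries its method provenance. With `out_dir` set, the
#' tables are written as CSV plus a plain-text summary.
#'
#' @param config Named list or YAML path; see
#'   [validate_pipeline_config()] for the schema. Stages:
#'   * `input`: either `biodist` (+ `metadata`) or `simulate` with `arm`
#'     (`"conventional"`/`"pretargeting"`), optional `params` overrides,
#'     `times_h`, `n_per_time`, `cv`.
#'   * `integration`: `tail`, `t0`, `k`.
#'   * `dose`: `method` (`"local"` or `"svalue"`), `absorbed_fraction`, or
#'     `svalue_path` + `masses_path`.
#'   * `tumor_label`, `survival` (CSV path), `seed`, `out_dir`.
#' @return Invisibly, a list with elements `study`, `aucs`, `doses`, `ti`
#'   and (if survival input given) `km` and `logrank`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)

  study <- if (!is.null(config$input$biodist)) {
    read_biodist(config$input$biodist,
                 metadata = config$input$metadata %||% list())
  } else {
    sim <- config$input$simulate
    p <- do.call(pretarget_params, sim$params %||% list())
    nm <- noise_model(cv = sim$cv %||% 0.15, seed = config$seed)
    args <- list(params = p,
                 times_h = sim$times_h %||% c(1, 4, 24, 48, 72),
                 n_per_time = sim$n_per_time %||% 3, noise = nm)
    if (identical(sim$arm %||% "conventional", "pretargeting")) {
      do.call(simulate_pretargeting, args)
    } else {
      do.call(simulate_conventional, args)
    }
  }

  aucs <- auc_table(study,
                    tail = config$integration$tail,
                    t0 = config$integration$t0,
                    k = config$integration$k)
  doses <- if (config$dose$method == "local") {
    local_deposition_dose(aucs, attr(study, "radionuclide"),
                          absorbed_fraction = config$dose$absorbed_fraction)
  } else {
    tab <- read_svalue_table(config$dose$svalue_path,
                             config$dose$masses_path)
    bind_rows(lapply(split(aucs, aucs$cohort), svalue_dose, table = tab))
  }

  tumor <- normalize_organ(config$tumor_label)
  ti <- bind_rows(lapply(split(doses, doses$cohort), function(d) {
    if (tumor %in% d$organ && any(d$mad_cGy_per_MBq[d$organ == tumor] > 0)) {
      therapeutic_index(d, tumor_label = tumor, arm = d$cohort[1])
    } else NULL
  }))

  bundle <- list(study = study, aucs = aucs, doses = doses, ti = ti)

  if (!is.null(config$survival)) {
    recs <- read_survival(config$survival)
    bundle$km <- km_by_group(recs)
    grp <- unique(recs$group)
    if (length(grp) >= 2) {
      pairs <- utils::combn(grp, 2)
      bundle$logrank <- bind_rows(lapply(seq_len(ncol(pairs)), function(i) {
        logrank(recs, groups = pairs[, i])
      }))
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(as_tibble(as.data.frame(bundle$aucs)),
                     file.path(config$out_dir, "cumulated_activity.csv"))
    readr::write_csv(as_tibble(as.data.frame(bundle$doses)),
                     file.path(config$out_dir, "doses.csv"))
    if (nrow(bundle$ti) > 0) {
      readr::write_csv(as_tibble(as.data.frame(bundle$ti)),
                       file.path(config$out_dir, "therapeutic_index.csv"))
    }
    if (!is.null(bundle$km)) {
      readr::write_csv(select(bundle$km, -"fit"),
                       file.path(config$out_dir, "survival_medians.csv"))
      readr::write_csv(bundle$logrank,
                       file.path(config$out_dir, "logrank.csv"))
    }
    writeLines(pipeline_summary(bundle, config),
               file.path(config$out_dir, "summary.txt"))
  }
  invisible(bundle)
}

pipeline_summary <- function(bundle, config) {
  c(
    "clickdosim pipeline summary",
    sprintf("measurements: %d | cohorts: %s", nrow(bundle$study),
            paste(unique(bundle$study$cohort_id), collapse = ", ")),
    sprintf("integration: %s | dose method: %s | seed: %d",
            bundle$aucs$method[1], config$dose$method, config$seed),
    "",
    utils::capture.output(print(as.data.frame(bundle$doses), digits = 4))
  )
}

#' Write the packaged worked-example fixtures
#'
#' Writes small plain-text fixtures used by the worked examples and the
#' acceptance script: (a) the published organ MAD tables of the two
#' dosimetry arms (`table1_mads.csv`) and the PDX re-study
#' (`table2_mads.csv`); (b) the published cumulated-activity pairs with SDs
#' (`cumulated_pairs.csv`); (c) a seeded synthetic one-step cohort
#' (`synthetic_onestep.csv` + metadata YAML) and a synthetic two-group
#' survival table (`synthetic_survival.csv`). Regeneration is
#' deterministic, hence byte-identical.
#'
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  t1 <- tibble(
    arm = rep(c("pretargeting_8h", "conventional"), each = 3),
    organ = rep(c("blood", "kidney", "tumor"), 2),
    mad_cGy_per_MBq = c(0.55, 15.64, 37.54, 0.54, 134.02, 60.03)
  )
  p <- file.path(out_dir, "table1_mads.csv")
  readr::write_csv(t1, p); paths <- c(paths, p)

  t2 <- tibble(
    arm = "conventional_pdx",
    organ = c("blood", "kidney", "tumor"),
    mad_cGy_per_MBq = c(0.21, 141.44, 1.98)
  )
  p <- file.path(out_dir, "table2_mads.csv")
  readr::write_csv(t2, p); paths <- c(paths, p)

  pairs <- tibble(
    comparison = c("kidney_healthy", "kidney_u87mg", "tumor_u87mg"),
    organ = c("kidney", "kidney", "tumor"),
    pretarget_value = c(11.2, 197, 404),
    pretarget_sd = c(0.7, 31, 41),
    conventional_value = c(260.4, 1615, 662),
    conventional_sd = c(11.8, 185, 60)
  )
  p <- file.path(out_dir, "cumulated_pairs.csv")
  readr::write_csv(pairs, p); paths <- c(paths, p)

  st <- simulate_conventional(noise = noise_model(cv = 0.15, seed = 20260101L))
  p <- file.path(out_dir, "synthetic_onestep.csv")
  write_biodist(st, p); paths <- c(paths, p)
  p <- file.path(out_dir, "synthetic_onestep_meta.yaml")
  write_biodist_metadata(st, p); paths <- c(paths, p)

  set.seed(20260102L)
  surv <- tibble(
    group = rep(c("control", "treated"), each = 10),
    time_d = round(c(stats::rexp(10, 1 / 70), stats::rexp(10, 1 / 85)) + 30, 1),
    event = rep(1, 20)
  )
  surv$event[c(5, 18)] <- 0
  p <- file.path(out_dir, "synthetic_survival.csv")
  readr::write_csv(surv, p); paths <- c(paths, p)

  invisible(paths)
}
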