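#' Configuration schema for scripted simulation runs
#'
#' Runs are described by a hierarchical YAML document with blocks `segment`
#' (`"A"`, `"B"` or `"C"`), `n_reps`, `seed`, `designs`, `scenario`,
#' `enrollment`, and optional `output` (`csv`, `manifest` paths) and `sweep`
#' (`sizes`: grid of first-trial sample sizes). Every field is validated
#' before any simulation starts and unknown keys are rejected, so a config
#' (or the manifest written after a run, which materializes all defaults)
#' fully determines a run.
#'
#' @name run_config
#' @examples
#' cfg <- yaml::yaml.load("
#' segment: A
#' n_reps: 100
#' seed: 7
#' designs:
#'   phase2: {n2: 60, orr0: 0.4, orr1_alt: 0.6, alpha: 0.05}
#'   phase3: {alpha: 0.05, target_power: 0.9, max_total: 400}
#' scenario: {orr1: 0.6, orr0: 0.4}
#' ")
#' validate_run_config(cfg)
NULL

config_schema <- list(
  top = c("segment", "n_reps", "seed", "designs", "scenario", "enrollment",
          "output", "sweep"),
  designs_A = c("phase2", "phase3"),
  designs_B = c("phase1", "phase2"),
  designs_C = c("phase2", "phase3"),
  phase2_A = c("n2", "orr0", "orr1_alt", "alpha"),
  phase3 = c("alpha", "target_power", "max_total", "sizing"),
  phase1_B = c("n1", "skeleton", "tox_target", "prior_sd", "start_dose",
               "no_skip"),
  phase2_B = c("n2", "orr0", "orr1_alt", "alpha", "tox_monitor_threshold"),
  phase2_C = c("n2", "cutoffs", "stage_fractions", "alpha",
               "min_subgroup_pairs"),
  scenario_A = c("orr1", "orr0"),
  scenario_B = c("tox", "orr"),
  scenario_C = c("type", "crossing", "slope", "orr0"),
  enrollment = c("rate_a", "rate_b", "gap_months", "followup_a", "followup_b"),
  output = c("csv", "manifest"),
  sweep = c("sizes")
)

unknown_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra)) {
    sprintf("unknown key(s) in %s: %s", where, paste(extra, collapse = ", "))
  } else {
    character(0)
  }
}

need_prob <- function(x, where, lower_open = FALSE, upper_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lower_open) x > 0 else x >= 0) && (if (upper_open) x < 1 else x <= 1)
  if (ok) character(0) else sprintf("%s must be a probability", where)
}

need_count <- function(x, where, min = 1) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
  if (ok) character(0) else sprintf("%s must be an integer >= %g", where, min)
}

#' Validate a run configuration
#'
#' Checks a configuration list (typically parsed from YAML) against the
#' schema in [run_config]: required blocks present, all values in range,
#' unknown keys rejected. Returns the problems found rather than stopping,
#' so callers can report all of them at once.
#'
#' @param cfg configuration list (see [run_config]).
#' @return Character vector of field-level problems; empty when valid.
#' @export
validate_run_config <- function(cfg) {
  probs <- character(0)
  if (!is.list(cfg)) return("config must be a mapping")
  probs <- c(probs, unknown_keys(cfg, config_schema$top, "config"))
  seg <- cfg$segment
  if (is.null(seg) || !seg %in% c("A", "B", "C")) {
    return(c(probs, "segment must be one of \"A\", \"B\", \"C\""))
  }
  probs <- c(probs, need_count(cfg$n_reps %||% 1, "n_reps"))
  probs <- c(probs, need_count(cfg$seed %||% 1, "seed", min = 0))
  des <- cfg$designs
  if (is.null(des)) return(c(probs, "designs block is required"))
  probs <- c(probs, unknown_keys(des, config_schema[[paste0("designs_", seg)]],
                                 "designs"))
  scn <- cfg$scenario
  if (is.null(scn)) return(c(probs, "scenario block is required"))
  probs <- c(probs,
             unknown_keys(scn, config_schema[[paste0("scenario_", seg)]],
                          "scenario"))
  if (seg == "A") {
    p2 <- des$phase2
    if (is.null(p2)) {
      probs <- c(probs, "designs.phase2 is required")
    } else {
      probs <- c(probs, unknown_keys(p2, config_schema$phase2_A, "designs.phase2"),
                 need_count(p2$n2 %||% NA, "designs.phase2.n2"),
                 need_prob(p2$orr0 %||% 0.4, "designs.phase2.orr0", TRUE, TRUE),
                 need_prob(p2$alpha %||% 0.05, "designs.phase2.alpha", TRUE, TRUE))
    }
    probs <- c(probs, need_prob(scn$orr1 %||% NA, "scenario.orr1"),
               need_prob(scn$orr0 %||% NA, "scenario.orr0"))
  }
  if (seg == "B") {
    p1 <- des$phase1
    if (is.null(p1)) {
      probs <- c(probs, "designs.phase1 is required")
    } else {
      probs <- c(probs, unknown_keys(p1, config_schema$phase1_B, "designs.phase1"),
                 need_count(p1$n1 %||% NA, "designs.phase1.n1"),
                 need_prob(p1$tox_target %||% 0.25, "designs.phase1.tox_target",
                           TRUE, TRUE))
      sk <- p1$skeleton
      if (!is.null(sk) && (any(sk <= 0) || any(sk >= 1) || any(diff(sk) <= 0))) {
        probs <- c(probs, "designs.phase1.skeleton must be strictly increasing in (0,1)")
      }
    }
    if (!is.null(des$phase2)) {
      probs <- c(probs, unknown_keys(des$phase2, config_schema$phase2_B,
                                     "designs.phase2"))
    }
    if (is.null(scn$tox) || is.null(scn$orr) ||
        length(scn$tox) != length(scn$orr)) {
      probs <- c(probs, "scenario.tox and scenario.orr must be aligned vectors")
    } else if (any(scn$tox < 0 | scn$tox > 1) || any(scn$orr < 0 | scn$orr > 1)) {
      probs <- c(probs, "scenario probabilities must lie in [0,1]")
    }
  }
  if (seg == "C") {
    p2 <- des$phase2
    if (is.null(p2)) {
      probs <- c(probs, "designs.phase2 is required")
    } else {
      probs <- c(probs, unknown_keys(p2, config_schema$phase2_C, "designs.phase2"),
                 need_count(p2$n2 %||% NA, "designs.phase2.n2", min = 4),
                 need_prob(p2$alpha %||% 0.05, "designs.phase2.alpha", TRUE, TRUE))
    }
    if (!is.null(scn$type) && !scn$type %in% c("logistic", "flat")) {
      probs <- c(probs, "scenario.type must be \"logistic\" or \"flat\"")
    }
    probs <- c(probs, need_prob(scn$orr0 %||% 0.4, "scenario.orr0", TRUE, TRUE))
  }
  if (seg %in% c("A", "C") && !is.null(des$phase3)) {
    p3 <- des$phase3
    probs <- c(probs, unknown_keys(p3, config_schema$phase3, "designs.phase3"),
               need_prob(p3$alpha %||% 0.05, "designs.phase3.alpha", TRUE, TRUE),
               need_prob(p3$target_power %||% 0.9, "designs.phase3.target_power",
                         TRUE, TRUE),
               need_count(p3$max_total %||% 400, "designs.phase3.max_total",
                          min = 2))
    if (!is.null(p3$sizing) && !p3$sizing %in% c("exact", "normal")) {
      probs <- c(probs, "designs.phase3.sizing must be \"exact\" or \"normal\"")
    }
  }
  if (!is.null(cfg$enrollment)) {
    en <- cfg$enrollment
    probs <- c(probs, unknown_keys(en, config_schema$enrollment, "enrollment"))
    for (k in intersect(names(en), config_schema$enrollment)) {
      if (!is.numeric(en[[k]]) || en[[k]] < 0) {
        probs <- c(probs, sprintf("enrollment.%s must be non-negative", k))
      }
    }
  }
  if (!is.null(cfg$output)) {
    probs <- c(probs, unknown_keys(cfg$output, config_schema$output, "output"))
  }
  if (!is.null(cfg$sweep)) {
    probs <- c(probs, unknown_keys(cfg$sweep, config_schema$sweep, "sweep"))
    if (is.null(cfg$sweep$sizes)) probs <- c(probs, "sweep.sizes is required")
  }
  probs
}

#' Build a `ddp_segment` from a validated configuration
#'
#' @param cfg configuration list; validated first, stopping on problems.
#' @return A `ddp_segment`.
#' @export
segment_from_config <- function(cfg) {
  probs <- validate_run_config(cfg)
  if (length(probs)) {
    stop(paste(c("invalid config:", probs), collapse = "\n  "), call. = FALSE)
  }
  enr <- do.call(enrollment_model, cfg$enrollment %||% list())
  des <- cfg$designs
  scn <- cfg$scenario
  if (cfg$segment == "A") {
    p2 <- des$phase2
    p3 <- des$phase3 %||% list()
    ddp_segment_A(
      phase2 = single_arm_design(p2$n2, p2$orr0 %||% 0.4,
                                 p2$orr1_alt %||% 0.6, p2$alpha %||% 0.05),
      phase3 = rct_design(NULL, p3$alpha %||% 0.05, p3$target_power %||% 0.9,
                          p3$max_total %||% 400, p3$sizing %||% "exact"),
      scenario = list(orr1 = scn$orr1, orr0 = scn$orr0),
      enrollment = enr
    )
  } else if (cfg$segment == "B") {
    p1 <- des$phase1
    p2 <- des$phase2 %||% list()
    ddp_segment_B(
      phase1 = crm_design(
        p1$n1,
        skeleton = unlist(p1$skeleton) %||% c(0.05, 0.12, 0.25, 0.40, 0.55, 0.68),
        tox_target = p1$tox_target %||% 0.25,
        prior_sd = p1$prior_sd %||% 1.34,
        start_dose = p1$start_dose %||% 3L,
        no_skip = p1$no_skip %||% TRUE
      ),
      scenario = dose_scenario(unlist(scn$tox), unlist(scn$orr)),
      phase2_n = p2$n2 %||% 42L,
      orr0 = p2$orr0 %||% 0.4,
      orr1_alt = p2$orr1_alt %||% 0.6,
      alpha = p2$alpha %||% 0.05,
      tox_monitor_threshold = p2$tox_monitor_threshold %||% 0.25,
      enrollment = enr
    )
  } else {
    p2 <- des$phase2
    p3 <- des$phase3 %||% list()
    scenario <- if ((scn$type %||% "logistic") == "flat") {
      make_null_biomarker_scenario(scn$orr0 %||% 0.4)
    } else {
      make_default_biomarker_scenario(crossing = scn$crossing %||% 0.6,
                                      slope = scn$slope %||% 5,
                                      orr0 = scn$orr0 %||% 0.4)
    }
    ddp_segment_C(
      phase2 = enrichment_design(
        p2$n2,
        cutoffs = unlist(p2$cutoffs) %||% seq(0.1, 0.9, by = 0.1),
        stage_fractions = unlist(p2$stage_fractions) %||% c(0.5, 0.25, 0.25),
        alpha = p2$alpha %||% 0.05,
        min_subgroup_pairs = p2$min_subgroup_pairs %||% 5L
      ),
      phase3 = rct_design(NULL, p3$alpha %||% 0.05, p3$target_power %||% 0.9,
                          p3$max_total %||% 400, p3$sizing %||% "exact"),
      scenario = scenario,
      enrollment = enr
    )
  }
}

#' Serialize a `ddp_segment` back to the configuration format
#'
#' Materializes every default so that the returned list, written as YAML,
#' reproduces the segment exactly; `segment_from_config()` of the result is
#' the identity (the serialization is lossless).
#'
#' @param segment a `ddp_segment`.
#' @param n_reps,seed run parameters recorded alongside the design.
#' @return A configuration list.
#' @export
segment_to_config <- function(segment, n_reps = 10000L, seed = 1L) {
  stopifnot(inherits(segment, "ddp_segment"))
  en <- unclass(segment$enrollment)
  if (segment$type == "A") {
    p2 <- segment$phase2
    p3 <- segment$phase3
    list(segment = "A", n_reps = n_reps, seed = seed,
         designs = list(
           phase2 = list(n2 = p2$n2, orr0 = p2$orr0, orr1_alt = p2$orr1_alt,
                         alpha = p2$alpha),
           phase3 = list(alpha = p3$alpha, target_power = p3$target_power,
                         max_total = p3$max_total, sizing = p3$sizing)
         ),
         scenario = list(orr1 = segment$scenario$orr1,
                         orr0 = segment$scenario$orr0),
         enrollment = en)
  } else if (segment$type == "B") {
    p1 <- segment$phase1
    p2 <- segment$phase2
    list(segment = "B", n_reps = n_reps, seed = seed,
         designs = list(
           phase1 = list(n1 = p1$n1, skeleton = p1$skeleton,
                         tox_target = p1$tox_target, prior_sd = p1$prior_sd,
                         start_dose = p1$start_dose, no_skip = p1$no_skip),
           phase2 = list(n2 = p2$n2, orr0 = p2$orr0, orr1_alt = p2$orr1_alt,
                         alpha = p2$alpha,
                         tox_monitor_threshold = segment$tox_monitor_threshold)
         ),
         scenario = list(tox = segment$scenario$tox,
                         orr = segment$scenario$orr),
         enrollment = en)
  } else {
    p2 <- segment$phase2
    p3 <- segment$phase3
    pars <- segment$scenario$params %||% list(type = "logistic")
    scn <- if (identical(pars$type, "flat")) {
      list(type = "flat", orr0 = segment$scenario$orr0)
    } else {
      list(type = "logistic", crossing = pars$crossing, slope = pars$slope,
           orr0 = segment$scenario$orr0)
    }
    list(segment = "C", n_reps = n_reps, seed = seed,
         designs = list(
           phase2 = list(n2 = p2$n2, cutoffs = p2$cutoffs,
                         stage_fractions = p2$stage_fractions,
                         alpha = p2$alpha,
                         min_subgroup_pairs = p2$min_subgroup_pairs),
           phase3 = list(alpha = p3$alpha, target_power = p3$target_power,
                         max_total = p3$max_total, sizing = p3$sizing)
         ),
         scenario = scn,
         enrollment = en)
  }
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  yaml::read_yaml(path)
}

write_metrics_csv <- function(df, path, comment) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  writeLines(paste0("# columns: ", paste(names(df), collapse = ", ")), con)
  utils::write.table(format(df, digits = 6, scientific = FALSE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Run a simulation described by a configuration
#'
#' Validates the configuration, runs the Monte-Carlo engine, and (when an
#' `output` block or explicit paths are given) writes a one-row metrics CSV
#' and a JSON run manifest containing the fully resolved configuration, the
#' seed, the estimates with their Monte-Carlo standard errors, the wall
#' time, and the package version -- enough to reproduce the run exactly.
#' Progress is logged to standard error.
#'
#' @param config a configuration list or the path to a YAML file.
#' @param out_csv,out_manifest optional output paths, overriding the
#'   config's `output` block.
#' @param n_reps,seed optional overrides of the config's values.
#' @param quiet suppress progress messages.
#' @return The [estimate_operating_characteristics()] result, invisibly.
#' @export
run_from_config <- function(config, out_csv = NULL, out_manifest = NULL,
                            n_reps = NULL, seed = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) read_config_file(config) else config
  segment <- segment_from_config(cfg)
  n_reps <- as.integer(n_reps %||% cfg$n_reps %||% 10000L)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  if (!quiet) {
    message(sprintf("ddpsim: segment %s, %d replicates, seed %d",
                    segment$type, n_reps, seed))
  }
  t0 <- proc.time()[["elapsed"]]
  m <- estimate_operating_characteristics(segment, n_reps = n_reps, seed = seed)
  wall <- proc.time()[["elapsed"]] - t0
  if (!quiet) {
    message(sprintf("ddpsim: done in %.1f s; DDP power %.4f (MC SE %.4f)",
                    wall, m$ddp_power, m$ddp_power_se))
  }
  out_csv <- out_csv %||% cfg$output$csv
  out_manifest <- out_manifest %||% cfg$output$manifest
  if (!is.null(out_csv)) {
    write_metrics_csv(
      metrics_row(m, first_trial_n = first_trial_size(segment)), out_csv,
      sprintf("ddpsim segment %s operating characteristics; MC SEs alongside each estimate", segment$type)
    )
  }
  if (!is.null(out_manifest)) {
    write_manifest(segment, m, n_reps, seed, wall, out_manifest)
  }
  invisible(m)
}

first_trial_size <- function(segment) {
  switch(segment$type, A = segment$phase2$n2, B = segment$phase1$n1,
         C = segment$phase2$n2)
}

write_manifest <- function(segment, m, n_reps, seed, wall, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    artifact = "ddpsim run manifest",
    package_version = as.character(utils::packageVersion("ddpsim")),
    config = segment_to_config(segment, n_reps = n_reps, seed = seed),
    metrics = unclass(m)[!vapply(unclass(m), is.null, TRUE)],
    wall_time_sec = wall
  )
  manifest$metrics$selection_distribution <-
    as.list(m$selection_distribution)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Sweep a configuration over first-trial sample sizes
#'
#' Runs [sweep_segment()] over the `sweep.sizes` grid of the configuration
#' (or an explicit `sizes` argument) and optionally writes the multi-row
#' metrics CSV.
#'
#' @inheritParams run_from_config
#' @param sizes integer grid of first-trial sizes; defaults to
#'   `config$sweep$sizes`.
#' @return The sweep data frame, invisibly.
#' @export
sweep_from_config <- function(config, sizes = NULL, out_csv = NULL,
                              n_reps = NULL, seed = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) read_config_file(config) else config
  segment <- segment_from_config(cfg)
  sizes <- as.integer(sizes %||% unlist(cfg$sweep$sizes))
  if (length(sizes) == 0L) stop("no sweep sizes given", call. = FALSE)
  n_reps <- as.integer(n_reps %||% cfg$n_reps %||% 10000L)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  if (!quiet) {
    message(sprintf("ddpsim: sweeping segment %s over %d sizes, %d reps each",
                    segment$type, length(sizes), n_reps))
  }
  df <- sweep_segment(segment, sizes, n_reps = n_reps, seed = seed)
  out_csv <- out_csv %||% cfg$output$csv
  if (!is.null(out_csv)) {
    write_metrics_csv(df, out_csv,
                      sprintf("ddpsim segment %s sweep over first-trial sample size", segment$type))
  }
  invisible(df)
}
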