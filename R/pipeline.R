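## End-to-end orchestration: synthesize (or read) inputs -> outlier filter
## -> trend fit -> projection -> prevalence/incidence conversion ->
## microsimulation under scenarios -> attribution -> costs -> reports.

#' Pipeline configuration
#'
#' Exactly one of `generator` (a [generator_spec()], synthetic inputs) or
#' `input_dir` (a directory of CSVs with the schemas written by
#' [write_synthetic_inputs()]) must be supplied.
#'
#' @param generator optional [generator_spec()].
#' @param input_dir optional directory of input CSVs.
#' @param start_year,end_year simulation window.
#' @param n_individuals microsimulation size.
#' @param scenario_ids scenarios to run (default 0, 1, 2).
#' @param seed master seed.
#' @param out_dir output directory for CSVs, figures and the manifest.
#' @param n_boot bootstrap draws for projection confidence limits; 0
#'   disables bands.
#' @param verbose print per-stage progress.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, input_dir = NULL,
                            start_year = 2010L, end_year = 2030L,
                            n_individuals = 50000L, scenario_ids = 0:2,
                            seed = 1L, out_dir = tempfile("obesitysim_"),
                            n_boot = 500L, verbose = FALSE) {
  if (is.null(generator) == is.null(input_dir)) {
    stop("supply exactly one of `generator` or `input_dir`")
  }
  structure(list(generator = generator, input_dir = input_dir,
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 n_individuals = as.integer(n_individuals),
                 scenario_ids = scenario_ids, seed = as.integer(seed),
                 out_dir = out_dir, n_boot = as.integer(n_boot),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

.read_inputs <- function(dir) {
  need <- c("survey.csv", "population.csv", "mortality.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("input file missing: ", file.path(dir, f))
    }
  }
  survey <- utils::read.csv(file.path(dir, "survey.csv"))
  req <- c("year", "sex", "age_lo", "age_hi", "category", "proportion", "n")
  miss <- setdiff(req, names(survey))
  if (length(miss) > 0) {
    stop("survey.csv: missing column(s) ", paste(miss, collapse = ", "))
  }
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  diseases <- lapply(manifest$diseases, function(md) {
    sched <- utils::read.csv(file.path(dir, paste0("disease_", md$name,
                                                   ".csv")))
    disease_definition(md$name, md$fatal, md$schedule_kind,
                       sched[, c("sex", "age", "value")],
                       rr = unlist(md$rr), case_fatality = md$case_fatality,
                       annual_unit_cost = md$annual_unit_cost)
  })
  list(survey = survey,
       population = utils::read.csv(file.path(dir, "population.csv")),
       mortality = utils::read.csv(file.path(dir, "mortality.csv")),
       diseases = diseases)
}

#' Run the whole two-stage projection pipeline
#'
#' Stages: (1) generate or read inputs; (2) outlier screen; (3) per-sex
#' constrained categorical trend fit and projection with bootstrap bands;
#' (4) prevalence-to-incidence conversion and relative-risk calibration;
#' (5) microsimulation under each scenario with common random numbers;
#' (6) obesity attribution, cases avoided, direct costs, savings and
#' indirect-cost extrapolation; (7) CSV artifacts and a run manifest.
#' Rerunning with the same config is bit-identical apart from the manifest
#' timestamp.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a `pipeline_bundle` list with all intermediate and
#'   final objects and the paths written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (cfg$verbose) message("[obesitysim] ", ...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$generator)) {
    say("stage 1: generating synthetic inputs")
    inputs <- list(survey = generate_survey_series(cfg$generator),
                   population = cfg$generator$population,
                   mortality = cfg$generator$mortality,
                   diseases = generate_disease_tables(cfg$generator))
  } else {
    say("stage 1: reading inputs from ", cfg$input_dir)
    inputs <- .read_inputs(cfg$input_dir)
  }

  say("stage 2: outlier screen")
  filt <- filter_outliers(inputs$survey)
  say("  kept ", nrow(filt$kept), " rows, removed ", nrow(filt$removed))

  say("stage 3: trend fit and projection")
  years <- cfg$start_year:cfg$end_year
  models <- lapply(SEXES, function(s) fit_category_trends(filt$kept, s))
  names(models) <- SEXES
  dist <- do.call(rbind, lapply(models, project_distribution, years = years))
  class(dist) <- c("projected_distribution", "data.frame")
  bands <- NULL
  if (cfg$n_boot > 0) {
    bands <- do.call(rbind, lapply(models, projection_confidence_limits,
                                   years = years, n_boot = cfg$n_boot,
                                   seed = cfg$seed))
  }

  say("stage 4: disease hazard preparation")
  hazards <- prepare_disease_hazards(inputs$diseases, dist,
                                     inputs$mortality, cfg$start_year)

  say("stage 5: microsimulation (n = ", cfg$n_individuals, ", scenarios ",
      paste(cfg$scenario_ids, collapse = "/"), ")")
  sim_cfg <- sim_config(cfg$n_individuals, cfg$start_year, cfg$end_year,
                        cfg$seed)
  tallies <- run_scenarios(sim_cfg, dist, hazards, inputs$population,
                           inputs$mortality, cfg$scenario_ids)

  say("stage 6: attribution, cases avoided, costs")
  unit_costs <- vapply(inputs$diseases, `[[`, 0, "annual_unit_cost")
  names(unit_costs) <- vapply(inputs$diseases, `[[`, "", "name")
  costs <- lapply(tallies, annual_direct_costs, unit_costs = unit_costs)
  base_id <- paste0("scenario_", cfg$scenario_ids[1])
  avoided <- list(); savings <- list()
  for (k in setdiff(names(tallies), base_id)) {
    avoided[[k]] <- cases_avoided(tallies[[base_id]], tallies[[k]],
                                  attributed = TRUE)
    savings[[k]] <- cost_savings(costs[[base_id]], costs[[k]])
  }
  indirect <- lapply(costs, function(ct) {
    data.frame(year = ct$totals$year,
               indirect_millions = indirect_from_ratio(ct$totals$total_millions))
  })

  say("stage 7: writing artifacts to ", cfg$out_dir)
  paths <- c(projection = file.path(cfg$out_dir, "projected_bmi.csv"))
  utils::write.csv(dist, paths["projection"], row.names = FALSE)
  if (!is.null(bands)) {
    paths["bands"] <- file.path(cfg$out_dir, "projected_bmi_bands.csv")
    utils::write.csv(bands, paths["bands"], row.names = FALSE)
  }
  for (k in names(tallies)) {
    p <- file.path(cfg$out_dir, paste0("tally_", k, ".csv"))
    utils::write.csv(tallies[[k]]$by_disease, p, row.names = FALSE)
    paths[paste0("tally_", k)] <- p
    p <- file.path(cfg$out_dir, paste0("costs_", k, ".csv"))
    utils::write.csv(costs[[k]]$by_disease, p, row.names = FALSE)
    paths[paste0("costs_", k)] <- p
  }
  for (k in names(avoided)) {
    p <- file.path(cfg$out_dir, paste0("cases_avoided_", k, ".csv"))
    utils::write.csv(avoided[[k]], p, row.names = FALSE)
    paths[paste0("avoided_", k)] <- p
  }
  manifest <- list(
    seed = cfg$seed, n_individuals = cfg$n_individuals,
    years = paste0(cfg$start_year, "-", cfg$end_year),
    scenarios = cfg$scenario_ids,
    n_boot = cfg$n_boot,
    outlier_rows_removed = nrow(filt$removed),
    units = list(prevalence = "cases per 100,000 alive population",
                 cumulative_incidence =
                   "cases per 100,000 of start-year population",
                 costs = "EUR millions per calendar year"),
    package_version = as.character(utils::packageVersion("obesitysim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))

  bundle <- structure(list(config = cfg, inputs = inputs, filtered = filt,
                           models = models, dist = dist, bands = bands,
                           hazards = hazards, tallies = tallies,
                           costs = costs, avoided = avoided,
                           savings = savings, indirect = indirect,
                           paths = paths),
                      class = "pipeline_bundle")
  invisible(bundle)
}

#' Render summary figures and a plain-text headline summary
#'
#' Produces: a bar chart of projected overweight+obesity prevalence by sex
#' at the start, middle and end year; line charts of obesity-related
#' disease prevalence per 100,000; bar charts of cumulative incident cases
#' avoided per 100,000 by scenario; and a text file of headline numbers.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @param out_dir where to write `summary.txt` (default: the bundle's
#'   output directory). Figures are returned, not written.
#' @return list of ggplot objects (`overweight_obese`, `prevalence`,
#'   `cases_avoided`) plus `summary_lines`.
#' @export
render_reports <- function(bundle, out_dir = bundle$config$out_dir) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  cfg <- bundle$config
  show_years <- unique(c(cfg$start_year,
                         cfg$start_year + (cfg$end_year - cfg$start_year) %/% 2,
                         cfg$end_year))
  ## population-weighted overweight+obese share by sex and year
  pop <- bundle$inputs$population
  dist <- bundle$dist
  age_groups <- make_age_groups(sort(unique(dist$age_lo)),
                                sort(unique(dist$age_hi)))
  gidx <- age_group_index(pmin(pop$age, 100), age_groups)
  wt <- stats::aggregate(count ~ grp + sex,
                         data.frame(count = pop$count, grp = gidx,
                                    sex = pop$sex), sum)
  ow_ob <- do.call(rbind, lapply(show_years, function(y) {
    d <- dist[dist$year == y, ]
    d$grp <- age_group_index(d$age_lo, age_groups)
    d <- merge(d, wt, by = c("grp", "sex"))
    agg <- stats::aggregate(
      cbind(w = count, x = (p_overweight + p_obese) * count) ~ sex, d, sum)
    data.frame(year = y, sex = agg$sex, pct = 100 * agg$x / agg$w)
  }))
  fig1 <- ggplot2::ggplot(ow_ob, ggplot2::aes(factor(.data$year), .data$pct,
                                              fill = .data$sex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Year", y = "Overweight + obese (%)",
                  title = "Projected prevalence of overweight and obesity") +
    ggplot2::theme_minimal()

  base_id <- names(bundle$tallies)[1]
  bd <- bundle$tallies[[base_id]]$by_disease
  fig2 <- ggplot2::ggplot(bd, ggplot2::aes(.data$year,
                                           .data$prevalent_attrib_per_100k,
                                           colour = .data$disease)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Obesity-related prevalent cases / 100,000",
                  title = "Projected obesity-related disease prevalence") +
    ggplot2::theme_minimal()

  fig3 <- NULL
  if (length(bundle$avoided) > 0) {
    av <- do.call(rbind, bundle$avoided)
    av_last <- av[av$year == cfg$end_year, ]
    fig3 <- ggplot2::ggplot(av_last,
                            ggplot2::aes(.data$disease, .data$avoided_per_100k,
                                         fill = factor(.data$scenario))) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = NULL, y = "Cumulative incident cases avoided / 100,000",
                    fill = "Scenario",
                    title = "Cases avoided relative to scenario 0") +
      ggplot2::theme_minimal()
  }

  lines <- c(
    "obesitysim pipeline summary",
    sprintf("Horizon %d; %d simulated individuals; seed %d",
            cfg$end_year, cfg$n_individuals, cfg$seed),
    sprintf("Overweight+obese at %d: %s", cfg$end_year,
            paste(sprintf("%s %.1f%%",
                          ow_ob$sex[ow_ob$year == cfg$end_year],
                          ow_ob$pct[ow_ob$year == cfg$end_year]),
                  collapse = ", ")))
  ct0 <- bundle$costs[[base_id]]$totals
  lines <- c(lines, sprintf(
    "Obesity-related direct costs at %d (scenario 0): EUR %.0f million",
    cfg$end_year, ct0$total_millions[ct0$year == cfg$end_year]))
  for (k in names(bundle$savings)) {
    sv <- bundle$savings[[k]]
    lines <- c(lines, sprintf(
      "%s: direct-cost saving at %d EUR %.0f million", k, cfg$end_year,
      sv$savings_millions[sv$year == cfg$end_year]))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(lines, file.path(out_dir, "summary.txt"))
  }
  list(overweight_obese = fig1, prevalence = fig2, cases_avoided = fig3,
       summary_lines = lines)
}
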