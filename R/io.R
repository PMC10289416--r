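#' Write a model-input set as plain-text parameter files
#'
#' Emits the fixed file set consumed by \code{\link{read_inputs}}:
#' \itemize{
#'   \item \code{config.json}: J, horizon_age, N0, screening_unit_cost;
#'   \item \code{incidence.csv}: columns \code{j, status, iota};
#'   \item \code{stages.csv}: columns \code{j, status, k, q};
#'   \item \code{survival.csv}: columns \code{j, k, t, lam, pi_d1, pi_d2}
#'     (the cause columns are 0 for \code{k = -1});
#'   \item \code{costs_c1.csv}, \code{costs_c2.csv}, \code{costs_c3.csv}:
#'     the phase cost tables, columns \code{band, stage_0..stage_4}.
#' }
#' Numbers always use the \code{.} decimal separator.
#'
#' @param inputs a \code{model_inputs}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_inputs <- function(inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- inputs$grid
  J <- grid$J
  jsonlite::write_json(
    list(J = grid$J, horizon_age = grid$horizon_age, N0 = inputs$N0,
         screening_unit_cost = inputs$cost_model$screening_unit_cost),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)

  inc <- expand.grid(j = seq_len(J), status = STATUS_LEVELS,
                     stringsAsFactors = FALSE)
  inc$iota <- inputs$incidence[cbind(inc$j, match(inc$status, STATUS_LEVELS))]
  utils::write.csv(inc, file.path(dir, "incidence.csv"), row.names = FALSE)

  st <- expand.grid(j = seq_len(J), status = STATUS_LEVELS, k = 0:4,
                    stringsAsFactors = FALSE)
  st$q <- inputs$stages[cbind(st$j, match(st$status, STATUS_LEVELS),
                              st$k + 1L)]
  utils::write.csv(st, file.path(dir, "stages.csv"), row.names = FALSE)

  Tn <- dim(inputs$survival)[3]
  sv <- expand.grid(j = seq_len(J), k = STAGE_CODES, t = 0:(Tn - 1L))
  sv$lam <- inputs$survival[cbind(sv$j, sv$k + 2L, sv$t + 1L)]
  sv$pi_d1 <- 0
  sv$pi_d2 <- 0
  dg <- sv$k >= 0
  sv$pi_d1[dg] <- inputs$causes[cbind(sv$j[dg], sv$k[dg] + 1L,
                                      sv$t[dg] + 1L, 1L)]
  sv$pi_d2[dg] <- inputs$causes[cbind(sv$j[dg], sv$k[dg] + 1L,
                                      sv$t[dg] + 1L, 2L)]
  utils::write.csv(sv, file.path(dir, "survival.csv"), row.names = FALSE)

  for (nm in c("C1", "C2", "C3")) {
    m <- inputs$cost_model[[nm]]
    df <- data.frame(band = rownames(m), m, check.names = FALSE,
                     row.names = NULL)
    colnames(df) <- c("band", paste0("stage_", 0:4))
    utils::write.csv(df, file.path(dir, paste0("costs_",
                                               tolower(nm), ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

read_param_csv <- function(path, required) {
  if (!file.exists(path)) stop("parameter file missing: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(required, colnames(df))
  if (length(miss) > 0L) {
    stop(basename(path), ": missing column(s) ", paste(miss, collapse = ", "))
  }
  df
}

#' Read a model-input set from parameter files
#'
#' Reads the file layout written by \code{\link{write_inputs}} and
#' validates the result. Validation is aggregated: every violation across
#' all files is collected and reported in a single error, so a broken
#' parameter set surfaces all its problems at once.
#'
#' @param dir directory holding the parameter files.
#' @return a validated \code{model_inputs}.
#' @export
read_inputs <- function(dir) {
  cfgp <- file.path(dir, "config.json")
  if (!file.exists(cfgp)) stop("parameter file missing: ", cfgp)
  cfg <- jsonlite::read_json(cfgp, simplifyVector = TRUE)
  grid <- age_grid(cfg$J, cfg$horizon_age)
  J <- grid$J

  inc_df <- read_param_csv(file.path(dir, "incidence.csv"),
                           c("j", "status", "iota"))
  incidence <- matrix(NA_real_, J, 2L,
                      dimnames = list(NULL, STATUS_LEVELS))
  incidence[cbind(inc_df$j, match(inc_df$status, STATUS_LEVELS))] <- inc_df$iota

  st_df <- read_param_csv(file.path(dir, "stages.csv"),
                          c("j", "status", "k", "q"))
  stages <- array(NA_real_, dim = c(J, 2L, 5L),
                  dimnames = list(NULL, STATUS_LEVELS, DIAG_STAGE_LABELS))
  stages[cbind(st_df$j, match(st_df$status, STATUS_LEVELS),
               st_df$k + 1L)] <- st_df$q

  sv_df <- read_param_csv(file.path(dir, "survival.csv"),
                          c("j", "k", "t", "lam", "pi_d1", "pi_d2"))
  Tn <- max(sv_df$t) + 1L
  survival <- array(0, dim = c(J, 6L, Tn),
                    dimnames = list(NULL, STAGE_LABELS, NULL))
  survival[cbind(sv_df$j, sv_df$k + 2L, sv_df$t + 1L)] <- sv_df$lam
  causes <- array(0, dim = c(J, 5L, Tn, 2L),
                  dimnames = list(NULL, DIAG_STAGE_LABELS, NULL,
                                  c("d1", "d2")))
  dg <- sv_df$k >= 0
  causes[cbind(sv_df$j[dg], sv_df$k[dg] + 1L, sv_df$t[dg] + 1L, 1L)] <-
    sv_df$pi_d1[dg]
  causes[cbind(sv_df$j[dg], sv_df$k[dg] + 1L, sv_df$t[dg] + 1L, 2L)] <-
    sv_df$pi_d2[dg]

  read_cost <- function(stem) {
    df <- read_param_csv(file.path(dir, paste0(stem, ".csv")),
                         c("band", paste0("stage_", 0:4)))
    m <- as.matrix(df[match(COST_BANDS, df$band), paste0("stage_", 0:4)])
    storage.mode(m) <- "double"
    m
  }
  cm <- cost_model(read_cost("costs_c1"), read_cost("costs_c2"),
                   read_cost("costs_c3"),
                   screening_unit_cost = as.numeric(cfg$screening_unit_cost))

  out <- model_inputs(grid, incidence, stages, survival, causes, cm,
                      N0 = as.numeric(cfg$N0))
  if (anyNA(incidence) || anyNA(stages)) {
    stop("parameter files leave (j, status) cells undefined in ", dir)
  }
  bad <- validate_inputs(out)
  if (length(bad) > 0L) {
    stop("invalid parameter set in ", dir, ":\n  ",
         paste(bad, collapse = "\n  "))
  }
  out
}

#' @rdname read_inputs
#' @export
load_inputs <- read_inputs

#' Build the four-policy cost-effectiveness comparison table
#'
#' Evaluates the reference policy (screening 50-69) and the three
#' extension scenarios (younger 46-69, older 50-74, both 46-74) and
#' assembles the comparison table: expected costs, expected life-years,
#' their ratio, incremental cost, ICER and expected breast cancer deaths.
#'
#' @param baseline a validated \code{model_inputs}.
#' @param older_incidence replacement old-age incidence rates (see
#'   \code{\link{build_older_extension}}); defaults to the synthetic
#'   stand-in \code{\link{synthetic_older_incidence}}.
#' @param baseline_policy the current policy.
#' @param out_csv optional path: write the table as CSV (monetary values
#'   at full precision; formatting is the caller's concern).
#' @return the comparison data.frame, reference row first.
#' @export
run_table4 <- function(baseline,
                       older_incidence = synthetic_older_incidence(baseline),
                       baseline_policy = finnish_current_policy(baseline$grid),
                       out_csv = NULL) {
  assert_valid(baseline)
  scen <- list(
    list(name = "50-69 yr", inputs = baseline, policy = baseline_policy),
    build_younger_extension(baseline, baseline_policy),
    build_older_extension(baseline, older_incidence,
                          baseline_policy = baseline_policy),
    build_both_extension(baseline, older_incidence,
                         baseline_policy = baseline_policy))
  res <- lapply(scen, function(s) {
    policy_result(s$inputs, s$policy, label = s$name, validate = FALSE)
  })
  tab <- comparison_table(res)
  if (!is.null(out_csv)) {
    utils::write.csv(tab, out_csv, row.names = FALSE, na = "")
  }
  tab
}

sensitivity_groups <- function(grid, scenario_name) {
  younger <- which(lower_age(grid, seq_len(grid$J)) <= 68) # ages 46-69
  older <- setdiff(seq_len(grid$J), younger)               # ages > 69
  switch(scenario_name,
         "46-69 yr" = younger,
         "50-74 yr" = older,
         "46-74 yr" = c(younger, older))
}

stage_shift_groups <- function(grid, scenario_name) {
  younger <- which(lower_age(grid, seq_len(grid$J)) <= 50) # ages 46-51
  older <- which(lower_age(grid, seq_len(grid$J)) > 69)
  switch(scenario_name,
         "46-69 yr" = younger,
         "50-74 yr" = older,
         "46-74 yr" = c(younger, older))
}

#' Run the six one-way sensitivity analyses
#'
#' Reproduces the sensitivity design: modelled incidence rates +/-10\%
#' (applied to the age groups each scenario models: 46-69 for the younger
#' extension, above 69 for the older, both for the double extension), all
#' treatment costs +10\% and +50\% (applied to every policy including the
#' reference), and +/-0.02 conditional probability moved between localized
#' and regional disease for the modelled stage distributions (ages 46-51
#' and/or above 69). Each analysis yields a comparison table shaped like
#' \code{\link{run_table4}}.
#'
#' @inheritParams run_table4
#' @param out_dir optional directory: write one CSV per analysis.
#' @return named list of six comparison data.frames.
#' @export
run_sensitivity <- function(baseline,
                            older_incidence = synthetic_older_incidence(baseline),
                            baseline_policy = finnish_current_policy(baseline$grid),
                            out_dir = NULL) {
  assert_valid(baseline)
  grid <- baseline$grid
  scen <- list(
    list(name = "50-69 yr", inputs = baseline, policy = baseline_policy),
    build_younger_extension(baseline, baseline_policy),
    build_older_extension(baseline, older_incidence,
                          baseline_policy = baseline_policy),
    build_both_extension(baseline, older_incidence,
                         baseline_policy = baseline_policy))
  variants <- c("incidence_up", "incidence_down", "costs_up_10",
                "costs_up_50", "stage_up", "stage_down")
  out <- list()
  for (v in variants) {
    res <- lapply(scen, function(s) {
      inp <- s$inputs
      if (v %in% c("costs_up_10", "costs_up_50")) {
        # cost uncertainty hits every policy, reference included
        inp <- apply_sensitivity(inp, v)
      } else if (s$name != "50-69 yr") {
        groups <- if (v %in% c("stage_up", "stage_down")) {
          stage_shift_groups(grid, s$name)
        } else {
          sensitivity_groups(grid, s$name)
        }
        inp <- apply_sensitivity(inp, v, groups = groups)
      }
      policy_result(inp, s$policy, label = s$name, validate = FALSE)
    })
    out[[v]] <- comparison_table(res)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(out[[v]],
                       file.path(out_dir, paste0("sensitivity_", v, ".csv")),
                       row.names = FALSE, na = "")
    }
  }
  out
}

#' Write a small JSON run manifest
#'
#' Records what produced a result directory: a content hash of the inputs,
#' the seed (if any randomness was involved), and the package version.
#'
#' @param path output JSON path.
#' @param inputs the \code{model_inputs} used.
#' @param seed seed used for any Monte Carlo component (NA for the
#'   deterministic analytic pipeline).
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, inputs, seed = NA) {
  hash <- sum(unlist(lapply(
    list(inputs$incidence, inputs$stages, inputs$survival, inputs$causes),
    function(m) sum(m * seq_along(m)))))
  jsonlite::write_json(
    list(inputs_checksum = hash, seed = seed,
         package = "flexscreen",
         version = as.character(utils::packageVersion("flexscreen"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
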