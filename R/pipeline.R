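# Pipeline entry points tying the stages together: synthetic cohort
# simulation, afferent tables, per-trial metric tables, and the cohort
# report. These are the package's equivalent of a command-line front end;
# each is reproducible from a seed and writes plain CSV/JSON.

#' Simulate a synthetic cohort and write trial files
#'
#' Generates a cohort table, per-subject phantom cycles and a gait trial per
#' requested condition, and (optionally) writes each trial as CSV + JSON
#' sidecar under `out_dir`.
#'
#' @param n_per_group Subjects per cohort (default 7, a 14-subject two-arm
#'   design).
#' @param conditions Condition labels to simulate per subject.
#' @param seed Global seed.
#' @param out_dir Optional output directory for trial CSV files.
#' @param noise Cohort metric noise (see [generate_cohort()]).
#' @return Tibble: one row per subject x condition with `subject`, `group`,
#'   `afferent`, `condition` and a `trial` list-column; attribute `cohort`
#'   holds the subject-level table, attribute `files` any written paths.
#' @export
simulate_cohort <- function(n_per_group = 7, conditions = "level_max",
                            seed = 1L, out_dir = NULL, noise = 0.1) {
  bad <- setdiff(conditions, gait_conditions())
  if (length(bad)) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cohort <- generate_cohort(n_per_group = n_per_group, seed = seed,
                            noise = noise)
  rows <- tidyr::expand_grid(subject = cohort$subject, condition = conditions)
  rows <- dplyr::left_join(rows, cohort[, c("subject", "group", "afferent")],
                           by = "subject")
  rows$trial <- purrr::pmap(
    list(rows$subject, rows$group, rows$afferent, rows$condition),
    function(s, g, a, cond) {
      spec <- archetype_spec(g, afferent_level = a,
                             seed = seed + match(s, cohort$subject) +
                               1000L * match(cond, conditions))
      generate_gait_trial(spec, condition = cond)
    })
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- purrr::pmap_chr(
      list(rows$subject, rows$condition, rows$trial),
      function(s, cond, tr) {
        path <- file.path(out_dir, sprintf("%s_%s.csv", s, cond))
        df <- dplyr::left_join(
          tr$kinematics, tr$kinetics[, c("time_s", "torque", "power")],
          by = "time_s")
        # name the ipsilateral ankle `angle` so the file is directly
        # consumable by normalize_cycle()
        names(df)[names(df) == "ankle"] <- "angle"
        write_trial_csv(df, path, sample_rate = 1000,
                        units = list(angle = "deg", torque = "Nm/kg",
                                     power = "W/kg"),
                        condition = cond, seed = tr$spec$seed)
        path
      })
  }
  attr(rows, "cohort") <- cohort
  attr(rows, "files") <- files
  rows
}

#' Afferent table for a set of archetype specifications
#'
#' Generates phantom cycles per subject, estimates spindle afferents and
#' tabulates the agonist-antagonist statistic.
#'
#' @param specs List of `bg_archetype` objects (must be non-empty).
#' @param params Spindle parameters.
#' @return Tibble: `group`, `afferent` (Imp/s), `units`.
#' @export
afferent_table <- function(specs, params = spindle_params()) {
  if (!length(specs)) stop("empty input: no archetype specs supplied",
                           call. = FALSE)
  purrr::map_dfr(specs, function(sp) {
    ph <- generate_phantom_cycles(sp, n_cycles = 3, params = params)
    est <- estimate_afferents(ph$fascicle, params = params)
    tibble::tibble(group = sp$group_label,
                   afferent = agonist_antagonist_afferent(est),
                   units = "Imp/s")
  })
}

#' Per-trial biomechanical metric table
#'
#' Normalizes each trial into gait cycles and computes the per-condition
#' metrics: peak power (negative peak for stair descent), net work (weight
#' acceptance and pull-up windows for stairs), range of motion and
#' lower-extremity kinematic symmetry, averaged across the trial's cycles.
#'
#' @param trials Data frame with a `trial` list-column (e.g. from
#'   [simulate_cohort()]) plus `subject` and `condition` columns.
#' @return Tidy tibble: `subject`, `condition`, `metric`, `value`, `units`.
#' @export
metric_table <- function(trials) {
  need <- c("subject", "condition", "trial")
  if (!all(need %in% names(trials))) {
    stop("missing column(s): ", paste(setdiff(need, names(trials)),
                                      collapse = ", "), call. = FALSE)
  }
  purrr::pmap_dfr(
    list(trials$subject, trials$condition, trials$trial),
    function(s, cond, tr) {
      cycles <- normalize_cycle(tr)
      pk_mode <- if (cond == "stair_down") "negative" else "positive"
      wk_window <- switch(cond,
        stair_down = c(0, 35), stair_up = c(30, 60), c(0, 100))
      pk <- mean(vapply(cycles, peak_power, numeric(1), mode = pk_mode))
      wk <- mean(vapply(cycles, net_work, numeric(1), window = wk_window))
      kin <- tr$kinematics[tr$kinematics$cycle == 1L, ]
      sym <- lek_symmetry(
        kin[, c("pct", "ankle", "knee", "hip")],
        stats::setNames(kin[, c("pct", "ankle_contra", "knee_contra",
                                "hip_contra")],
                        c("pct", "ankle", "knee", "hip")))
      tibble::tibble(
        subject = s, condition = cond,
        metric = c("peak_power", "net_work", "rom", "lek_symmetry", "speed"),
        value = c(pk, wk, rom(cycles[[1]]$angle),
                  sym$lek_symmetry[1], tr$speed),
        units = c("W/kg", "J/kg", "deg", "%", "m/s"))
    })
}

#' Cohort report: group contrasts and percent-change table
#'
#' Builds the headline cohort summary from a subject-level table: group
#' means, AMI-vs-CTL percent increases (or absolute differences where the
#' reference crosses zero), and normality-gated group comparisons.
#'
#' @param cohort Data frame with `group` plus numeric metric columns (and
#'   optionally `afferent`).
#' @param metrics Metric columns to report; defaults to every numeric column
#'   except `afferent`.
#' @return List of class `bg_report`: `summary` tibble (per metric: group
#'   means, contrast value and type, test branch and p value) and
#'   `markdown` (character vector of a printable table).
#' @export
cohort_report <- function(cohort, metrics = NULL) {
  stopifnot("group" %in% names(cohort))
  if (is.null(metrics)) {
    metrics <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    metrics <- setdiff(metrics, "afferent")
  }
  missing_m <- setdiff(metrics, names(cohort))
  if (length(missing_m)) {
    stop("missing metric column(s): ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  summary <- purrr::map_dfr(metrics, function(m) {
    a <- cohort[[m]][cohort$group == "AMI"]
    c_ <- cohort[[m]][cohort$group == "CTL"]
    cmp <- group_compare(a, c_)
    if (mean(c_) > 0) {
      pc <- percent_increase(mean(a), mean(c_))
      contrast <- pc$percent_raw; type <- "percent_increase"
    } else {
      contrast <- mean(a) - mean(c_); type <- "absolute_difference"
    }
    tibble::tibble(metric = m, mean_ami = mean(a), mean_ctl = mean(c_),
                   contrast = contrast, contrast_type = type,
                   test = cmp$test, p_value = cmp$p_value)
  })
  md <- c(
    "| metric | AMI mean | CTL mean | contrast | test | p |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %.3g | %.3g | %.3g (%s) | %s | %.2g |",
            summary$metric, summary$mean_ami, summary$mean_ctl,
            summary$contrast, summary$contrast_type, summary$test,
            summary$p_value))
  structure(list(summary = summary, markdown = md), class = "bg_report")
}

#' @export
print.bg_report <- function(x, ...) {
  cat(x$markdown, sep = "\n")
  invisible(x)
}
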