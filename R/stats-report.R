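#' Build a tidy cohort table of per-session metrics
#'
#' One row per (animal, session, condition, metric, stratum) with the
#' metric value; the substrate for the group-comparison layer.
#'
#' @param animal,session,condition,metric,value vectors of equal length.
#' @param stratum optional stratum label (velocity bin, distance bin, ...).
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(animal, session, condition, metric, value,
                         stratum = NA_character_) {
  d <- data.frame(animal = as.character(animal),
                  session = as.character(session),
                  condition = as.character(condition),
                  metric = as.character(metric),
                  stratum = as.character(stratum),
                  value = as.numeric(value),
                  stringsAsFactors = FALSE)
  structure(d, class = c("cohort_table", "data.frame"))
}

#' Nonparametric group comparison on per-animal means
#'
#' Aggregates a metric to one mean per animal (per condition) and applies
#' the two-sided Mann-Whitney U test (unpaired) or Wilcoxon signed-rank
#' test (paired, matched by animal).  Exact null distributions are used at
#' small n (the stats default).
#'
#' @param table a [cohort_table()].
#' @param metric metric name to test.
#' @param test `"mann_whitney"` or `"wilcoxon_signed_rank"`.
#' @param conditions length-2 character vector selecting and ordering the
#'   two groups (default: the two conditions present).
#' @return list with `test`, `statistic` (U or V), `p`, `n`, and
#'   `degenerate` (TRUE when all paired differences are zero).
#' @export
compare_groups <- function(table, metric,
                           test = c("mann_whitney",
                                    "wilcoxon_signed_rank"),
                           conditions = NULL) {
  test <- match.arg(test)
  d <- table[table$metric == metric, , drop = FALSE]
  if (!nrow(d)) stop("compare_groups: no rows for metric ", metric,
                     call. = FALSE)
  agg <- stats::aggregate(value ~ animal + condition, d, mean)
  if (is.null(conditions)) conditions <- sort(unique(agg$condition))
  if (length(conditions) != 2L)
    stop("compare_groups: exactly two conditions required", call. = FALSE)
  x <- agg$value[agg$condition == conditions[1]]
  y <- agg$value[agg$condition == conditions[2]]
  if (test == "mann_whitney") {
    if (length(x) < 2L || length(y) < 2L)
      stop("compare_groups: need >= 2 animals per group", call. = FALSE)
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
    return(list(test = test, statistic = unname(w$statistic),
                p = w$p.value, n = c(length(x), length(y)),
                degenerate = FALSE))
  }
  vx <- stats::setNames(x, agg$animal[agg$condition == conditions[1]])
  vy <- stats::setNames(y, agg$animal[agg$condition == conditions[2]])
  common <- intersect(names(vx), names(vy))
  if (length(common) < 2L)
    stop("compare_groups: need >= 2 paired animals", call. = FALSE)
  dx <- vx[common] - vy[common]
  if (all(dx == 0))
    return(list(test = test, statistic = NA_real_, p = NA_real_,
                n = length(common), degenerate = TRUE))
  w <- suppressWarnings(stats::wilcox.test(dx, exact = NULL))
  list(test = test, statistic = unname(w$statistic), p = w$p.value,
       n = length(common), degenerate = FALSE)
}

#' Mixed-effects condition contrast with per-animal grouping
#'
#' For metrics measured repeatedly within animals across strata (velocity
#' bins, distance bins), fits `value ~ condition + (1 | animal)` on the
#' per-(animal, condition, stratum) means via lme4 and reports the Wald
#' condition effect the way the repeated-measures literature does:
#' beta, SE, z = beta/SE, normal two-sided p, and the 95% Wald CI.
#' Strata receive equal weight.  A singular random-effects fit is reported
#' as such (`singular = TRUE`), never silently refit.
#'
#' @param table a [cohort_table()].
#' @param metric metric name.
#' @param conditions optional length-2 ordering; the second level is the
#'   treatment whose effect is reported.
#' @return list with `beta`, `se`, `z`, `p`, `ci` (length 2),
#'   `singular`, `n_animals`, `n_strata`.
#' @export
grouped_slope_contrast <- function(table, metric, conditions = NULL) {
  d <- table[table$metric == metric, , drop = FALSE]
  if (!nrow(d)) stop("grouped_slope_contrast: no rows for metric ", metric,
                     call. = FALSE)
  if (is.null(conditions)) conditions <- sort(unique(d$condition))
  d <- d[d$condition %in% conditions, , drop = FALSE]
  if (length(unique(d$animal)) < 2L)
    stop("grouped_slope_contrast: need >= 2 animals", call. = FALSE)
  if (length(unique(d$stratum)) < 2L)
    stop("grouped_slope_contrast: need >= 2 strata", call. = FALSE)
  agg <- stats::aggregate(value ~ animal + condition + stratum, d, mean)
  agg$condition <- factor(agg$condition, levels = conditions)
  fit <- lme4::lmer(value ~ condition + (1 | animal), data = agg,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  co <- summary(fit)$coefficients
  row <- grep("^condition", rownames(co))[1]
  beta <- co[row, "Estimate"]
  se <- co[row, "Std. Error"]
  z <- beta / se
  list(beta = beta, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       ci = c(beta - 1.96 * se, beta + 1.96 * se),
       singular = lme4::isSingular(fit),
       n_animals = length(unique(agg$animal)),
       n_strata = length(unique(agg$stratum)))
}

#' Assemble a session/cohort report
#'
#' Gathers pipeline outputs into one JSON-serializable document with the
#' configuration and seeds embedded for provenance.  Missing stages are a
#' hard error naming the stage.
#'
#' @param stages named list of pipeline outputs; must contain at least
#'   `behavior` (epoch statistics) and `coactivity` (profile); optional
#'   `events`, `sci`, `group_tests`, `config`, `seed`.
#' @param path optional path; when given the JSON document is written
#'   there.
#' @return the report list, invisibly when written.
#' @export
build_report <- function(stages, path = NULL) {
  required <- c("behavior", "coactivity")
  for (r in required)
    if (is.null(stages[[r]]))
      stop("build_report: missing output from stage `", r, "`",
           call. = FALSE)
  report <- list(
    generated_by = "minicoact",
    config = stages$config,
    seed = stages$seed,
    behavior = stages$behavior,
    events = stages$events,
    coactivity = stages$coactivity,
    sci = stages$sci,
    group_tests = stages$group_tests)
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}

#' Validate a report document's minimal schema
#'
#' @param report a list as returned by [build_report()].
#' @return TRUE, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  need <- c("generated_by", "behavior", "coactivity")
  for (f in need)
    if (is.null(report[[f]]))
      stop("validate_report: missing field `", f, "`", call. = FALSE)
  TRUE
}
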