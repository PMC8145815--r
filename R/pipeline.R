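#' Study configuration for the end-to-end pipeline
#'
#' Names the columns and analysis choices [run_study()] uses: outcome
#' columns, the income (ranking) column, optional weight, cluster and
#' period columns, the determinant list for the decomposition, the need
#' set, and the decomposition method.
#'
#' @param outcomes character vector of binary outcome columns.
#' @param income,weight,cluster,period column names (\code{weight} may
#'   be absent from the data; unit weights are then used).
#' @param determinants covariate columns entering the decomposition
#'   regression.
#' @param need subset of \code{determinants} treated as need.
#' @param method decomposition method, \code{"ame"} or \code{"ols"}.
#' @return a \code{study_config} list.
#' @export
study_config <- function(outcomes = c("outpatient", "inpatient"),
                         income = "income", weight = "weight",
                         cluster = "cluster", period = "period",
                         determinants = c("sex", "age_group", "education",
                                          "economic_status", "living_status",
                                          "sleeping_hours", "smoking",
                                          "alcohol", "disability",
                                          "body_pain", "chronic_diseases"),
                         need = c("sex", "age_group", "disability",
                                  "body_pain", "chronic_diseases"),
                         method = c("ame", "ols")) {
  structure(
    list(outcomes = outcomes, income = income, weight = weight,
         cluster = cluster, period = period, determinants = determinants,
         need = need, method = match.arg(method)),
    class = "study_config"
  )
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config)), f)
  unname(tools::md5sum(f))
}

#' Run the full utilization-equity study
#'
#' Orchestrates every stage on a validated respondent-level dataset:
#' sample composition, utilization rates with confidence limits per
#' outcome and period, chi-square tests of outcome against period,
#' and — per outcome within each period stratum — the concentration
#' index with its curve and the decomposition with the horizontal
#' inequity index. The analysis is seed-free: running twice on the same
#' data and config gives identical reports.
#'
#' @param data respondent-level data frame (see [validate_survey()]).
#' @param config a [study_config()].
#' @return object of class \code{study_report} with elements
#'   \code{composition}, \code{rates}, \code{chisq},
#'   \code{concentration} (list by outcome then period),
#'   \code{decomposition} (idem), \code{inequity} (summary data frame),
#'   \code{provenance}.
#' @export
run_study <- function(data, config = study_config()) {
  data <- validate_survey(data, outcomes = config$outcomes,
                          income = config$income, weight = config$weight,
                          cluster = config$cluster, period = config$period)
  periods <- unique(as.character(data[[config$period]]))
  for (p in periods) {
    if (sum(data[[config$period]] == p) == 0) {
      stop(sprintf("empty stratum: period '%s'", p), call. = FALSE)
    }
  }

  comp_vars <- c(config$period, config$determinants)
  composition <- composition_table(
    cbind(data[config$determinants],
          stats::setNames(data[config$period], config$period)),
    variables = comp_vars)

  rates <- do.call(rbind, lapply(config$outcomes, function(o) {
    do.call(rbind, lapply(periods, function(p) {
      idx <- data[[config$period]] == p
      if (!any(idx)) stop(sprintf("empty stratum: period '%s'", p),
                          call. = FALSE)
      r <- utilization_rate(data[[o]][idx], data[[config$weight]][idx])
      data.frame(outcome = o, period = p,
                 n = sum(idx), rate = r$rate,
                 cl_low = r$cl_low, cl_high = r$cl_high,
                 pct = 100 * r$rate, stringsAsFactors = FALSE)
    }))
  }))

  chisq <- lapply(stats::setNames(config$outcomes, config$outcomes),
                  function(o) {
    counts <- as.matrix(table(data[[config$period]], data[[o]]))
    chi_square(counts)
  })

  concentration <- list()
  decomposition <- list()
  ineq_rows <- list()
  fml_rhs <- paste(config$determinants, collapse = " + ")
  for (o in config$outcomes) {
    concentration[[o]] <- list()
    decomposition[[o]] <- list()
    for (p in periods) {
      idx <- data[[config$period]] == p
      sub <- data[idx, , drop = FALSE]
      if (sum(sub[[o]]) == 0) {
        stop(sprintf("empty stratum: no '%s' events in period '%s'", o, p),
             call. = FALSE)
      }
      ci <- concindex(ranked_outcome(sub[[o]], sub[[config$income]],
                                     sub[[config$weight]]),
                      cluster = sub[[config$cluster]])
      dc <- ci_decomp(stats::as.formula(paste(o, "~", fml_rhs)),
                      sub, rank = config$income, need = config$need,
                      weights = config$weight, cluster = config$cluster,
                      method = config$method)
      concentration[[o]][[p]] <- ci
      decomposition[[o]][[p]] <- dc
      ineq_rows[[length(ineq_rows) + 1L]] <- data.frame(
        outcome = o, period = p, C = ci$C,
        cl_low = ci$cl_low, cl_high = ci$cl_high,
        need_contribution = dc$need_contribution,
        residual = dc$residual, HI = dc$HI,
        stringsAsFactors = FALSE)
    }
  }

  structure(
    list(composition = composition, rates = rates, chisq = chisq,
         concentration = concentration, decomposition = decomposition,
         inequity = do.call(rbind, ineq_rows),
         provenance = list(config = config,
                           config_hash = config_hash(config),
                           n_rows = nrow(data),
                           periods = periods,
                           timestamp = NULL)),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Utilization-equity study report:", x$provenance$n_rows,
      "respondents,", length(x$provenance$periods), "periods\n\n")
  cat("Rates (%):\n")
  r <- x$rates
  r$rate <- sprintf("%.2f (%.2f, %.2f)", 100 * r$rate, 100 * r$cl_low,
                    100 * r$cl_high)
  print(r[, c("outcome", "period", "n", "rate")], row.names = FALSE)
  cat("\nConcentration and horizontal inequity:\n")
  iq <- x$inequity
  num <- vapply(iq, is.numeric, logical(1))
  iq[num] <- lapply(iq[num], round, 4)
  print(iq, row.names = FALSE)
  invisible(x)
}

#' Write a study report to CSV/JSON files
#'
#' Emits \code{composition.csv}, \code{rates.csv}, \code{chisq.csv},
#' one \code{concentration_<outcome>_<period>.csv} of curve
#' coordinates per stratum, \code{decomposition.csv} (grouped rows per
#' stratum plus CI and HI), and \code{report.json} with the headline
#' numbers and provenance.
#'
#' @param report a \code{study_report}.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE)
  wcsv(report$composition, "composition.csv")
  wcsv(report$rates, "rates.csv")
  wcsv(do.call(rbind, lapply(names(report$chisq), function(o) {
    ct <- report$chisq[[o]]
    data.frame(outcome = o, chi2 = ct$chi2, df = ct$df,
               p = ct$p_value, stringsAsFactors = FALSE)
  })), "chisq.csv")
  decomp_rows <- list()
  for (o in names(report$decomposition)) {
    for (p in names(report$decomposition[[o]])) {
      ci <- report$concentration[[o]][[p]]
      crv <- ci$curve
      wcsv(crv, sprintf("concentration_%s_%s.csv", o, p))
      dc <- report$decomposition[[o]][[p]]
      g <- dc$groups
      g <- rbind(g, data.frame(group = "HI", contribution = dc$HI,
                               pct = NA_real_))
      g$outcome <- o
      g$period <- p
      decomp_rows[[length(decomp_rows) + 1L]] <-
        g[, c("outcome", "period", "group", "contribution", "pct")]
    }
  }
  wcsv(do.call(rbind, decomp_rows), "decomposition.csv")
  jsonlite::write_json(
    list(rates = report$rates, inequity = report$inequity,
         provenance = list(
           config_hash = report$provenance$config_hash,
           n_rows = report$provenance$n_rows,
           periods = report$provenance$periods)),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
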