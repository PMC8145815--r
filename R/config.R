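# YAML config readers for the command-line entry points.

#' Read generator / study configuration from a YAML file
#'
#' \code{read_sim_config()} overlays the file's keys on the
#' [sim_config()] defaults (scalar fields plus optional
#' \code{covariates} / \code{outcomes} blocks; a covariate's
#' \code{probs} may be a vector or a list of per-band vectors).
#' \code{read_study_config()} does the same for [study_config()].
#'
#' @param path YAML file path.
#' @return a validated \code{sim_config} / \code{study_config}.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("n_respondents", "n_clusters", "income_meanlog",
                          "income_sdlog", "cluster_sd", "period", "seed"))]
  if (!is.null(raw$covariates)) {
    args$covariates <- lapply(raw$covariates, function(cv) {
      p <- cv$probs
      if (is.list(p)) p <- do.call(rbind, lapply(p, unlist))
      list(levels = unlist(cv$levels), probs = p)
    })
  }
  if (!is.null(raw$outcomes)) {
    args$outcomes <- lapply(raw$outcomes, function(oc) {
      list(intercept = oc$intercept,
           income_gradient = oc$income_gradient,
           effects = lapply(oc$effects, unlist))
    })
  }
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("outcomes", "income", "weight", "cluster",
                          "period", "determinants", "need", "method"))]
  args <- lapply(args, unlist)
  do.call(study_config, args)
}
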