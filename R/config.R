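#' Read and validate a run configuration
#'
#' Parses a YAML (or JSON) run configuration with two optional top-level
#' blocks: `cohort` (arguments of [cohort_config()], including the nested
#' `infected`, `noninfected`, `optics` and `acquisition` blocks) and
#' `analysis` (`mc_draws`, `seed`, `holm`, `group_test`). Unknown keys are
#' rejected with the offending path named.
#'
#' @param path Path to the configuration file.
#' @return List with elements `cohort` (a validated [cohort_config()]) and
#'   `analysis`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("cohort", "analysis"))
  if (length(bad)) {
    stop("unknown top-level configuration key(s): ",
         paste(bad, collapse = ", "))
  }
  coh <- raw$cohort
  if (is.null(coh)) coh <- list()
  top_ok <- c("n_infected", "n_noninfected", "master_seed", "infected",
              "noninfected", "optics", "acquisition")
  bad <- setdiff(names(coh), top_ok)
  if (length(bad)) {
    stop("unknown configuration key(s) in `cohort`: ",
         paste(bad, collapse = ", "))
  }
  cohort <- do.call(cohort_config, coh)
  ana_def <- list(mc_draws = 1e5, seed = 1, holm = FALSE,
                  group_test = "ranksum")
  ana <- raw$analysis
  if (is.null(ana)) ana <- list()
  bad <- setdiff(names(ana), names(ana_def))
  if (length(bad)) {
    stop("unknown configuration key(s) in `analysis`: ",
         paste(bad, collapse = ", "))
  }
  list(cohort = cohort, analysis = utils::modifyList(ana_def, ana))
}
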