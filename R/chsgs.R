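#' Published CHSGS reference tables
#'
#' The package ships three small published reference tables for the
#' seven-herb formula Chai-Hu-Shu-Gan-San (CHSGS) applied to depression:
#' the physicochemical properties of the 71-member core group of
#' functional components (CGFC), the per-herb component counts before and
#' after ADME screening, and the 13 retained receptor-to-effector cascades
#' with their maximum-targeting-weight scores. They serve as worked-example
#' inputs and as fixed points for auditing the screening and retention
#' rules.
#'
#' @return `chsgs_components()`: a `component_table` of the 71 CGFC members
#'   (columns `id`, `name`, `mw`, `hdon`, `hacc`, `rbn`, `logp`, `ob`).
#' @name chsgs
NULL

#' @rdname chsgs
#' @export
chsgs_components <- function() {
  read_component_table(system.file("extdata", "chsgs_cgfc_properties.tsv",
                                   package = "netpharm", mustWork = TRUE))
}

#' @rdname chsgs
#' @return `chsgs_herb_counts()`: data frame with one row per herb —
#'   `code`, `herb`, `n_components` (database components collected) and
#'   `n_active` (components passing the ADME screen).
#' @export
chsgs_herb_counts <- function() {
  df <- read_tsv_checked(system.file("extdata", "chsgs_herb_components.tsv",
                                     package = "netpharm", mustWork = TRUE))
  df$n_components <- as.integer(df$n_components)
  df$n_active <- as.integer(df$n_active)
  df
}

#' @rdname chsgs
#' @return `chsgs_cascades()`: data frame with `cascade` ("A--B--C" node
#'   chains) and `score` (normalised MTW score).
#' @export
chsgs_cascades <- function() {
  df <- read_tsv_checked(system.file("extdata", "chsgs_cascades.tsv",
                                     package = "netpharm", mustWork = TRUE))
  df$score <- as.numeric(df$score)
  df
}
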